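#' Phenotype ontology objects
#'
#' An `ontology` is a rooted directed acyclic graph of phenotype terms with
#' is-a (child -> parent) edges, as used by the Human Phenotype Ontology.
#' Ancestor closures are precomputed at construction so downstream semantic
#' similarity and obfuscation operations are cheap lookups.
#'
#' @param ids character vector of term accessions (CURIE-style, unique)
#' @param names character vector of term labels, parallel to `ids`
#' @param parents named list mapping each term id to a character vector of
#'   parent term ids (empty for the root)
#' @param root id of the single root term; if `NULL`, the unique term with no
#'   parents is taken as root
#' @return an object of class `ontology` with elements `ids`, `names`
#'   (named character), `parents`, `children` (named lists), `root`, and
#'   `closure` (named list: reflexive-transitive ancestor sets, sorted)
#' @export
ontology <- function(ids, names = ids, parents, root = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  labels <- stats::setNames(as.character(names), ids)
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) sort(unique(as.character(p))))
  bad <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(bad) > 0) {
    stop("parent ids not present in ontology: ", paste(bad, collapse = ", "))
  }
  no_parent <- ids[vapply(parents, length, 1L) == 0L]
  if (is.null(root)) {
    if (length(no_parent) != 1L) {
      stop("missing root: expected exactly one parentless term, found ",
           length(no_parent))
    }
    root <- no_parent
  } else {
    if (!root %in% ids) stop("missing root: ", root, " not among terms")
    if (!identical(sort(no_parent), sort(root))) {
      stop("missing root: parentless terms (", paste(no_parent, collapse = ", "),
           ") do not match designated root ", root)
    }
  }

  order <- topo_order(ids, parents)  # errors on cycles
  closure <- vector("list", length(ids))
  names(closure) <- ids
  for (t in order) {
    ps <- parents[[t]]
    if (length(ps) == 0L) {
      closure[[t]] <- t
    } else {
      closure[[t]] <- sort(unique(c(t, unlist(closure[ps], use.names = FALSE))))
    }
  }

  children <- lapply(ids, function(x) character(0))
  names(children) <- ids
  for (t in ids) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  children <- lapply(children, sort)

  structure(
    list(ids = ids, names = labels, parents = parents, children = children,
         root = root, closure = closure),
    class = "ontology"
  )
}

# Kahn topological sort from root downwards; parents precede children.
# Fatal on cycles (the is-a graph must be a DAG).
topo_order <- function(ids, parents) {
  indeg <- vapply(parents, length, 1L)
  queue <- ids[indeg == 0L]
  child_map <- new.env(parent = emptyenv())
  for (t in ids) {
    for (p in parents[[t]]) {
      assign(p, c(get0(p, envir = child_map, ifnotfound = character(0)), t),
             envir = child_map)
    }
  }
  out <- character(0)
  while (length(queue) > 0L) {
    t <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, t)
    for (ch in get0(t, envir = child_map, ifnotfound = character(0))) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids)) stop("not a DAG: cycle detected in is-a edges")
  out
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, root %s (%s)\n",
              length(x$ids), x$root, unname(x$names[x$root])))
  invisible(x)
}

#' Read an OBO-format ontology
#'
#' Minimal reader for the OBO 1.2/1.4 flat-file format: `[Term]` stanzas with
#' `id`, `name`, `is_a`, `is_obsolete` and `replaced_by` tags. Trailing
#' `!`-comments on tag values are stripped. Obsolete terms are either dropped
#' or remapped onto their `replaced_by` target.
#'
#' @param path path to an OBO file
#' @param root designated root term id, or `NULL` to infer the unique
#'   parentless term
#' @param obsolete one of `"drop"` (discard obsolete terms) or `"remap"`
#'   (treat references to an obsolete term as its `replaced_by` target)
#' @return an [ontology] object
#' @export
load_ontology <- function(path, root = NULL, obsolete = c("drop", "remap")) {
  obsolete <- match.arg(obsolete)
  lines <- readLines(path, encoding = "UTF-8")
  in_term <- FALSE
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("\\s*$", "", ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NULL, name = NA_character_, is_a = character(0),
                  obsolete = FALSE, replaced_by = character(0))
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {  # other stanza type ends any open term
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !grepl(":", ln, fixed = TRUE)) next
    tag <- sub(":.*$", "", ln)
    val <- sub("^[^:]+:\\s*", "", ln)
    val <- sub("\\s*!.*$", "", val)  # strip trailing comment
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (tag == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (tag == "replaced_by") cur$replaced_by <- c(cur$replaced_by, val)
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0L) stop("no [Term] stanzas found in ", path)

  remap <- character(0)
  if (obsolete == "remap") {
    obs <- Filter(function(t) t$obsolete && length(t$replaced_by) > 0, terms)
    remap <- stats::setNames(vapply(obs, function(t) t$replaced_by[1L], ""),
                             vapply(obs, function(t) t$id, ""))
  }
  terms <- Filter(function(t) !t$obsolete, terms)
  ids <- vapply(terms, function(t) t$id, "")
  parents <- lapply(terms, function(t) {
    p <- t$is_a
    hit <- p %in% names(remap)
    p[hit] <- remap[p[hit]]
    p
  })
  names(parents) <- ids
  ontology(ids = ids,
           names = vapply(terms, function(t) t$name, ""),
           parents = parents, root = root)
}

#' Write an ontology to an OBO file
#'
#' Emits the minimal `[Term]` dialect that [load_ontology()] reads, with
#' terms in sorted id order so output bytes are deterministic.
#'
#' @param o an [ontology]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_obo <- function(o, path) {
  stopifnot(inherits(o, "ontology"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in sort(o$ids)) {
    ps <- o$parents[[t]]
    block <- c("[Term]",
               paste0("id: ", t),
               paste0("name: ", unname(o$names[t])),
               if (length(ps) > 0) paste0("is_a: ", ps),
               "")
    writeLines(block, con)
  }
  invisible(path)
}

#' Ancestors of a term
#'
#' Reflexive-transitive closure of the is-a parent relation. Every closure
#' contains the root.
#'
#' @param o an [ontology]
#' @param term a term id in `o`
#' @param include_self include `term` itself (default `TRUE`)
#' @return character vector of ancestor term ids (sorted)
#' @export
ancestors <- function(o, term, include_self = TRUE) {
  stopifnot(inherits(o, "ontology"))
  if (!term %in% o$ids) stop("unknown term: ", term)
  cl <- o$closure[[term]]
  if (!include_self) cl <- setdiff(cl, term)
  cl
}

# Union of ancestor closures over a set of terms; terms absent from the
# ontology are an error upstream, so this assumes membership.
term_set_closure <- function(o, terms) {
  if (length(terms) == 0L) return(character(0))
  sort(unique(unlist(o$closure[terms], use.names = FALSE)))
}
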