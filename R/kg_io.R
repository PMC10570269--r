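#' Knowledge-graph table input/output
#'
#' A knowledge graph is stored on disk as a directory of UTF-8 TSV files
#' (header row required) plus an OBO ontology:
#' \describe{
#'   \item{ontology.obo}{phenotype ontology}
#'   \item{diseases.tsv}{disease_id, name, classification, parent_id,
#'     gene_ids (comma separated), age_ranges (comma separated), date}
#'   \item{disease_phenotype.tsv}{disease_id, term_id, prevalence (numeric
#'     fraction or Orphanet-style frequency class name)}
#'   \item{gene_disease.tsv}{gene_id, disease_id, date}
#'   \item{gene_phenotype.tsv}{gene_id, term_id}
#'   \item{gene_gene.tsv}{gene1, gene2}
#'   \item{nondisease_genes.tsv}{gene_id}
#'   \item{flags.tsv}{gene_id, rare_variant_count}
#'   \item{expression.tsv}{gene_id then one numeric column per tissue}
#'   \item{claims.tsv}{stratum, term_id, prevalence}
#' }
#'
#' @param dir directory containing the files above
#' @param timestamp knowledge cutoff `Date` for the loaded graph
#' @param root optional designated ontology root id
#' @return a [knowledge_graph]
#' @export
load_knowledge_graph <- function(dir, timestamp = as.Date("2015-02-01"),
                                 root = NULL) {
  read_tsv <- function(name) {
    utils::read.delim(file.path(dir, name), sep = "\t", header = TRUE,
                      colClasses = "character", check.names = FALSE,
                      quote = "", fileEncoding = "UTF-8")
  }
  ont <- load_ontology(file.path(dir, "ontology.obo"), root = root)

  dtab <- read_tsv("diseases.tsv")
  ptab <- read_tsv("disease_phenotype.tsv")
  prev <- parse_prevalence(ptab$prevalence)
  split_list <- function(x) {
    if (is.na(x) || x == "") character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
  }
  diseases <- lapply(seq_len(nrow(dtab)), function(i) {
    row <- dtab[i, ]
    sel <- ptab$disease_id == row$disease_id
    disease_record(
      id = row$disease_id, name = row$name,
      classification = row$classification,
      genes = split_list(row$gene_ids),
      phenotypes = stats::setNames(prev[sel], ptab$term_id[sel]),
      ages = split_list(row$age_ranges),
      parent = if (row$parent_id == "") NA_character_ else row$parent_id,
      date = as.Date(ifelse(row$date == "", NA, row$date)))
  })

  gp <- read_tsv("gene_phenotype.tsv")
  gene_phenotype <- lapply(split(gp$term_id, gp$gene_id), function(x) sort(unique(x)))

  gd <- read_tsv("gene_disease.tsv")
  gene_disease <- data.frame(gene = gd$gene_id, disease = gd$disease_id,
                             date = as.Date(ifelse(gd$date == "", NA, gd$date)))

  gg <- read_tsv("gene_gene.tsv")
  flags <- read_tsv("flags.tsv")
  expr <- utils::read.delim(file.path(dir, "expression.tsv"), sep = "\t",
                            header = TRUE, check.names = FALSE, quote = "",
                            fileEncoding = "UTF-8")
  em <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(em) <- "double"
  rownames(em) <- expr[[1]]
  claims <- read_tsv("claims.tsv")

  knowledge_graph(
    ontology = ont, diseases = diseases, gene_phenotype = gene_phenotype,
    gene_disease = gene_disease,
    gene_gene = data.frame(a = gg$gene1, b = gg$gene2),
    nondisease_genes = read_tsv("nondisease_genes.tsv")$gene_id,
    flags = data.frame(gene = flags$gene_id,
                       count = as.numeric(flags$rare_variant_count)),
    expression = em,
    claims = data.frame(stratum = claims$stratum, term = claims$term_id,
                        prevalence = as.numeric(claims$prevalence)),
    timestamp = timestamp)
}

# Prevalence column values are either numeric fractions or Orphanet-style
# qualitative frequency classes, mapped to representative point fractions.
parse_prevalence <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  qual <- is.na(out)
  if (any(qual)) {
    mapped <- frequency_class_map[x[qual]]
    if (any(is.na(mapped))) {
      stop("unknown frequency class: ",
           paste(unique(x[qual][is.na(mapped)]), collapse = ", "))
    }
    out[qual] <- mapped
  }
  out
}

#' Write a knowledge graph as its TSV/OBO directory
#'
#' Inverse of [load_knowledge_graph()]. Rows are emitted in sorted order so
#' a graph generated from a fixed seed serializes to identical bytes.
#'
#' @param kg a [knowledge_graph]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_knowledge_graph <- function(kg, dir) {
  stopifnot(inherits(kg, "knowledge_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, name) {
    df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
    con <- file(file.path(dir, name), open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(df), collapse = "\t"), con)
    if (nrow(df) > 0) {
      writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
    }
    invisible(NULL)
  }
  write_obo(kg$ontology, file.path(dir, "ontology.obo"))

  ds <- kg$diseases
  write_tsv(data.frame(
    disease_id = names(ds),
    name = vapply(ds, function(d) d$name, ""),
    classification = vapply(ds, function(d) d$classification, ""),
    parent_id = vapply(ds, function(d) ifelse(is.na(d$parent), "", d$parent), ""),
    gene_ids = vapply(ds, function(d) paste(d$genes, collapse = ","), ""),
    age_ranges = vapply(ds, function(d) paste(d$ages, collapse = ","), ""),
    date = vapply(ds, function(d) ifelse(is.na(d$date), "", format(d$date)), "")
  ), "diseases.tsv")

  dp <- do.call(rbind, c(list(
    data.frame(disease_id = character(0), term_id = character(0),
               prevalence = character(0))),
    lapply(ds, function(d) {
      if (length(d$phenotypes) == 0) return(NULL)
      data.frame(disease_id = d$id, term_id = names(d$phenotypes),
                 prevalence = format_fraction(d$phenotypes))
    })))
  write_tsv(dp, "disease_phenotype.tsv")

  gd <- kg$gene_disease
  write_tsv(data.frame(gene_id = gd$gene, disease_id = gd$disease,
                       date = format(gd$date)), "gene_disease.tsv")

  gp <- kg$gene_phenotype
  gp_df <- data.frame(
    gene_id = rep(names(gp), vapply(gp, length, 1L)),
    term_id = unlist(gp, use.names = FALSE))
  if (length(gp) == 0) gp_df <- data.frame(gene_id = character(0),
                                           term_id = character(0))
  write_tsv(gp_df, "gene_phenotype.tsv")

  write_tsv(data.frame(gene1 = kg$gene_gene$a, gene2 = kg$gene_gene$b),
            "gene_gene.tsv")
  write_tsv(data.frame(gene_id = kg$nondisease_genes), "nondisease_genes.tsv")
  write_tsv(data.frame(gene_id = kg$flags$gene,
                       rare_variant_count = format_fraction(kg$flags$count)),
            "flags.tsv")
  write_tsv(data.frame(stratum = kg$claims$stratum, term_id = kg$claims$term,
                       prevalence = format_fraction(kg$claims$prevalence)),
            "claims.tsv")

  em <- kg$expression
  em <- em[order(rownames(em)), , drop = FALSE]
  con <- file(file.path(dir, "expression.tsv"), open = "wb")
  writeLines(paste(c("gene_id", colnames(em)), collapse = "\t"), con)
  if (nrow(em) > 0) {
    writeLines(paste(rownames(em),
                     apply(em, 1, function(r) paste(format_fraction(r), collapse = "\t")),
                     sep = "\t"), con)
  }
  close(con)
  invisible(dir)
}

# Locale-independent, trailing-zero-free numeric formatting for TSV output.
format_fraction <- function(x) {
  out <- formatC(x, format = "fg", digits = 15)
  sub("^\\s+", "", out)
}
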