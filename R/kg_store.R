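#' Disease records
#'
#' A disease record holds the knowledge-base view of one rare disease: its
#' causal genes, phenotype annotations with per-term prevalence
#' P(term | disease), typical age-of-onset categories, its Orphanet-style
#' classification, an optional parent disease (for subtypes) and the calendar
#' date the disease was first described.
#'
#' @param id disease accession (ORPHA-style string)
#' @param name disease label
#' @param classification one of `"disorder"`, `"category"`,
#'   `"clinical_subtype"`, `"etiological_subtype"`,
#'   `"histopathological_subtype"`
#' @param genes character vector of causal gene ids (may be empty before
#'   subtype imputation)
#' @param phenotypes named numeric vector: term id -> prevalence in \[0, 1\]
#' @param ages character vector of [age_categories()] values
#' @param parent parent disease id or `NA`
#' @param date discovery `Date` (or `NA` if unknown; novelty classification
#'   then fails loudly)
#' @return an object of class `disease_record`
#' @export
disease_record <- function(id, name = id, classification = "disorder",
                           genes = character(0),
                           phenotypes = stats::setNames(numeric(0), character(0)),
                           ages = "adult", parent = NA_character_,
                           date = as.Date(NA)) {
  classification <- match.arg(classification, c(
    "disorder", "category", "clinical_subtype", "etiological_subtype",
    "histopathological_subtype"))
  phenotypes <- unlist(phenotypes)
  if (length(phenotypes) > 0 &&
      (any(is.na(phenotypes)) || any(phenotypes < 0) || any(phenotypes > 1))) {
    stop("disease ", id, ": phenotype prevalences must lie in [0, 1]")
  }
  bad_age <- setdiff(ages, age_categories())
  if (length(bad_age) > 0) stop("disease ", id, ": unknown age categories ",
                                paste(bad_age, collapse = ", "))
  structure(
    list(id = as.character(id), name = as.character(name),
         classification = classification,
         genes = sort(unique(as.character(genes))),
         phenotypes = phenotypes, ages = sort(unique(as.character(ages))),
         parent = as.character(parent), date = as.Date(date)),
    class = "disease_record"
  )
}

#' Age categories and claims strata
#'
#' Patient ages are modelled as five categories matching the age strata of
#' the claims-derived phenotype prevalence table: infants 0-1 years, children
#' 2-11, adolescents 12-18, adults 19-64, seniors 65+.
#'
#' @return character vector of the five category names, in age order
#' @export
age_categories <- function() {
  c("infant", "child", "adolescent", "adult", "senior")
}

#' Discretize a phenotype prevalence into a qualitative bucket
#'
#' Prevalence P(term | disease) is bucketed as: 1 -> `obligate`,
#' \[0.80, 0.99\] -> `strong`, \[0.01, 0.29\] -> `weak`, 0 -> `excluded`,
#' anything else in (0, 1) -> `moderate`. The moderate band is usable for
#' phenotype-overlap matching but never drives obligate/excluded distractor
#' logic.
#'
#' @param p numeric vector of prevalences in \[0, 1\]
#' @return character vector of bucket labels
#' @export
bucket_prevalence <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("prevalence must lie in [0, 1]")
  }
  out <- rep("moderate", length(p))
  out[p == 1] <- "obligate"
  out[p >= 0.80 & p <= 0.99] <- "strong"
  out[p >= 0.01 & p <= 0.29] <- "weak"
  out[p == 0] <- "excluded"
  out
}

# Orphanet-style qualitative frequency classes -> representative point
# prevalences, applied at load time so Bernoulli sampling has a number.
frequency_class_map <- c(
  "Obligate"      = 1.0,
  "Very frequent" = 0.895,
  "Frequent"      = 0.545,
  "Occasional"    = 0.17,
  "Very rare"     = 0.025,
  "Excluded"      = 0.0
)

#' Assemble a knowledge graph
#'
#' The knowledge graph bundles the phenotype ontology with the disease
#' knowledge base and the auxiliary gene resources the distractor modules
#' draw on, plus a timestamp that defines which gene-disease edges count as
#' "known" for novelty classification and for prioritization.
#'
#' @param ontology an [ontology]
#' @param diseases list of [disease_record]s (names taken from record ids)
#' @param gene_phenotype named list: gene id -> character vector of term ids
#' @param gene_disease data.frame with columns `gene`, `disease`, `date`
#'   (the dated causal gene-disease association edges)
#' @param gene_gene data.frame with columns `a`, `b` (undirected interaction
#'   edges, no self-loops)
#' @param nondisease_genes character vector of genes not causally associated
#'   with any disease
#' @param flags data.frame with columns `gene`, `count` (frequently-mutated
#'   genes and their rare functional variant counts)
#' @param expression numeric matrix, genes x tissues (rownames = gene ids)
#' @param claims data.frame with columns `stratum`, `term`, `prevalence`
#'   (age-stratified population phenotype prevalences)
#' @param timestamp `Date` at which the graph's knowledge is frozen
#' @return an object of class `knowledge_graph`
#' @export
knowledge_graph <- function(ontology, diseases, gene_phenotype = list(),
                            gene_disease = data.frame(gene = character(0),
                                                      disease = character(0),
                                                      date = as.Date(character(0))),
                            gene_gene = data.frame(a = character(0),
                                                   b = character(0)),
                            nondisease_genes = character(0),
                            flags = data.frame(gene = character(0),
                                               count = numeric(0)),
                            expression = matrix(numeric(0), 0, 0),
                            claims = data.frame(stratum = character(0),
                                                term = character(0),
                                                prevalence = numeric(0)),
                            timestamp = as.Date("2015-02-01")) {
  stopifnot(inherits(ontology, "ontology"))
  if (is.null(names(diseases)) || any(names(diseases) == "")) {
    names(diseases) <- vapply(diseases, function(d) d$id, "")
  }
  diseases <- diseases[sort(names(diseases))]
  for (d in diseases) {
    bad <- setdiff(names(d$phenotypes), ontology$ids)
    if (length(bad) > 0) {
      stop("disease ", d$id, " annotated to unknown terms: ",
           paste(bad, collapse = ", "))
    }
  }
  gene_phenotype <- lapply(gene_phenotype, function(ts) sort(unique(ts)))
  gene_phenotype <- gene_phenotype[sort(names(gene_phenotype))]
  bad <- setdiff(unlist(lapply(gene_phenotype, identity), use.names = FALSE),
                 ontology$ids)
  if (length(bad) > 0) {
    stop("gene-phenotype annotations reference unknown terms: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(gene_gene) > 0 && any(gene_gene$a == gene_gene$b)) {
    stop("gene-gene interaction edges must not contain self-loops")
  }
  if (nrow(claims) > 0 &&
      (any(claims$prevalence < 0) || any(claims$prevalence > 1))) {
    stop("claims prevalences must lie in [0, 1]")
  }
  gene_disease$date <- as.Date(gene_disease$date)
  genes <- sort(unique(c(
    unlist(lapply(diseases, function(d) d$genes), use.names = FALSE),
    gene_disease$gene, names(gene_phenotype), gene_gene$a, gene_gene$b,
    nondisease_genes, flags$gene, rownames(expression))))
  structure(
    list(ontology = ontology, diseases = diseases,
         gene_phenotype = gene_phenotype, gene_disease = gene_disease,
         gene_gene = gene_gene, nondisease_genes = sort(nondisease_genes),
         flags = flags, expression = expression, claims = claims,
         timestamp = as.Date(timestamp), genes = genes),
    class = "knowledge_graph"
  )
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf(
    "<knowledge_graph> %d diseases, %d genes, %d terms; timestamp %s\n",
    length(x$diseases), length(x$genes), length(x$ontology$ids),
    format(x$timestamp)))
  invisible(x)
}

#' Impute causal genes / phenotypes for disease subtypes
#'
#' Clinical, etiological, and histopathological subtypes missing exactly one
#' of \{causal genes, phenotype annotations\} inherit the missing element
#' from their parent disease (e.g. a "type A" subtype with phenotypes but no
#' gene gains the parent's gene). Subtypes missing both elements, or whose
#' parent also lacks the needed element, are left unfilled and recorded in
#' the `"unimputed"` attribute of the result. Inherited causal genes also
#' inherit the parent's gene-disease edge dates, since the association was
#' discovered through the parent disease. The operation is idempotent.
#'
#' @param kg a [knowledge_graph]
#' @return the knowledge graph with subtype records filled in
#' @export
impute_subtype_annotations <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  subtype_classes <- c("clinical_subtype", "etiological_subtype",
                       "histopathological_subtype")
  unimputed <- character(0)
  gd <- kg$gene_disease
  for (id in names(kg$diseases)) {
    d <- kg$diseases[[id]]
    if (!d$classification %in% subtype_classes) next
    need_genes <- length(d$genes) == 0L
    need_phen <- length(d$phenotypes) == 0L
    if (!need_genes && !need_phen) next
    if (need_genes && need_phen) {
      unimputed <- c(unimputed, id)
      next
    }
    if (is.na(d$parent) || !d$parent %in% names(kg$diseases)) {
      unimputed <- c(unimputed, id)
      next
    }
    parent <- kg$diseases[[d$parent]]
    if (need_genes) {
      if (length(parent$genes) == 0L) {
        unimputed <- c(unimputed, id)
        next
      }
      d$genes <- parent$genes
      pe <- gd[gd$disease == parent$id & gd$gene %in% parent$genes, , drop = FALSE]
      if (nrow(pe) > 0) {
        add <- data.frame(gene = pe$gene, disease = id, date = pe$date)
        have <- paste(gd$gene, gd$disease)
        add <- add[!paste(add$gene, add$disease) %in% have, , drop = FALSE]
        gd <- rbind(gd, add)
      }
    } else {
      if (length(parent$phenotypes) == 0L) {
        unimputed <- c(unimputed, id)
        next
      }
      d$phenotypes <- parent$phenotypes
    }
    kg$diseases[[id]] <- d
  }
  if (length(unimputed) > 0) {
    message("subtype imputation: ", length(unimputed),
            " record(s) left unfilled: ", paste(unimputed, collapse = ", "))
  }
  kg$gene_disease <- gd
  attr(kg, "unimputed") <- unimputed
  kg
}

#' Select diseases eligible for patient simulation
#'
#' Keeps diseases that are not bare classification categories, have at least
#' one phenotype annotation and at least one causal gene. Run after
#' [impute_subtype_annotations()]. Output order is deterministic (sorted by
#' disease id), regardless of input order.
#'
#' @param kg a [knowledge_graph]
#' @return list of [disease_record]s, sorted by id
#' @export
select_simulatable_diseases <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  keep <- Filter(function(d) {
    d$classification != "category" &&
      length(d$phenotypes) >= 1L && length(d$genes) >= 1L
  }, kg$diseases)
  keep[sort(names(keep))]
}

#' Novelty categories for causal gene-disease pairs
#'
#' @return the five category labels, ordered from most to least prior
#'   knowledge
#' @export
novelty_categories <- function() {
  c("known_disease_known_gene", "known_disease_new_gene_link",
    "known_disease_undiscovered_gene", "novel_disease_known_gene",
    "novel_disease_undiscovered_gene")
}

#' Classify the novelty of a causal gene-disease pair
#'
#' Using only knowledge dated on or before the graph's timestamp: if the
#' gene-disease edge itself is known the pair is
#' `known_disease_known_gene`; a known disease caused by a gene that causes
#' some other known disease is `known_disease_new_gene_link`; a known
#' disease caused by a gene with no disease association is
#' `known_disease_undiscovered_gene`; the two `novel_disease_*` categories
#' mirror these when the disease itself postdates the timestamp. The five
#' categories partition all pairs, and moving the timestamp later never
#' demotes a `known_disease_known_gene` pair.
#'
#' @param kg a [knowledge_graph] (full, undated knowledge base with a
#'   timestamp)
#' @param gene causal gene id
#' @param disease disease id
#' @return one of [novelty_categories()]
#' @export
classify_novelty <- function(kg, gene, disease) {
  stopifnot(inherits(kg, "knowledge_graph"))
  d <- kg$diseases[[disease]]
  if (is.null(d)) stop("unknown disease: ", disease)
  if (is.na(d$date)) stop("disease ", disease, " has no discovery date")
  gd <- kg$gene_disease
  pair <- gd[gd$gene == gene & gd$disease == disease, , drop = FALSE]
  if (nrow(pair) == 0L) stop("no gene-disease edge for (", gene, ", ",
                             disease, ")")
  if (any(is.na(pair$date))) stop("gene-disease edge (", gene, ", ", disease,
                                  ") has no discovery date")
  ts <- kg$timestamp
  others <- gd[gd$gene == gene & !is.na(gd$date) & gd$date <= ts, , drop = FALSE]
  if (anyNA(gd$date[gd$gene == gene])) {
    stop("gene ", gene, " has gene-disease edges without discovery dates")
  }
  disease_known <- d$date <= ts
  pair_known <- any(pair$date <= ts)
  gene_known <- nrow(others) > 0L
  if (disease_known && pair_known) return("known_disease_known_gene")
  if (disease_known && gene_known) return("known_disease_new_gene_link")
  if (disease_known) return("known_disease_undiscovered_gene")
  if (gene_known) return("novel_disease_known_gene")
  "novel_disease_undiscovered_gene"
}

#' Restrict a knowledge graph to knowledge at a date
#'
#' Returns a view keeping only gene-disease edges dated on or before `date`
#' and diseases discovered on or before `date`. Undated resources
#' (gene-phenotype annotations, interactions, expression, claims) are kept
#' as-is; the dated edges are what define novelty.
#'
#' @param kg a [knowledge_graph]
#' @param date cutoff `Date`; defaults to the graph's own timestamp
#' @return a [knowledge_graph] restricted to the cutoff
#' @export
kg_as_of <- function(kg, date = kg$timestamp) {
  stopifnot(inherits(kg, "knowledge_graph"))
  date <- as.Date(date)
  gd <- kg$gene_disease
  gd <- gd[!is.na(gd$date) & gd$date <= date, , drop = FALSE]
  keep <- vapply(kg$diseases, function(d) !is.na(d$date) && d$date <= date,
                 TRUE)
  kg$diseases <- kg$diseases[keep]
  gd <- gd[gd$disease %in% names(kg$diseases), , drop = FALSE]
  for (id in names(kg$diseases)) {
    d <- kg$diseases[[id]]
    d$genes <- sort(unique(gd$gene[gd$disease == id]))
    kg$diseases[[id]] <- d
  }
  kg$gene_disease <- gd
  kg$timestamp <- date
  kg
}
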