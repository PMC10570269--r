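#' Simulated patient container
#'
#' A simulated patient is an age category, disjoint sets of positive and
#' negative phenotype terms, a causal disease/gene pair, and an ordered
#' candidate gene list in which every gene carries a provenance label
#' (`"causal"`, one of `"module_1"` .. `"module_6"`, or
#' `"random_backfill"`).
#'
#' @param id patient identifier
#' @param disease true disease id
#' @param gene true causal gene id
#' @param age one of [age_categories()]
#' @param positives,negatives character vectors of phenotype term ids
#' @param candidates data.frame with columns `gene`, `provenance`
#' @param novelty one of [novelty_categories()], or `NA` before
#'   classification
#' @return an object of class `simulated_patient`
#' @export
simulated_patient <- function(id, disease, gene, age, positives, negatives,
                              candidates = data.frame(
                                gene = gene, provenance = "causal",
                                stringsAsFactors = FALSE),
                              novelty = NA_character_) {
  if (length(intersect(positives, negatives)) > 0) {
    stop("positive and negative phenotype sets must be disjoint")
  }
  if (!gene %in% candidates$gene[candidates$provenance == "causal"]) {
    stop("causal gene must appear among candidates with provenance 'causal'")
  }
  structure(list(id = as.character(id), disease = disease, gene = gene,
                 age = age, positives = sort(unique(positives)),
                 negatives = sort(unique(negatives)),
                 candidates = candidates, novelty = novelty),
            class = "simulated_patient")
}

#' @export
print.simulated_patient <- function(x, ...) {
  cat(sprintf(
    "<simulated_patient> %s: disease %s, causal gene %s (%s), age %s\n  %d positive / %d negative terms, %d candidate genes\n",
    x$id, x$disease, x$gene,
    ifelse(is.na(x$novelty), "unclassified", x$novelty), x$age,
    length(x$positives), length(x$negatives), nrow(x$candidates)))
  invisible(x)
}

#' Initialize a simulated patient from a disease record
#'
#' Draws the causal gene uniformly from the disease's causal genes and the
#' age category uniformly from the disease's age-of-onset ranges. Each
#' annotated phenotype term lands in the positive set with probability
#' P(term | disease) and in the negative set otherwise, so at this stage the
#' union of the two sets is exactly the disease's annotated term set. The
#' candidate list starts as the causal gene alone.
#'
#' @param d a simulatable [disease_record] (>= 1 phenotype, gene, age range)
#' @param kg a [knowledge_graph] (terms are checked against its ontology)
#' @param id patient identifier
#' @return a [simulated_patient]
#' @export
init_patient <- function(d, kg, id = paste0(d$id, "_p1")) {
  stopifnot(inherits(d, "disease_record"))
  if (length(d$phenotypes) == 0L) {
    stop("disease ", d$id, " has no phenotype annotations")
  }
  if (length(d$genes) == 0L) stop("disease ", d$id, " has no causal gene")
  if (length(d$ages) == 0L) stop("disease ", d$id, " has no age ranges")
  gene <- if (length(d$genes) == 1L) d$genes else
    d$genes[sample.int(length(d$genes), 1L)]
  age <- if (length(d$ages) == 1L) d$ages else
    d$ages[sample.int(length(d$ages), 1L)]
  pos <- stats::runif(length(d$phenotypes)) < d$phenotypes
  simulated_patient(id = id, disease = d$id, gene = gene, age = age,
                    positives = names(d$phenotypes)[pos],
                    negatives = names(d$phenotypes)[!pos])
}
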