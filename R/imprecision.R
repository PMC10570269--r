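#' Imprecision parameters
#'
#' Probabilities and rates for the three operators that degrade a freshly
#' initialized patient the way real diagnostic workups do: dropout
#' (partially observed symptoms), obfuscation (specific terms recorded as
#' their less precise parents), and noise (unrelated comorbidities sampled
#' by their prevalence in an age-matched claims population). Dropout and
#' obfuscation probabilities default to the values used throughout this
#' package's cohort simulations (0.7 positive / 0.2 negative dropout, 0.15
#' obfuscation for both sets). Noise adds `1 + Poisson(lambda)` terms per
#' set.
#'
#' @param p_pos_dropout,p_neg_dropout per-term removal probabilities
#' @param p_pos_obfuscate,p_neg_obfuscate per-term parent-replacement
#'   probabilities
#' @param lambda_noise_pos,lambda_noise_neg Poisson rates for the number of
#'   extra noise terms beyond the first
#' @return an object of class `imprecision_params`
#' @export
imprecision_params <- function(p_pos_dropout = 0.7, p_neg_dropout = 0.2,
                               p_pos_obfuscate = 0.15,
                               p_neg_obfuscate = 0.15,
                               lambda_noise_pos = 2, lambda_noise_neg = 1) {
  ps <- c(p_pos_dropout, p_neg_dropout, p_pos_obfuscate, p_neg_obfuscate)
  if (any(ps < 0) || any(ps > 1)) stop("probabilities must lie in [0, 1]")
  if (lambda_noise_pos < 0 || lambda_noise_neg < 0) {
    stop("noise rates must be >= 0")
  }
  structure(list(p_pos_dropout = p_pos_dropout, p_neg_dropout = p_neg_dropout,
                 p_pos_obfuscate = p_pos_obfuscate,
                 p_neg_obfuscate = p_neg_obfuscate,
                 lambda_noise_pos = lambda_noise_pos,
                 lambda_noise_neg = lambda_noise_neg),
            class = "imprecision_params")
}

#' Phenotype dropout
#'
#' Removes each positive term independently with probability
#' `p_pos_dropout` and each negative term with `p_neg_dropout`. Removal is
#' unconditional: a patient may lose every initial disease phenotype.
#'
#' @param patient a [simulated_patient]
#' @param params an [imprecision_params]
#' @return the patient with thinned term sets
#' @export
apply_dropout <- function(patient, params = imprecision_params()) {
  keep_p <- stats::runif(length(patient$positives)) >= params$p_pos_dropout
  keep_n <- stats::runif(length(patient$negatives)) >= params$p_neg_dropout
  patient$positives <- patient$positives[keep_p]
  patient$negatives <- patient$negatives[keep_n]
  patient
}

#' Phenotype obfuscation
#'
#' Independently replaces each term, with its set's probability, by one of
#' its parent terms chosen uniformly — recording "long fingers" where
#' "arachnodactyly" was observed. The ontology root is never used as a
#' replacement: a term whose only parent is the root is left unchanged. If a
#' replacement collides with a term already present in either set, the two
#' deduplicate (term sets, not multisets); a replacement already asserted
#' absent stays out of the positive set.
#'
#' @param patient a [simulated_patient]
#' @param ontology an [ontology] containing all patient terms
#' @param params an [imprecision_params]
#' @return the patient with obfuscated term sets
#' @export
apply_obfuscation <- function(patient, ontology,
                              params = imprecision_params()) {
  obfuscate_one <- function(term, p) {
    if (stats::runif(1L) >= p) return(term)
    parents <- setdiff(ontology$parents[[term]], ontology$root)
    if (length(parents) == 0L) return(term)
    if (length(parents) == 1L) parents else
      parents[sample.int(length(parents), 1L)]
  }
  for (t in patient$positives) {
    if (!t %in% ontology$ids) stop("unknown term: ", t)
  }
  for (t in patient$negatives) {
    if (!t %in% ontology$ids) stop("unknown term: ", t)
  }
  pos <- vapply(patient$positives, obfuscate_one, "",
                p = params$p_pos_obfuscate)
  neg <- vapply(patient$negatives, obfuscate_one, "",
                p = params$p_neg_obfuscate)
  pos <- sort(unique(unname(pos)))
  neg <- sort(unique(unname(neg)))
  # a term asserted absent (or still present as negative) wins collisions
  patient$positives <- setdiff(pos, neg)
  patient$negatives <- neg
  patient
}

#' Claims stratum for an age category
#'
#' The five patient age categories map one-to-one onto the age strata of the
#' claims prevalence table.
#'
#' @param age one of [age_categories()]
#' @return the stratum key (identical to the category name)
#' @export
age_stratum <- function(age) {
  if (!age %in% age_categories()) stop("unknown age category: ", age)
  age
}

#' Phenotype noise
#'
#' Adds unrelated symptoms and comorbidities from an age-matched
#' population: `1 + Poisson(lambda_noise_pos)` new positive terms drawn
#' without replacement with probability proportional to their prevalence in
#' the patient's claims stratum, and `1 + Poisson(lambda_noise_neg)` new
#' negative terms drawn uniformly from the same stratum's vocabulary. Terms
#' already present in either set are never drawn. If the stratum vocabulary
#' cannot cover a draw, all remaining terms are taken and a warning is
#' raised.
#'
#' @param patient a [simulated_patient]
#' @param claims data.frame with columns `stratum`, `term`, `prevalence`
#' @param params an [imprecision_params]
#' @return the patient with noise terms added
#' @export
apply_noise <- function(patient, claims, params = imprecision_params()) {
  stratum <- age_stratum(patient$age)
  tab <- claims[claims$stratum == stratum, , drop = FALSE]
  if (nrow(tab) == 0L) stop("claims table does not cover stratum ", stratum)

  draw <- function(pool, weights, n) {
    if (n >= length(pool)) {
      if (n > length(pool)) {
        warning("stratum ", stratum, " vocabulary smaller than requested ",
                "noise draw; taking all ", length(pool), " available terms")
      }
      return(pool)
    }
    if (is.null(weights)) pool[sample.int(length(pool), n)] else
      sample_without_replacement(pool, weights, n)
  }

  n_pos <- 1L + stats::rpois(1L, params$lambda_noise_pos)
  avail <- !(tab$term %in% c(patient$positives, patient$negatives))
  new_pos <- draw(tab$term[avail], tab$prevalence[avail], n_pos)
  patient$positives <- sort(unique(c(patient$positives, new_pos)))

  n_neg <- 1L + stats::rpois(1L, params$lambda_noise_neg)
  avail <- !(tab$term %in% c(patient$positives, patient$negatives))
  new_neg <- draw(tab$term[avail], NULL, n_neg)
  patient$negatives <- sort(unique(c(patient$negatives, new_neg)))
  patient
}

# Sequential weighted sampling without replacement (weights need not sum
# to 1; zero-weight items are never drawn).
sample_without_replacement <- function(pool, weights, n) {
  out <- character(0)
  idx <- seq_along(pool)
  for (i in seq_len(n)) {
    w <- weights[idx]
    if (sum(w) <= 0) break
    pick <- idx[sample.int(length(idx), 1L, prob = w)]
    out <- c(out, pool[pick])
    idx <- setdiff(idx, pick)
    if (length(idx) == 0L) break
  }
  out
}
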