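#' Distractor module parameters
#'
#' The candidate gene list of a simulated patient holds the causal gene plus
#' `1 + N_G` plausible-but-noncausal genes, `N_G ~ Poisson(lambda_genes)`.
#' Each noncausal slot is assigned to one of six distractor modules by a
#' categorical draw over `weights`:
#' \enumerate{
#'   \item phenotypically-similar disease genes
#'   \item phenotypically-distinct disease genes
#'   \item insufficiently explanatory non-disease genes
#'   \item non-disease genes with incidental phenotypes
#'   \item similarly expressed genes
#'   \item common false-positive (frequently mutated) genes
#' }
#' Modules 1, 3 and 4 also add phenotype terms; every such "add some" step
#' adds `1 + Poisson(lambda_phen)` terms, truncated to availability.
#'
#' @param weights module probabilities, summing to 1 (defaults 0.33, 0.42,
#'   0.05, 0.09, 0.08, 0.03)
#' @param lambda_genes Poisson rate for the noncausal gene budget (default
#'   12, giving a mean candidate list of 14 genes)
#' @param lambda_phen Poisson rate for each phenotype side-effect budget
#' @param top_k size of the expression-similarity neighbourhood (module 5)
#' @param gene_only suppress all phenotype side-effects (ablation)
#' @return an object of class `distractor_params`
#' @export
distractor_params <- function(weights = c(0.33, 0.42, 0.05, 0.09, 0.08, 0.03),
                              lambda_genes = 12, lambda_phen = 1,
                              top_k = 100, gene_only = FALSE) {
  if (length(weights) != 6L) stop("weights must have length 6")
  if (abs(sum(weights) - 1) > 1e-9) stop("module weights must sum to 1")
  if (any(weights < 0)) stop("module weights must be >= 0")
  if (lambda_genes < 0 || lambda_phen < 0) stop("rates must be >= 0")
  if (top_k < 1) stop("top_k must be >= 1")
  structure(list(weights = weights, lambda_genes = lambda_genes,
                 lambda_phen = lambda_phen, top_k = as.integer(top_k),
                 gene_only = isTRUE(gene_only)),
            class = "distractor_params")
}

#' Sample the noncausal gene budget and module assignment
#'
#' @param params a [distractor_params]
#' @return list with `n_noncausal` (`1 + Poisson(lambda_genes)`) and
#'   `modules`, an integer vector assigning one module to each slot
#' @export
sample_budgets <- function(params = distractor_params()) {
  n <- 1L + stats::rpois(1L, params$lambda_genes)
  list(n_noncausal = n,
       modules = sample.int(6L, n, replace = TRUE, prob = params$weights))
}

#' Precompute per-disease distractor candidate pools
#'
#' Enumerates, once per knowledge graph, everything the six modules need per
#' true disease: eligible phenotypically-similar (disease, gene) pairs,
#' phenotypically disjoint disease genes, qualifying non-disease genes, the
#' min-max normalized expression matrix, and the gene -> diseases map.
#' Phenotype overlap between diseases is computed on raw annotated term
#' sets with positive prevalence (no ancestor expansion).
#'
#' @param kg a [knowledge_graph]
#' @return an opaque context object consumed by the distractor samplers
#' @export
build_distractor_context <- function(kg) {
  sims <- select_simulatable_diseases(kg)
  all_d <- kg$diseases
  term_set <- lapply(all_d, function(d) names(d$phenotypes)[d$phenotypes > 0])
  buckets <- lapply(all_d, function(d) {
    stats::setNames(bucket_prevalence(d$phenotypes), names(d$phenotypes))
  })
  gene2dis <- list()
  for (id in names(all_d)) {
    for (g in all_d[[id]]$genes) gene2dis[[g]] <- c(gene2dis[[g]], id)
  }
  disease_genes <- sort(names(gene2dis))

  gp_sets <- kg$gene_phenotype
  nd_annot <- gp_sets[intersect(kg$nondisease_genes, names(gp_sets))]
  nd_annot <- nd_annot[vapply(nd_annot, length, 1L) > 0L]

  m1_pairs <- m2_genes <- m3_genes <- m4_genes <- m5_excluded <-
    stats::setNames(vector("list", length(sims)), names(sims))
  for (id in names(sims)) {
    ts1 <- term_set[[id]]
    own <- all_d[[id]]$genes
    # module 1: eligible distractor diseases with overlapping phenotypes
    pairs <- list()
    for (id2 in names(sims)) {
      if (id2 == id) next
      ov <- intersect(ts1, term_set[[id2]])
      if (length(ov) == 0L) next
      b2 <- buckets[[id2]]
      # eligible when the distractor can be made definitively noncausal:
      # it has an obligate term, or an excluded term, or at least one weak
      # overlapping term (then only weak overlap terms are ever added, so
      # every added overlap term is weak)
      eligible <- any(b2 == "obligate") || any(b2 == "excluded") ||
        any(b2[ov] == "weak")
      if (!eligible) next
      genes <- setdiff(all_d[[id2]]$genes, own)
      if (length(genes) > 0L) {
        pairs[[length(pairs) + 1L]] <- data.frame(disease = id2, gene = genes)
      }
    }
    m1_pairs[[id]] <- if (length(pairs) > 0) do.call(rbind, pairs) else
      data.frame(disease = character(0), gene = character(0))
    # module 2: disease genes all of whose diseases are disjoint from ts1
    m2_genes[[id]] <- setdiff(Filter(function(g) {
      all(vapply(gene2dis[[g]],
                 function(d2) length(intersect(ts1, term_set[[d2]])) == 0L,
                 TRUE))
    }, disease_genes), own)
    # module 3: non-disease genes annotated to a nonempty strict subset of
    # the disease's weak terms
    weak <- names(buckets[[id]])[buckets[[id]] == "weak"]
    m3_genes[[id]] <- names(Filter(function(ts) {
      length(ts) > 0L && all(ts %in% weak) && length(ts) < length(weak)
    }, nd_annot))
    # module 4: non-disease genes annotated only to non-overlapping terms
    m4_genes[[id]] <- names(Filter(function(ts) {
      length(ts) > 0L && length(intersect(ts, ts1)) == 0L
    }, nd_annot))
    # module 5 exclusions: disease genes with phenotypic overlap
    m5_excluded[[id]] <- sort(unique(c(own, Filter(function(g) {
      any(vapply(gene2dis[[g]],
                 function(d2) length(intersect(ts1, term_set[[d2]])) > 0L,
                 TRUE))
    }, disease_genes))))
  }

  expr <- kg$expression
  norm <- expr
  if (nrow(expr) > 0) {
    rng <- apply(expr, 2, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    norm <- sweep(sweep(expr, 2, rng[1, ], "-"), 2, span, "/")
  }
  row_norms <- sqrt(rowSums(norm ^ 2))

  list(kg = kg, term_set = term_set, buckets = buckets, gene2dis = gene2dis,
       m1_pairs = m1_pairs, m2_genes = m2_genes, m3_genes = m3_genes,
       m4_genes = m4_genes, m5_excluded = m5_excluded,
       norm_expr = norm, row_norms = row_norms,
       m5_cache = new.env(parent = emptyenv()))
}

# 1 + Poisson(lambda) draws without replacement from `pool`, truncated.
draw_some <- function(pool, lambda) {
  n <- 1L + stats::rpois(1L, lambda)
  if (length(pool) == 0L) return(character(0))
  if (n >= length(pool)) return(pool)
  pool[sample.int(length(pool), n)]
}

# Apply the positive/negative additions of a distractor result to a
# patient, honouring the collision rules: a term already asserted negative
# is never moved to positive, and vice versa; sets stay deduplicated.
apply_side_effects <- function(patient, res) {
  add_pos <- setdiff(res$add_pos, patient$negatives)
  patient$positives <- sort(unique(c(patient$positives, add_pos)))
  add_neg <- setdiff(res$add_neg, patient$positives)
  patient$negatives <- sort(unique(c(patient$negatives, add_neg)))
  patient
}

#' Distractor module 1: phenotypically-similar disease genes
#'
#' Samples a gene causing a distractor disease whose annotated phenotypes
#' overlap the true disease's. A distractor disease is eligible if it has at
#' least one obligate term, or at least one excluded term, or all its
#' overlapping terms are weak (prevalence 1-29%). The overlapping terms join
#' the patient's positives; to guarantee the gene is noncausal, some of the
#' distractor's excluded (prevalence 0) terms join the positives and some of
#' its obligate (prevalence 1) terms join the negatives. A distractor with
#' neither obligate nor excluded terms is eligible only through its weak
#' overlapping terms: then only the weak overlap terms are added to the
#' positives (so every added overlap term is weak) and some strong
#' non-overlapping terms join the negatives instead.
#'
#' @param patient a [simulated_patient]
#' @param ctx context from [build_distractor_context()]
#' @param params a [distractor_params]
#' @param exclude genes that may not be returned (existing candidates)
#' @return a distractor result (list with `gene`, `module`, `add_pos`,
#'   `add_neg`, `detail`) or `NULL` when no candidate exists
#' @export
phenotypically_similar_distractor <- function(patient, ctx,
                                              params = distractor_params(),
                                              exclude = character(0)) {
  pool <- ctx$m1_pairs[[patient$disease]]
  pool <- pool[!pool$gene %in% exclude, , drop = FALSE]
  if (nrow(pool) == 0L) return(NULL)
  pick <- pool[sample.int(nrow(pool), 1L), ]
  d2 <- pick$disease
  b2 <- ctx$buckets[[d2]]
  overlap <- intersect(ctx$term_set[[patient$disease]], ctx$term_set[[d2]])
  obligate <- names(b2)[b2 == "obligate"]
  excluded <- names(b2)[b2 == "excluded"]
  lam <- params$lambda_phen
  add_neg <- character(0)
  via_all_weak <- length(obligate) == 0L && length(excluded) == 0L
  add_pos <- if (via_all_weak) overlap[b2[overlap] == "weak"] else overlap
  detail <- list(distractor_disease = d2, overlap = add_pos,
                 excluded_to_pos = character(0),
                 obligate_to_neg = character(0),
                 strong_to_neg = character(0))
  if (!via_all_weak) {
    if (length(excluded) > 0L) {
      detail$excluded_to_pos <- draw_some(excluded, lam)
      add_pos <- c(add_pos, detail$excluded_to_pos)
    }
    if (length(obligate) > 0L) {
      detail$obligate_to_neg <- draw_some(obligate, lam)
      add_neg <- detail$obligate_to_neg
    }
  } else {
    strong <- setdiff(names(b2)[b2 == "strong"], overlap)
    detail$strong_to_neg <- draw_some(strong, lam)
    add_neg <- detail$strong_to_neg
  }
  list(gene = pick$gene, module = 1L, add_pos = unique(add_pos),
       add_neg = setdiff(unique(add_neg), unique(add_pos)), detail = detail)
}

#' Distractor module 2: phenotypically-distinct disease genes
#'
#' Uniform draw among genes causing diseases with zero phenotype-term
#' overlap with the true disease (raw annotated term sets). No phenotype
#' side-effects.
#'
#' @inheritParams phenotypically_similar_distractor
#' @return a distractor result or `NULL`
#' @export
phenotypically_distinct_distractor <- function(patient, ctx,
                                               params = distractor_params(),
                                               exclude = character(0)) {
  pool <- setdiff(ctx$m2_genes[[patient$disease]], exclude)
  if (length(pool) == 0L) return(NULL)
  g <- pool[sample.int(length(pool), 1L)]
  list(gene = g, module = 2L, add_pos = character(0),
       add_neg = character(0), detail = list())
}

#' Distractor module 3: insufficiently explanatory genes
#'
#' Uniform draw among non-disease genes whose phenotype annotations form a
#' nonempty strict subset of the true disease's weak (low-prevalence)
#' terms. Some of the gene's terms join the positives, but only when none of
#' them are already positive.
#'
#' @inheritParams phenotypically_similar_distractor
#' @return a distractor result or `NULL`
#' @export
insufficiently_explanatory_distractor <- function(patient, ctx,
                                                  params = distractor_params(),
                                                  exclude = character(0)) {
  pool <- setdiff(ctx$m3_genes[[patient$disease]], exclude)
  if (length(pool) == 0L) return(NULL)
  g <- pool[sample.int(length(pool), 1L)]
  terms <- ctx$kg$gene_phenotype[[g]]
  add_pos <- if (any(terms %in% patient$positives)) character(0) else
    draw_some(terms, params$lambda_phen)
  list(gene = g, module = 3L, add_pos = add_pos, add_neg = character(0),
       detail = list())
}

#' Distractor module 4: genes associated with incidental phenotypes
#'
#' Uniform draw among non-disease genes annotated only to terms that do not
#' overlap the true disease. Some of the gene's terms join the positives.
#'
#' @inheritParams phenotypically_similar_distractor
#' @return a distractor result or `NULL`
#' @export
incidental_phenotype_distractor <- function(patient, ctx,
                                            params = distractor_params(),
                                            exclude = character(0)) {
  pool <- setdiff(ctx$m4_genes[[patient$disease]], exclude)
  if (length(pool) == 0L) return(NULL)
  g <- pool[sample.int(length(pool), 1L)]
  terms <- ctx$kg$gene_phenotype[[g]]
  list(gene = g, module = 4L,
       add_pos = draw_some(terms, params$lambda_phen),
       add_neg = character(0), detail = list())
}

# Top-k expression neighbours of a causal gene by cosine similarity over
# the per-tissue min-max normalized matrix, excluding the causal gene,
# disease genes whose diseases overlap the true disease, and any `exclude`
# genes; only strictly positive similarities are kept.
expression_neighbours <- function(ctx, causal, exclude = character(0),
                                  overlap_excluded = character(0),
                                  top_k = 100L) {
  key <- causal
  top <- get0(key, envir = ctx$m5_cache, ifnotfound = NULL)
  if (is.null(top)) {
    if (!causal %in% rownames(ctx$norm_expr)) return(NULL)
    v <- ctx$norm_expr[causal, ]
    nv <- sqrt(sum(v ^ 2))
    if (nv == 0) return(NULL)
    sims <- as.numeric(ctx$norm_expr %*% v) / (ctx$row_norms * nv)
    sims[!is.finite(sims)] <- 0
    names(sims) <- rownames(ctx$norm_expr)
    sims <- sims[names(sims) != causal]
    top <- sort(sims, decreasing = TRUE)
    assign(key, top, envir = ctx$m5_cache)
  }
  top <- top[seq_len(min(top_k, length(top)))]
  top <- top[!names(top) %in% c(exclude, overlap_excluded)]
  top <- top[top > 0]
  if (length(top) == 0L) return(NULL)
  data.frame(gene = names(top), sim = unname(top))
}

#' Distractor module 5: similarly expressed genes
#'
#' Per-tissue min-max normalizes the expression matrix over all genes,
#' ranks genes by cosine similarity of their tissue expression vector to
#' the causal gene's, and samples one of the top `top_k` most similar genes
#' with probability proportional to similarity — excluding the causal gene
#' and any disease gene whose disease phenotypically overlaps the true
#' disease. No phenotype side-effects.
#'
#' @inheritParams phenotypically_similar_distractor
#' @return a distractor result or `NULL` (also when the causal gene has no
#'   expression vector)
#' @export
similarly_expressed_distractor <- function(patient, ctx,
                                           params = distractor_params(),
                                           exclude = character(0)) {
  nb <- expression_neighbours(ctx, patient$gene, exclude = exclude,
                              overlap_excluded = ctx$m5_excluded[[patient$disease]],
                              top_k = params$top_k)
  if (is.null(nb)) return(NULL)
  g <- nb$gene[sample.int(nrow(nb), 1L, prob = nb$sim)]
  list(gene = g, module = 5L, add_pos = character(0),
       add_neg = character(0), detail = list())
}

#' Distractor module 6: common false-positive genes
#'
#' Weighted draw from the frequently-mutated (FLAGS-style) gene table with
#' probability proportional to each gene's rare functional variant count;
#' zero-count genes are never chosen. No phenotype side-effects.
#'
#' @param ctx context from [build_distractor_context()]
#' @param exclude genes that may not be returned
#' @return a distractor result or `NULL`
#' @export
false_positive_distractor <- function(ctx, exclude = character(0)) {
  tab <- ctx$kg$flags
  tab <- tab[!tab$gene %in% exclude & tab$count > 0, , drop = FALSE]
  if (nrow(tab) == 0L) return(NULL)
  g <- tab$gene[sample.int(nrow(tab), 1L, prob = tab$count)]
  list(gene = g, module = 6L, add_pos = character(0),
       add_neg = character(0), detail = list())
}

# Dispatch one module draw.
run_module <- function(m, patient, ctx, params, exclude) {
  switch(m,
    phenotypically_similar_distractor(patient, ctx, params, exclude),
    phenotypically_distinct_distractor(patient, ctx, params, exclude),
    insufficiently_explanatory_distractor(patient, ctx, params, exclude),
    incidental_phenotype_distractor(patient, ctx, params, exclude),
    similarly_expressed_distractor(patient, ctx, params, exclude),
    false_positive_distractor(ctx, exclude))
}

#' Attach distractor genes (and their phenotypes) to a patient
#'
#' Samples the noncausal gene budget, assigns each slot a module, and fills
#' the slots. A slot whose module yields no candidate is redrawn (module
#' resampled from the weights, renormalized over enabled modules) up to 10
#' times, then backfilled with a uniformly random unused gene labelled
#' `random_backfill`; disabled modules backfill immediately, so ablations
#' preserve candidate-list length. In `gene_only` mode the modules'
#' phenotype side-effects are suppressed. The final candidate list is
#' shuffled with provenance labels retained.
#'
#' @param patient a [simulated_patient] (candidates initialized to the
#'   causal gene)
#' @param kg a [knowledge_graph]
#' @param params a [distractor_params]
#' @param ctx optional precomputed [build_distractor_context()] (built on
#'   the fly when `NULL`; prebuild it for cohorts)
#' @param enabled logical vector of length 6: which modules are active
#' @return the patient with a full, shuffled candidate list
#' @export
attach_distractors <- function(patient, kg, params = distractor_params(),
                               ctx = NULL, enabled = rep(TRUE, 6L)) {
  if (is.null(ctx)) ctx <- build_distractor_context(kg)
  budget <- sample_budgets(params)
  w <- params$weights * as.numeric(enabled)
  for (slot in seq_len(budget$n_noncausal)) {
    m <- budget$modules[slot]
    res <- NULL
    if (enabled[m]) {
      res <- run_module(m, patient, ctx, params, patient$candidates$gene)
      tries <- 0L
      while (is.null(res) && tries < 10L && sum(w) > 0) {
        m <- sample.int(6L, 1L, prob = w)
        res <- run_module(m, patient, ctx, params, patient$candidates$gene)
        tries <- tries + 1L
      }
    }
    if (is.null(res)) {
      pool <- setdiff(kg$genes, patient$candidates$gene)
      if (length(pool) == 0L) {
        warning("gene universe exhausted; candidate list left short")
        next
      }
      res <- list(gene = pool[sample.int(length(pool), 1L)], module = NA,
                  add_pos = character(0), add_neg = character(0))
      label <- "random_backfill"
    } else {
      label <- paste0("module_", res$module)
    }
    patient$candidates <- rbind(
      patient$candidates,
      data.frame(gene = res$gene, provenance = label, stringsAsFactors = FALSE))
    if (!params$gene_only) patient <- apply_side_effects(patient, res)
  }
  patient$candidates <-
    patient$candidates[sample.int(nrow(patient$candidates)), , drop = FALSE]
  rownames(patient$candidates) <- NULL
  patient
}
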