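fresh_patient <- function(kg, d = first_simulatable(kg)) {
  init_patient(d, kg)
}

test_that("gene and module budgets follow their distributions", {
  set.seed(21)
  z <- sample_budgets(distractor_params(lambda_genes = 0))
  expect_identical(z$n_noncausal, 1L)

  n <- vapply(1:10000,
              function(i) sample_budgets(distractor_params())$n_noncausal,
              1L)
  expect_lt(abs(mean(n) - 13), 0.2)  # 1 + Poisson(12)

  w <- c(1, 0, 0, 0, 0, 0)
  b <- sample_budgets(distractor_params(weights = w, lambda_genes = 5))
  expect_true(all(b$modules == 1L))

  # provenance frequencies track the configured weights
  par <- distractor_params(lambda_genes = 12)
  mods <- unlist(lapply(1:3000, function(i) sample_budgets(par)$modules))
  freq <- tabulate(mods, 6) / length(mods)
  expect_true(all(abs(freq - par$weights) < 0.02))
})

test_that("invalid distractor parameters are rejected", {
  expect_error(distractor_params(weights = rep(0.2, 5)), "length 6")
  expect_error(distractor_params(weights = rep(0.2, 6)), "sum to 1")
  expect_error(distractor_params(lambda_genes = -1), ">= 0")
  expect_error(distractor_params(top_k = 0), ">= 1")
})

test_that("phenotypically-similar distractors obey the eligibility logic", {
  kg <- fixture_kg()
  ctx <- build_distractor_context(kg)
  d <- first_simulatable(kg)
  set.seed(22)
  for (i in 1:50) {
    p <- fresh_patient(kg, d)
    res <- phenotypically_similar_distractor(p, ctx,
                                             exclude = p$candidates$gene)
    expect_false(is.null(res))
    expect_false(res$gene %in% d$genes)   # never the causal gene
    d2 <- kg$diseases[[res$detail$distractor_disease]]
    expect_true(res$gene %in% d2$genes)
    # overlap terms added to positives are annotated to both diseases
    expect_true(all(res$detail$overlap %in% names(d$phenotypes)))
    expect_true(all(res$detail$overlap %in% names(d2$phenotypes)))
    # excluded-step terms have distractor prevalence exactly 0
    expect_true(all(d2$phenotypes[res$detail$excluded_to_pos] == 0))
    # obligate-step terms have distractor prevalence exactly 1
    expect_true(all(d2$phenotypes[res$detail$obligate_to_neg] == 1))
    expect_length(intersect(res$add_pos, res$add_neg), 0)
  }
})

test_that("the Alstrom/Wolfram-style fixture is eligible via the weak clause", {
  kg <- alstrom_style_kb()
  ctx <- build_distractor_context(kg)
  pool <- ctx$m1_pairs[["ORPHA:T"]]
  expect_identical(pool$gene, "G_DIST")      # eligible despite no
  expect_identical(pool$disease, "ORPHA:D")  # obligate/excluded terms
  set.seed(23)
  d2 <- kg$diseases[["ORPHA:D"]]
  for (i in 1:25) {
    p <- fresh_patient(kg, kg$diseases[["ORPHA:T"]])
    res <- phenotypically_similar_distractor(p, ctx,
                                             exclude = p$candidates$gene)
    # only the weak overlap terms are added to positives
    expect_true(all(bucket_prevalence(d2$phenotypes[res$detail$overlap]) ==
                      "weak"))
    # strong non-overlapping terms land in negatives instead
    expect_gt(length(res$detail$strong_to_neg), 0)
    expect_true(all(bucket_prevalence(d2$phenotypes[res$detail$strong_to_neg])
                    == "strong"))
    expect_false(any(res$detail$strong_to_neg %in% names(
      kg$diseases[["ORPHA:T"]]$phenotypes)))
  }
  # a distractor with neither obligate/excluded nor weak overlap is
  # ineligible: raise all the distractor's overlap terms out of the weak band
  kg2 <- kg
  ov <- intersect(names(kg2$diseases[["ORPHA:D"]]$phenotypes),
                  names(kg2$diseases[["ORPHA:T"]]$phenotypes))
  kg2$diseases[["ORPHA:D"]]$phenotypes[ov] <- 0.9
  ctx2 <- build_distractor_context(kg2)
  expect_identical(nrow(ctx2$m1_pairs[["ORPHA:T"]]), 0L)
})

test_that("phenotypically-distinct distractors have zero overlap", {
  kg <- fixture_kg()
  ctx <- build_distractor_context(kg)
  d <- first_simulatable(kg)
  ts1 <- names(d$phenotypes)[d$phenotypes > 0]
  set.seed(24)
  for (i in 1:25) {
    p <- fresh_patient(kg, d)
    res <- phenotypically_distinct_distractor(p, ctx,
                                              exclude = p$candidates$gene)
    expect_false(res$gene %in% d$genes)
    # every disease of the chosen gene is disjoint from the true disease
    for (d2 in kg$diseases) {
      if (res$gene %in% d2$genes) {
        expect_length(intersect(ts1, names(d2$phenotypes)[d2$phenotypes > 0]),
                      0)
      }
    }
    expect_length(res$add_pos, 0)
    expect_length(res$add_neg, 0)
  }
})

test_that("insufficiently explanatory genes are strict weak subsets", {
  kg <- fixture_kg()
  ctx <- build_distractor_context(kg)
  d <- first_simulatable(kg)
  weak <- names(d$phenotypes)[bucket_prevalence(d$phenotypes) == "weak"]
  causal_sets <- unlist(lapply(kg$diseases, function(x) x$genes))
  set.seed(25)
  for (i in 1:25) {
    p <- fresh_patient(kg, d)
    res <- insufficiently_explanatory_distractor(p, ctx,
                                                 exclude = p$candidates$gene)
    terms <- kg$gene_phenotype[[res$gene]]
    expect_gt(length(terms), 0)
    expect_true(all(terms %in% weak))
    expect_lt(length(terms), length(weak))      # strict subset
    expect_false(res$gene %in% causal_sets)     # truly non-disease
    # additions only when none of the gene's terms are already positive
    if (any(terms %in% p$positives)) {
      expect_length(res$add_pos, 0)
    } else {
      expect_true(all(res$add_pos %in% terms))
    }
  }
})

test_that("incidental-phenotype genes never overlap the true disease", {
  kg <- fixture_kg()
  ctx <- build_distractor_context(kg)
  d <- first_simulatable(kg)
  ts1 <- names(d$phenotypes)[d$phenotypes > 0]
  set.seed(26)
  par0 <- distractor_params(lambda_phen = 0)
  for (i in 1:25) {
    p <- fresh_patient(kg, d)
    res <- incidental_phenotype_distractor(p, ctx, par0,
                                           exclude = p$candidates$gene)
    terms <- kg$gene_phenotype[[res$gene]]
    expect_length(intersect(terms, ts1), 0)
    expect_length(res$add_pos, 1)               # lambda 0: exactly one term
    expect_true(all(res$add_pos %in% terms))
  }
})

test_that("expression neighbours use cosine similarity on normalized vectors", {
  kg <- fixture_kg()
  # plant a twin of the first causal gene and an orthogonal gene
  d <- first_simulatable(kg)
  causal <- d$genes[1]
  expr <- kg$expression
  twin <- "ENSG_TWIN"
  orth <- "ENSG_ORTH"
  expr <- rbind(expr, matrix(rep(expr[causal, ], 2), nrow = 2, byrow = TRUE,
                             dimnames = list(c(twin, orth), colnames(expr))))
  # orthogonal after min-max normalization: zero everywhere the causal gene
  # is nonzero requires care; instead plant the global min in every tissue
  expr[orth, ] <- apply(kg$expression, 2, min)
  kg2 <- kg
  kg2$expression <- expr
  ctx <- build_distractor_context(kg2)
  nb <- phenosim:::expression_neighbours(ctx, causal, top_k = nrow(expr))
  expect_identical(nb$gene[1], twin)
  expect_equal(nb$sim[1], 1.0, tolerance = 1e-12)
  expect_false(orth %in% nb$gene)   # zero vector -> similarity 0, dropped

  # selection frequencies are proportional to similarity within the top-k
  set.seed(27)
  p <- fresh_patient(kg2, d)
  par <- distractor_params(top_k = 10)
  pool <- phenosim:::expression_neighbours(
    ctx, p$gene, exclude = p$candidates$gene,
    overlap_excluded = ctx$m5_excluded[[p$disease]], top_k = 10)
  draws <- vapply(1:10000, function(i) {
    similarly_expressed_distractor(p, ctx, par,
                                   exclude = p$candidates$gene)$gene
  }, "")
  freq <- table(factor(draws, levels = pool$gene)) / length(draws)
  expect_true(all(abs(freq - pool$sim / sum(pool$sim)) < 0.02))
})

test_that("false-positive genes are drawn by rare-variant count", {
  kg <- fixture_kg()
  ctx <- build_distractor_context(kg)
  ctx$kg$flags <- data.frame(gene = c("G_A", "G_B", "G_Z"),
                             count = c(300, 100, 0))
  set.seed(28)
  draws <- vapply(1:10000,
                  function(i) false_positive_distractor(ctx)$gene, "")
  expect_false(any(draws == "G_Z"))      # zero-count gene never chosen
  expect_lt(abs(mean(draws == "G_A") - 0.75), 0.02)
  one <- ctx
  one$kg$flags <- data.frame(gene = "G_ONLY", count = 5)
  expect_identical(false_positive_distractor(one)$gene, "G_ONLY")
  none <- ctx
  none$kg$flags <- data.frame(gene = character(0), count = numeric(0))
  expect_null(false_positive_distractor(none))
})

test_that("attach_distractors keeps the candidate-list invariants", {
  kg <- fixture_kg()
  ctx <- build_distractor_context(kg)
  d <- first_simulatable(kg)
  set.seed(29)
  for (i in 1:20) {
    p <- attach_distractors(fresh_patient(kg, d), kg, ctx = ctx)
    expect_false(anyDuplicated(p$candidates$gene) > 0)
    expect_true(p$gene %in% p$candidates$gene)
    expect_identical(
      p$candidates$provenance[p$candidates$gene == p$gene], "causal")
    expect_length(intersect(p$positives, p$negatives), 0)
    # modules 2, 5, 6 never touch phenotypes: with only those enabled the
    # phenotype sets are unchanged
  }
  base <- fresh_patient(kg, d)
  only256 <- distractor_params(weights = c(0, 0.4, 0, 0, 0.3, 0.3) /
                                 sum(c(0, 0.4, 0, 0, 0.3, 0.3)))
  p <- attach_distractors(base, kg, params = only256, ctx = ctx)
  expect_identical(p$positives, base$positives)
  expect_identical(p$negatives, base$negatives)
  expect_true(all(p$candidates$provenance %in%
                    c("causal", "module_2", "module_5", "module_6")))

  # gene_only suppresses all phenotype side-effects
  p <- attach_distractors(base, kg,
                          params = distractor_params(gene_only = TRUE),
                          ctx = ctx)
  expect_identical(p$positives, base$positives)
  expect_identical(p$negatives, base$negatives)

  # weights concentrated on module 6 draw only flags genes
  w6 <- distractor_params(weights = c(0, 0, 0, 0, 0, 1), lambda_genes = 2)
  p <- attach_distractors(base, kg, params = w6, ctx = ctx)
  lab <- p$candidates$provenance
  expect_true(all(p$candidates$gene[lab == "module_6"] %in% kg$flags$gene))

  # disabling a module backfills randomly but preserves list length
  set.seed(30)
  en <- c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  p <- attach_distractors(base, kg, ctx = ctx, enabled = en)
  expect_false(any(p$candidates$provenance == "module_2"))
  expect_gte(nrow(p$candidates), 2)
})

test_that("candidate count is 2 + N_G and backfill keeps length on exhaustion", {
  kg <- fixture_kg()
  ctx <- build_distractor_context(kg)
  d <- first_simulatable(kg)
  set.seed(31)
  lens <- vapply(1:300, function(i) {
    nrow(attach_distractors(fresh_patient(kg, d), kg, ctx = ctx)$candidates)
  }, 1L)
  expect_lt(abs(mean(lens) - 14), 3.5 * sqrt(12 / 300))  # 2 + Poisson(12)

  # all modules disabled: every noncausal slot is a random backfill
  p <- attach_distractors(fresh_patient(kg, d), kg, ctx = ctx,
                          enabled = rep(FALSE, 6))
  lab <- p$candidates$provenance
  expect_setequal(unique(lab), c("causal", "random_backfill"))
})
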