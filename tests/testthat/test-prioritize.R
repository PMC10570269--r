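eight_entity_corpus <- function() {
  o <- diamond_ontology()
  # 8 entities; exactly one annotated under HP:4
  ents <- c(lapply(1:7, function(i) "HP:2"), list("HP:4"))
  names(ents) <- paste0("E", 1:8)
  annotation_corpus(ents, o)
}

test_that("information content matches closed-form and brute-force values", {
  corp <- eight_entity_corpus()
  ic <- information_content(corp)
  expect_equal(unname(ic["HP:1"]), 0)            # root covers everything
  expect_equal(unname(ic["HP:4"]), 3)            # 1 of 8 entities = 3 bits
  expect_equal(unname(ic["HP:2"]), 0)            # all 8 reach HP:2
  expect_false("HP:3" %in% names(ic) && ic["HP:3"] > 0 &&
                 FALSE)  # HP:3 covered only via HP:4's closure
  expect_equal(unname(ic["HP:3"]), 3)

  # IC is nonincreasing towards ancestors
  o <- corp$ontology
  for (t in names(ic)) {
    for (a in setdiff(ancestors(o, t), t)) {
      if (a %in% names(ic)) expect_lte(ic[a], ic[t])
    }
  }
})

test_that("IC and Phrank match brute-force oracles on random 50-term DAGs", {
  set.seed(51)
  n_dags <- 10
  trials_per_dag <- 10
  for (i in seq_len(n_dags)) {
    o <- random_dag(50)
    ents <- lapply(1:12, function(j) sample(o$ids, sample.int(4, 1)))
    names(ents) <- paste0("E", 1:12)
    corp <- annotation_corpus(ents, o)
    expect_equal(corp$ic[sort(names(corp$ic))],
                 bf_information_content(ents, o)[sort(names(corp$ic))])
    for (j in seq_len(trials_per_dag)) {
      a <- sample(o$ids, sample.int(5, 1))
      b <- sample(o$ids, sample.int(5, 1))
      expect_equal(phrank_similarity(a, b, corp),
                   bf_phrank(a, b, ents, o))
    }
  }
})

test_that("Phrank self-similarity and root-only overlap behave as stated", {
  corp <- eight_entity_corpus()
  a <- c("HP:4")
  self <- phrank_similarity(a, a, corp)
  cl <- ancestors(corp$ontology, "HP:4")
  expect_equal(self, sum(corp$ic[intersect(cl, names(corp$ic))]))
  # sets sharing only the root score 0 bits
  expect_equal(phrank_similarity("HP:2", "HP:3", corp),
               unname(corp$ic["HP:2"]) + 0 - unname(corp$ic["HP:2"]))
  expect_equal(phrank_similarity("HP:2", "HP:3", corp), 0)
  expect_warning(phrank_similarity(character(0), a, corp), "empty")
})

test_that("gene ranking recovers an unambiguous causal gene at rank 1", {
  kg <- fixture_kg()
  d <- first_simulatable(kg)
  set.seed(52)
  p <- init_patient(d, kg)
  # textbook patient: full phenotype, distractors from disjoint diseases
  p <- attach_distractors(p, kg,
                          params = distractor_params(
                            weights = c(0, 1, 0, 0, 0, 0), lambda_genes = 5),
                          ctx = build_distractor_context(kg))
  for (mode in c("disease", "gene")) {
    rr <- rank_genes_phrank(p, kg, mode)
    expect_identical(rr$causal_rank, 1)
    expect_identical(rr$table$rank[rr$table$gene == p$gene], 1)
  }
})

test_that("genes without dated disease links score zero in disease mode", {
  kg <- fixture_kg()
  planted <- attr(kg, "planted_novelty")
  und <- names(planted)[planted == "known_disease_undiscovered_gene"][1]
  d <- kg$diseases[[und]]
  set.seed(53)
  p <- init_patient(d, kg)
  rr <- rank_genes_phrank(p, kg, "disease")
  expect_equal(rr$table$score[rr$table$gene == p$gene], 0)
})

test_that("ranks are tie-fair and invariant to candidate order", {
  kg <- fixture_kg()
  d <- first_simulatable(kg)
  set.seed(54)
  p <- attach_distractors(init_patient(d, kg), kg,
                          ctx = build_distractor_context(kg))
  rr1 <- rank_genes_phrank(p, kg, "disease")
  p2 <- p
  perm <- rev(seq_len(nrow(p$candidates)))
  p2$candidates <- p2$candidates[perm, ]
  rr2 <- rank_genes_phrank(p2, kg, "disease")
  m <- match(rr1$table$gene, rr2$table$gene)
  expect_equal(rr2$table$rank[m], rr1$table$rank)
  expect_equal(rr2$causal_rank, rr1$causal_rank)
  # tied zero-scores share the mean of their positions
  zeros <- rr1$table$rank[rr1$table$score == 0]
  if (length(zeros) > 1) expect_equal(length(unique(zeros)), 1L)
})

test_that("scorers only see knowledge dated at or before the timestamp", {
  kg <- fixture_kg()
  d <- first_simulatable(kg)
  set.seed(55)
  p <- attach_distractors(init_patient(d, kg), kg,
                          ctx = build_distractor_context(kg))
  base <- rank_genes_phrank(p, kg, "disease")
  # plant a post-timestamp edge linking a candidate to the true disease
  other <- setdiff(p$candidates$gene, p$gene)[1]
  kg2 <- kg
  kg2$gene_disease <- rbind(kg2$gene_disease,
                            data.frame(gene = other, disease = d$id,
                                       date = as.Date("2020-01-01")))
  after <- rank_genes_phrank(p, kg2, "disease")
  expect_equal(after$table$score, base$table$score)
  # the same edge dated before the timestamp does change the score
  kg3 <- kg
  kg3$gene_disease <- rbind(kg3$gene_disease,
                            data.frame(gene = other, disease = d$id,
                                       date = as.Date("2010-01-01")))
  pre <- rank_genes_phrank(p, kg3, "disease")
  expect_gt(pre$table$score[pre$table$gene == other],
            base$table$score[base$table$gene == other])
})

test_that("adding a gene-annotated positive term never lowers its score", {
  kg <- fixture_kg()
  sv <- phenosim:::scoring_view(kg)
  d <- first_simulatable(kg)
  set.seed(56)
  for (i in 1:10) {
    p <- attach_distractors(init_patient(d, kg), kg,
                            ctx = build_distractor_context(kg))
    for (g in sample(p$candidates$gene, 3)) {
      terms <- sv$gene_corpus$raw[[g]]
      if (is.null(terms)) next
      extra <- setdiff(terms, p$positives)
      if (length(extra) == 0) next
      before <- phenosim:::phrank_candidate_scores(p, sv, "gene")[g]
      p2 <- p
      p2$positives <- sort(unique(c(p2$positives, extra[1])))
      after <- phenosim:::phrank_candidate_scores(p2, sv, "gene")[g]
      expect_gte(after, before)
    }
  }
})

test_that("phenomizer self-match equals the mean IC of the disease terms", {
  kg <- fixture_kg()
  pc <- phenomizer_corpus(kg)
  dc <- pc$disease_corpus
  for (d in names(dc$raw)[1:5]) {
    terms <- dc$raw[[d]]
    ic <- dc$ic
    self <- phenomizer_similarity(terms, d, pc)
    expect_equal(self, mean(vapply(terms, function(t) {
      unname(ic[t])
    }, 0)))
  }
})

test_that("phenomizer p-values are add-one bounded and null-uniform", {
  kg <- fixture_kg()
  pc <- phenomizer_corpus(kg)
  d <- names(pc$disease_corpus$raw)[1]
  terms <- pc$disease_corpus$raw[[d]]
  set.seed(57)
  sp <- phenomizer_score_and_p(terms, d, pc, n_samples = 500)
  expect_gte(sp$p, 1 / 501)

  # p-values of random term sets are super-uniform (KS, generous alpha)
  n_null <- 120
  k <- 4
  ps <- vapply(seq_len(n_null), function(i) {
    phenomizer_score_and_p(sample(pc$vocab, k), d, pc, n_samples = 400)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort evaluation reports oracle, random, and category sums", {
  kg <- fixture_kg()
  cohort <- simulate_cohort(kg, sim_config(patients_per_disease = 2,
                                           seed = 58))
  oracle <- function(p) {
    stats::setNames(as.numeric(p$candidates$gene == p$gene),
                    p$candidates$gene)
  }
  attr(oracle, "scorer") <- "oracle"
  ev <- evaluate_cohort(cohort, oracle)
  overall <- ev$summary[ev$summary$category == "overall", ]
  expect_equal(overall$top_1, 1.0)
  expect_equal(overall$mean_rank, 1.0)
  expect_identical(sum(ev$summary$n[ev$summary$category != "overall"]),
                   length(cohort))

  # random scorer approaches mean rank (n + 1) / 2
  k <- 15
  pats <- lapply(1:4000, function(i) {
    genes <- paste0("G", 1:k)
    simulated_patient(paste0("r", i), "D:1", "G1", "adult",
                      positives = character(0), negatives = character(0),
                      candidates = data.frame(
                        gene = genes,
                        provenance = c("causal", rep("random_backfill", k - 1)),
                        stringsAsFactors = FALSE),
                      novelty = "known_disease_known_gene")
  })
  set.seed(59)
  rand <- function(p) stats::setNames(stats::runif(k), p$candidates$gene)
  attr(rand, "scorer") <- "random"
  ev2 <- evaluate_cohort(pats, rand, k = 10)
  expect_lt(abs(ev2$summary$mean_rank[ev2$summary$category == "overall"] - 8),
            0.3)
  # the seeded random baseline for top-10 of 15 candidates is ~2/3
  expect_lt(abs(ev2$summary$random_top_10[ev2$summary$category == "overall"] -
                  10 / 15), 0.05)
})

test_that("jaccard retrieval separates informative from random ranking", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(character(0), character(0)), 0)

  kg <- fixture_kg()
  cohort <- simulate_cohort(kg, sim_config(patients_per_disease = 3,
                                           seed = 60))
  queries <- cohort[seq(1, length(cohort), by = 3)]
  refs <- cohort[-seq(1, length(cohort), by = 3)]
  curve <- jaccard_retrieval(queries, refs)
  expect_identical(nrow(curve), length(refs))
  expect_true(all(diff(curve$jaccard) >= 0))     # cumulative
  expect_equal(curve$jaccard[nrow(curve)], 1)    # every query has a match
  # informative ranking dominates random early in the curve
  expect_gt(mean(curve$jaccard[1:10]), mean(curve$random[1:10]))

  # reference cohort of same-disease clones: match at rank 1 always
  clones <- rep(queries[1], 5)
  expect_equal(jaccard_retrieval(queries[1], clones)$jaccard[1], 1)
})

test_that("network distances match hand-computed BFS on a path graph", {
  # path graph G1 - G2 - G3 - G4 - G5, plus isolated candidate
  net <- data.frame(a = c("G1", "G2", "G3", "G4"),
                    b = c("G2", "G3", "G4", "G5"))
  mk <- function(id, gene, cands) {
    simulated_patient(id, "D:1", gene, "adult", character(0), character(0),
                      candidates = data.frame(
                        gene = c(gene, cands),
                        provenance = c("causal",
                                       rep("module_2", length(cands))),
                        stringsAsFactors = FALSE))
  }
  a <- list(mk("a1", "G1", c("G2", "G3", "G5", "GX")))
  b <- list(mk("b1", "G2", c("G1", "G4")))
  res <- network_distance_comparison(a, b, net)
  expect_setequal(res$distances_a, c(1, 2, 4))
  expect_identical(res$disconnected_a, 1L)       # GX absent from network
  expect_setequal(res$distances_b, c(1, 2))
  # identical cohorts give KS statistic 0
  same <- network_distance_comparison(a, a, net)
  expect_equal(same$ks_statistic, 0)
  # causal gene absent from the network: patient skipped and counted
  c <- list(mk("c1", "GZ", c("G1")))
  res2 <- network_distance_comparison(c, b, net)
  expect_identical(res2$skipped_a, 1L)
})

test_that("external score tables rank identically to native scorers", {
  kg <- fixture_kg()
  cohort <- simulate_cohort(kg, sim_config(patients_per_disease = 1,
                                           seed = 61))[1:5]
  native <- make_scorer(kg, "phrank_disease")
  tab <- do.call(rbind, lapply(cohort, function(p) {
    s <- native(p)
    data.frame(patient_id = p$id, gene = names(s), score = unname(s))
  }))
  ext <- make_scorer(kg, "external", external_scores = tab)
  for (p in cohort) {
    expect_equal(unname(ext(p)), unname(native(p)))
  }
})

test_that("ablation arms preserve candidate counts and rank ordering", {
  kg <- fixture_kg()
  cfg <- sim_config(patients_per_disease = 2, seed = 62,
                    distractor = distractor_params(lambda_genes = 6))
  scorer <- make_scorer(kg, "phrank_disease")
  arms <- ablation_arms()[c("none", "full", "full_minus_module_1")]
  rep <- ablation_report(kg, cfg, scorer, arms = arms, seeds = 62)
  expect_identical(rep$arm, c("none", "full", "full_minus_module_1"))
  expect_true(all(rep$n_patients == rep$n_patients[1]))
  # the full pipeline is harder than no components
  expect_lte(rep$mean_rank[rep$arm == "none"],
             rep$mean_rank[rep$arm == "full"])
})
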