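#' Build an ancestor-propagated annotation corpus
#'
#' An annotation corpus maps entities (genes or diseases) to phenotype term
#' sets, propagated up the ontology (every entity annotated to a term is
#' implicitly annotated to all its ancestors), and carries the per-term
#' information content in bits:
#' `IC(t) = -log2(|entities annotated to t or any descendant| / |entities|)`.
#' The root always covers every entity, so `IC(root) = 0`, and IC never
#' increases from a term to its ancestors.
#'
#' @param entity_terms named list: entity id -> character vector of term ids
#' @param ontology an [ontology]
#' @param propagate propagate annotations through ancestor closure (default
#'   `TRUE`; scoring without propagation is available for sensitivity
#'   checks)
#' @return an object of class `annotation_corpus` with elements `sets`
#'   (closed term sets), `raw` (as given), `ic` (named numeric, only terms
#'   covering >= 1 entity), `n_entities`, `ontology`
#' @export
annotation_corpus <- function(entity_terms, ontology, propagate = TRUE) {
  bad <- setdiff(unique(unlist(entity_terms, use.names = FALSE)), ontology$ids)
  if (length(bad) > 0) {
    stop("corpus references terms missing from the ontology: ",
         paste(bad, collapse = ", "))
  }
  raw <- lapply(entity_terms, function(ts) sort(unique(ts)))
  sets <- if (propagate) {
    lapply(raw, function(ts) term_set_closure(ontology, ts))
  } else raw
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  n <- length(sets)
  ic <- -log2(as.numeric(counts) / n)
  names(ic) <- names(counts)
  structure(list(sets = sets, raw = raw, ic = ic, n_entities = n,
                 ontology = ontology),
            class = "annotation_corpus")
}

#' Per-term information content of a corpus
#'
#' @param corpus an [annotation_corpus]
#' @return named numeric vector of IC in bits; terms annotated to zero
#'   entities have undefined IC and are absent
#' @export
information_content <- function(corpus) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  corpus$ic
}

#' Phrank-style phenotype-set similarity
#'
#' The similarity of two term sets is the summed information content of the
#' shared ancestors: `sum of IC(t)` over the intersection of the ancestor
#' closures of the two sets. Sets sharing only the root score 0 bits.
#'
#' @param set_a,set_b character vectors of term ids
#' @param corpus an [annotation_corpus] (provides the IC and ontology)
#' @return similarity in bits
#' @export
phrank_similarity <- function(set_a, set_b, corpus) {
  o <- corpus$ontology
  a <- intersect(set_a, o$ids)
  b <- intersect(set_b, o$ids)
  if (length(a) == 0L || length(b) == 0L) {
    warning("phenotype set empty after ontology filtering; score 0")
    return(0)
  }
  shared <- intersect(term_set_closure(o, a), term_set_closure(o, b))
  ic <- corpus$ic[intersect(shared, names(corpus$ic))]
  sum(ic)
}

# Corpora and gene -> disease map for scoring against the dated knowledge
# view. Disease term sets exclude prevalence-0 (excluded) annotations.
scoring_view <- function(kg, propagate = TRUE) {
  view <- kg_as_of(kg)
  disease_terms <- lapply(view$diseases, function(d) {
    names(d$phenotypes)[d$phenotypes > 0]
  })
  disease_terms <- disease_terms[vapply(disease_terms, length, 1L) > 0L]
  gene_terms <- view$gene_phenotype
  gene_terms <- gene_terms[vapply(gene_terms, length, 1L) > 0L]
  gene2dis <- split(view$gene_disease$disease, view$gene_disease$gene)
  gene2dis <- lapply(gene2dis, function(d) intersect(unique(d),
                                                    names(disease_terms)))
  list(view = view,
       disease_corpus = annotation_corpus(disease_terms, kg$ontology,
                                          propagate = propagate),
       gene_corpus = annotation_corpus(gene_terms, kg$ontology,
                                       propagate = propagate),
       gene2dis = gene2dis)
}

#' Rank a patient's candidate genes with Phrank-style similarity
#'
#' In `gene` mode each candidate is scored by the similarity of the
#' patient's positive terms to the gene's own phenotype annotations. In
#' `disease` mode each candidate is scored against every disease it is
#' associated with in the dated knowledge view and takes the highest
#' disease similarity. Genes with no annotations (or, in disease mode, no
#' disease known by the timestamp) score 0. Tied scores receive the mean of
#' the tied rank positions, so ranks do not depend on candidate order.
#'
#' @param patient a [simulated_patient]
#' @param kg a [knowledge_graph] (scored through its timestamp view)
#' @param mode `"gene"` or `"disease"`
#' @param sv optional precomputed scoring view (internal reuse)
#' @return a `ranking_result`: list with `patient`, `scorer`, `table`
#'   (data.frame gene, provenance, score, rank) and `causal_rank`
#' @export
rank_genes_phrank <- function(patient, kg, mode = c("disease", "gene"),
                              sv = NULL) {
  mode <- match.arg(mode)
  if (is.null(sv)) sv <- scoring_view(kg)
  scores <- phrank_candidate_scores(patient, sv, mode)
  ranking_result(patient, scores, paste0("phrank_", mode))
}

phrank_candidate_scores <- function(patient, sv, mode) {
  pos <- patient$positives
  vapply(patient$candidates$gene, function(g) {
    if (mode == "gene") {
      ts <- sv$gene_corpus$raw[[g]]
      if (is.null(ts)) return(0)
      suppressWarnings(phrank_similarity(pos, ts, sv$gene_corpus))
    } else {
      ds <- sv$gene2dis[[g]]
      if (is.null(ds) || length(ds) == 0L) return(0)
      max(vapply(ds, function(d) {
        suppressWarnings(phrank_similarity(pos, sv$disease_corpus$raw[[d]],
                                           sv$disease_corpus))
      }, 0))
    }
  }, 0)
}

# Assemble a ranking result with mean-tie ranks.
ranking_result <- function(patient, scores, scorer) {
  ranks <- rank(-scores, ties.method = "average")
  tab <- data.frame(gene = patient$candidates$gene,
                    provenance = patient$candidates$provenance,
                    score = unname(scores), rank = unname(ranks),
                    stringsAsFactors = FALSE)
  structure(list(patient = patient$id, scorer = scorer, table = tab,
                 causal_rank = unname(ranks[patient$candidates$gene ==
                                              patient$gene][1L])),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %s by %s: causal rank %.1f of %d\n",
              x$patient, x$scorer, x$causal_rank, nrow(x$table)))
  invisible(x)
}

#' Precompute Phenomizer-style disease match structures
#'
#' For each disease known at the knowledge-graph timestamp, precomputes the
#' best-match information content of every ontology term against the
#' disease's annotated terms: the IC of the most informative common
#' ancestor (MICA), maximized over the disease's terms. Patient-disease
#' similarity is then the mean best-match IC over the patient's terms
#' (one-sided, patient to disease).
#'
#' @param kg a [knowledge_graph]
#' @return an object of class `phenomizer_corpus`
#' @export
phenomizer_corpus <- function(kg) {
  sv <- scoring_view(kg)
  dc <- sv$disease_corpus
  o <- kg$ontology
  ic_full <- stats::setNames(numeric(length(o$ids)), o$ids)
  ic_full[names(dc$ic)] <- dc$ic
  # best[t, d] = max IC over closure(t) ∩ ancestor-closed terms of d
  best <- vapply(names(dc$sets), function(d) {
    dset <- dc$sets[[d]]
    vapply(o$ids, function(t) {
      common <- intersect(o$closure[[t]], dset)
      if (length(common) == 0L) 0 else max(ic_full[common])
    }, 0)
  }, numeric(length(o$ids)))
  rownames(best) <- o$ids
  vocab <- sort(unique(unlist(dc$raw, use.names = FALSE)))
  structure(list(best = best, vocab = vocab, gene2dis = sv$gene2dis,
                 disease_corpus = dc, ontology = o),
            class = "phenomizer_corpus")
}

#' Phenomizer-style similarity score and permutation p-value
#'
#' The score of a patient term set against a disease is the mean, over
#' patient terms, of the maximum information content of the most
#' informative common ancestor with any of the disease's terms. The
#' p-value is estimated by scoring `n_samples` random term sets of the
#' same cardinality drawn from the annotated vocabulary, with the add-one
#' convention `p = (b + 1) / (n + 1)` (so p is never below
#' `1/(n_samples + 1)`).
#'
#' @param terms patient phenotype term ids
#' @param disease disease id present in the corpus
#' @param pc a [phenomizer_corpus]
#' @param n_samples number of random samplings (default 10000)
#' @return list with `score` (bits) and `p`
#' @export
phenomizer_score_and_p <- function(terms, disease, pc, n_samples = 10000) {
  score <- phenomizer_similarity(terms, disease, pc)
  k <- length(intersect(terms, pc$ontology$ids))
  if (k == 0L) return(list(score = score, p = 1))
  dvec <- pc$best[, disease]
  vocab <- pc$vocab
  null_scores <- vapply(seq_len(n_samples), function(i) {
    mean(dvec[vocab[sample.int(length(vocab), min(k, length(vocab)))]])
  }, 0)
  list(score = score, p = (sum(null_scores >= score) + 1) / (n_samples + 1))
}

#' Phenomizer-style patient-disease similarity
#'
#' @inheritParams phenomizer_score_and_p
#' @return mean best-match IC in bits (0 when no patient term is in the
#'   ontology)
#' @export
phenomizer_similarity <- function(terms, disease, pc) {
  stopifnot(inherits(pc, "phenomizer_corpus"))
  if (!disease %in% colnames(pc$best)) stop("unknown disease: ", disease)
  terms <- intersect(terms, pc$ontology$ids)
  if (length(terms) == 0L) return(0)
  mean(pc$best[terms, disease])
}

#' Build a candidate-gene scorer
#'
#' Returns a function `f(patient)` producing a named numeric score per
#' candidate gene, for use with [evaluate_cohort()]. Methods:
#' `"phrank_disease"`, `"phrank_gene"`, `"phenomizer"` (gene score = the
#' highest patient-disease score across the gene's diseases), or
#' `"external"` with a data.frame of columns `patient_id`, `gene`, `score`
#' (pre-scored output of an external tool; missing pairs score 0).
#'
#' @param kg a [knowledge_graph] (ignored for `"external"`)
#' @param method scoring method name
#' @param external_scores data.frame for `method = "external"`
#' @return scoring function with attribute `"scorer"`
#' @export
make_scorer <- function(kg, method = c("phrank_disease", "phrank_gene",
                                       "phenomizer", "external"),
                        external_scores = NULL) {
  method <- match.arg(method)
  f <- switch(method,
    phrank_disease = {
      sv <- scoring_view(kg)
      function(patient) phrank_candidate_scores(patient, sv, "disease")
    },
    phrank_gene = {
      sv <- scoring_view(kg)
      function(patient) phrank_candidate_scores(patient, sv, "gene")
    },
    phenomizer = {
      pc <- phenomizer_corpus(kg)
      function(patient) {
        vapply(patient$candidates$gene, function(g) {
          ds <- pc$gene2dis[[g]]
          if (is.null(ds) || length(ds) == 0L) return(0)
          max(vapply(ds, function(d) {
            phenomizer_similarity(patient$positives, d, pc)
          }, 0))
        }, 0)
      }
    },
    external = {
      if (is.null(external_scores)) {
        stop("external method needs an external_scores data.frame")
      }
      tab <- external_scores
      function(patient) {
        sel <- tab$patient_id == patient$id
        s <- stats::setNames(tab$score[sel], tab$gene[sel])
        out <- s[patient$candidates$gene]
        out[is.na(out)] <- 0
        stats::setNames(as.numeric(out), patient$candidates$gene)
      }
    })
  attr(f, "scorer") <- method
  f
}

#' Evaluate a scorer over a cohort
#'
#' Ranks every patient's candidates, then reports — per novelty category
#' and overall — the fraction of patients whose causal gene ranks within
#' the top k (for each k), the mean causal rank, and a random baseline
#' (mean top-k fraction over ten seeded random candidate permutations per
#' patient).
#'
#' @param patients list of [simulated_patient]s (each with >= 2 candidates)
#' @param scorer function from [make_scorer()] (or any
#'   `function(patient) -> named scores`)
#' @param k integer vector of rank cutoffs
#' @param n_random_rankings permutations per patient for the baseline
#' @return list with `per_patient` (data.frame: patient, novelty,
#'   n_candidates, causal_rank) and `summary` (data.frame: category, n,
#'   mean_rank, `top_k`, `random_top_k` columns)
#' @export
evaluate_cohort <- function(patients, scorer, k = c(1, 3, 5, 10),
                            n_random_rankings = 10) {
  per <- do.call(rbind, lapply(patients, function(p) {
    if (nrow(p$candidates) < 2L) stop("patient ", p$id, " has < 2 candidates")
    rr <- ranking_result(p, scorer(p), attr(scorer, "scorer"))
    data.frame(patient = p$id, novelty = p$novelty,
               n_candidates = nrow(p$candidates),
               causal_rank = rr$causal_rank, stringsAsFactors = FALSE)
  }))
  # seeded random-permutation baseline ranks, per patient
  rand_ranks <- lapply(patients, function(p) {
    n <- nrow(p$candidates)
    pos <- which(p$candidates$gene == p$gene)[1L]
    set.seed(substream_seed(877, p$id, 1L))
    vapply(seq_len(n_random_rankings), function(i) {
      which(sample.int(n) == pos)
    }, 1L)
  })
  cats <- c(novelty_categories(), "overall")
  summarize <- function(sel) {
    any_sel <- any(sel)
    row <- data.frame(n = sum(sel),
                      mean_rank = if (any_sel) mean(per$causal_rank[sel])
                                  else NA_real_)
    for (kk in k) {
      row[[paste0("top_", kk)]] <-
        if (any_sel) mean(per$causal_rank[sel] <= kk) else NA_real_
      row[[paste0("random_top_", kk)]] <- if (any_sel) {
        mean(vapply(which(sel), function(i) mean(rand_ranks[[i]] <= kk), 0))
      } else NA_real_
    }
    row
  }
  summary <- do.call(rbind, lapply(cats, function(cat) {
    sel <- if (cat == "overall") rep(TRUE, nrow(per)) else per$novelty == cat
    cbind(data.frame(category = cat), summarize(sel))
  }))
  rownames(summary) <- NULL
  list(per_patient = per, summary = summary)
}

#' Ablation arms of the component grid
#'
#' The named preset `"fig_grid"` covers: no components; each
#' phenotype-altering component alone (dropout, obfuscation, noise,
#' distractor-module phenotypes); all phenotype components without
#' distractor modules; distractor modules without phenotype components;
#' leave-one-module-out; and the full pipeline. All arms use uniform
#' module weights.
#'
#' @return named list of configuration modifier lists
#' @export
ablation_arms <- function() {
  base <- list(dropout = FALSE, obfuscation = FALSE, noise = FALSE,
               distractor_phenotypes = FALSE,
               modules_enabled = rep(FALSE, 6L))
  full <- list(dropout = TRUE, obfuscation = TRUE, noise = TRUE,
               distractor_phenotypes = TRUE,
               modules_enabled = rep(TRUE, 6L))
  arms <- list(
    none = base,
    dropout_only = utils::modifyList(base, list(dropout = TRUE)),
    obfuscation_only = utils::modifyList(base, list(obfuscation = TRUE)),
    noise_only = utils::modifyList(base, list(noise = TRUE)),
    distractor_phenotypes_only = utils::modifyList(
      full, list(dropout = FALSE, obfuscation = FALSE, noise = FALSE)),
    phenotype_only = utils::modifyList(
      base, list(dropout = TRUE, obfuscation = TRUE, noise = TRUE)),
    distractors_only = utils::modifyList(
      full, list(dropout = FALSE, obfuscation = FALSE, noise = FALSE,
                 distractor_phenotypes = TRUE)),
    full = full)
  for (m in 1:6) {
    en <- rep(TRUE, 6L)
    en[m] <- FALSE
    arms[[paste0("full_minus_module_", m)]] <-
      utils::modifyList(full, list(modules_enabled = en))
  }
  arms
}

#' Component-ablation report
#'
#' Simulates a cohort under each ablation arm (with uniform module
#' weights) on matched master seeds and reports the mean causal rank of a
#' fixed scorer per arm, averaged over seeds.
#'
#' @param kg a [knowledge_graph]
#' @param config base [sim_config] (its seed is replaced by `seeds`)
#' @param scorer scoring function from [make_scorer()]
#' @param arms named list of config modifiers (default [ablation_arms()])
#' @param seeds master seeds to average over
#' @return data.frame with columns `arm`, `mean_rank` (over all seeds
#'   pooled), and `n_patients`
#' @export
ablation_report <- function(kg, config = sim_config(), scorer,
                            arms = ablation_arms(), seeds = config$seed) {
  rows <- lapply(names(arms), function(a) {
    cfg <- config
    for (nm in names(arms[[a]])) cfg[[nm]] <- arms[[a]][[nm]]
    cfg$uniform_module_weights <- TRUE
    ranks <- unlist(lapply(seeds, function(s) {
      cfg$seed <- as.integer(s)
      cohort <- simulate_cohort(kg, cfg)
      evaluate_cohort(cohort, scorer)$per_patient$causal_rank
    }))
    data.frame(arm = a, mean_rank = mean(ranks), n_patients = length(ranks))
  })
  do.call(rbind, rows)
}

#' Jaccard nearest-neighbour retrieval curve
#'
#' For each query patient, ranks the reference patients by Jaccard
#' similarity of positive phenotype term sets and records the rank at
#' which the first same-disease reference appears. Returns, per rank r,
#' the cumulative fraction of queries matched by rank r, together with the
#' same curve under a seeded random ranking.
#'
#' @param queries,references lists of [simulated_patient]s sharing an
#'   ontology
#' @param seed seed for the random-ranking baseline
#' @return data.frame with columns `rank`, `jaccard`, `random`
#' @export
jaccard_retrieval <- function(queries, references, seed = 7L) {
  n_ref <- length(references)
  ref_dis <- vapply(references, function(p) p$disease, "")
  ref_sets <- lapply(references, function(p) p$positives)
  first_match <- function(ord, q_dis) {
    hit <- which(ref_dis[ord] == q_dis)
    if (length(hit) == 0L) Inf else hit[1L]
  }
  jac_rank <- numeric(length(queries))
  rnd_rank <- numeric(length(queries))
  set.seed(seed)
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    jac <- vapply(ref_sets, function(s) jaccard(q$positives, s), 0)
    jac_rank[i] <- first_match(order(-jac), q$disease)
    rnd_rank[i] <- first_match(sample.int(n_ref), q$disease)
  }
  data.frame(rank = seq_len(n_ref),
             jaccard = vapply(seq_len(n_ref),
                              function(r) mean(jac_rank <= r), 0),
             random = vapply(seq_len(n_ref),
                             function(r) mean(rnd_rank <= r), 0))
}

#' Jaccard similarity of two term sets
#'
#' @param a,b character vectors
#' @return `|a intersect b| / |a union b|` (0 when both sets are empty)
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Compare candidate-to-causal network distances between two cohorts
#'
#' For every patient, computes the shortest-path distance in an undirected
#' gene-gene interaction network from each noncausal candidate to the
#' causal gene (unreachable pairs and candidates absent from the network
#' are counted as a distinct "disconnected" class). Patients whose causal
#' gene is absent from the network are skipped and counted. The pooled
#' finite distances of the two cohorts are compared with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param patients_a,patients_b lists of [simulated_patient]s
#' @param network data.frame with columns `a`, `b` (undirected edges)
#' @return list with `distances_a`, `distances_b` (finite distances),
#'   `disconnected_a`, `disconnected_b`, `skipped_a`, `skipped_b`,
#'   `ks_statistic`, `ks_p`
#' @export
network_distance_comparison <- function(patients_a, patients_b, network) {
  g <- igraph::graph_from_data_frame(network[, c("a", "b")],
                                     directed = FALSE)
  vs <- igraph::V(g)$name
  cohort_distances <- function(patients) {
    finite <- numeric(0)
    disconnected <- 0L
    skipped <- 0L
    for (p in patients) {
      if (!p$gene %in% vs) {
        skipped <- skipped + 1L
        next
      }
      noncausal <- setdiff(p$candidates$gene, p$gene)
      present <- intersect(noncausal, vs)
      disconnected <- disconnected + length(noncausal) - length(present)
      if (length(present) == 0L) next
      d <- as.numeric(igraph::distances(g, v = p$gene, to = present))
      finite <- c(finite, d[is.finite(d)])
      disconnected <- disconnected + sum(!is.finite(d))
    }
    list(finite = finite, disconnected = disconnected, skipped = skipped)
  }
  a <- cohort_distances(patients_a)
  b <- cohort_distances(patients_b)
  if (length(a$finite) > 0 && length(b$finite) > 0) {
    ks <- suppressWarnings(stats::ks.test(a$finite, b$finite))
    ks_stat <- unname(ks$statistic)
    ks_p <- ks$p.value
  } else {
    ks_stat <- NA_real_
    ks_p <- NA_real_
  }
  list(distances_a = a$finite, distances_b = b$finite,
       disconnected_a = a$disconnected, disconnected_b = b$disconnected,
       skipped_a = a$skipped, skipped_b = b$skipped,
       ks_statistic = ks_stat, ks_p = ks_p)
}
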