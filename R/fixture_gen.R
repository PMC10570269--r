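#' Specification for a synthetic knowledge base
#'
#' Describes the size and planted structure of a self-contained synthetic
#' knowledge base: ontology shape, disease/gene/tissue counts, and novelty
#' quotas (how many diseases should fall into each post-timestamp novelty
#' category). Diseases are organised into phenotype-overlap blocks: diseases
#' within a block share a common weak phenotype term (so phenotypically
#' similar distractor diseases always exist), while diseases in different
#' blocks are phenotypically disjoint (so phenotypically distinct distractor
#' genes always exist).
#'
#' @param n_diseases number of diseases (> `block_size`, so that at least
#'   one disjoint block exists; the default keeps every module's candidate
#'   pool comfortably larger than its expected per-patient draw count under
#'   the default module weights, so configured weights are realizable)
#' @param block_size diseases per overlap block (>= 2)
#' @param n_genes total gene universe size (>= 100 so the expression
#'   neighbourhood module has its default top-100 pool)
#' @param frac_nondisease fraction of genes never causally associated with a
#'   disease
#' @param n_tissues number of tissues in the expression matrix
#' @param depth,branching ontology shape: complete `branching`-ary tree of
#'   the given depth below the root (`depth >= 2`)
#' @param extra_parent_frac fraction of deep terms receiving a second parent
#' @param quotas named integer vector of novelty quotas over
#'   [novelty_categories()]; unnamed categories default to 0 and
#'   `known_disease_known_gene` takes the remainder
#' @param n_claims_terms claims vocabulary size per age stratum
#' @param seed integer seed; the same spec always generates byte-identical
#'   tables
#' @return an object of class `fixture_spec`
#' @export
fixture_spec <- function(n_diseases = 36, block_size = 12, n_genes = 200,
                         frac_nondisease = 0.6, n_tissues = 8, depth = 3,
                         branching = 7, extra_parent_frac = 0.15,
                         quotas = c(known_disease_new_gene_link = 2,
                                    known_disease_undiscovered_gene = 2,
                                    novel_disease_known_gene = 2,
                                    novel_disease_undiscovered_gene = 2),
                         n_claims_terms = 40, seed = 42) {
  if (depth < 2) stop("ontology depth must be >= 2")
  if (block_size < 2) stop("block_size must be >= 2")
  if (n_diseases <= block_size) {
    stop("infeasible spec: n_diseases must exceed block_size so every ",
         "disease has a phenotypically disjoint disease")
  }
  if (any(c(n_diseases, n_genes, n_tissues, n_claims_terms) <= 0)) {
    stop("all counts must be positive")
  }
  bad <- setdiff(names(quotas), novelty_categories())
  if (length(bad) > 0) stop("unknown novelty categories in quotas: ",
                            paste(bad, collapse = ", "))
  full <- stats::setNames(integer(5), novelty_categories())
  full[names(quotas)] <- as.integer(quotas)
  planted <- sum(full[setdiff(novelty_categories(), "known_disease_known_gene")])
  rest <- n_diseases - planted
  if (rest < 0) stop("infeasible spec: novelty quotas exceed n_diseases")
  if (full["known_disease_known_gene"] == 0L) {
    full["known_disease_known_gene"] <- rest
  } else if (full["known_disease_known_gene"] != rest) {
    stop("infeasible spec: known_disease_known_gene quota must equal the ",
         "remainder after the planted categories (", rest, ")")
  }
  needs_host <- full["known_disease_new_gene_link"] +
    full["novel_disease_known_gene"] > 0
  if (needs_host && full["known_disease_known_gene"] < 1) {
    stop("infeasible spec: *_known_gene plants need at least one ",
         "known_disease_known_gene host disease")
  }
  n_terms <- sum(branching ^ (0:depth))
  n_blocks <- ceiling(n_diseases / block_size)
  need_terms <- 7L * n_diseases + n_blocks + 10L + 1L
  if (n_terms < need_terms) {
    stop("infeasible spec: ontology has ", n_terms, " terms but the planted ",
         "annotations need at least ", need_terms)
  }
  if (n_genes < 100) {
    stop("infeasible spec: n_genes must be >= 100 so the expression ",
         "similarity module has its default top-100 pool")
  }
  n_nondisease <- round(frac_nondisease * n_genes)
  need_nd <- 3L * n_diseases + 10L
  if (n_nondisease < need_nd) {
    stop("infeasible spec: need at least ", need_nd, " non-disease genes ",
         "(3 insufficiently-explanatory per disease + 10 incidental)")
  }
  if (n_genes - n_nondisease < n_diseases) {
    stop("infeasible spec: not enough disease genes for one causal gene ",
         "per disease")
  }
  structure(list(n_diseases = n_diseases, block_size = block_size,
                 n_genes = n_genes, frac_nondisease = frac_nondisease,
                 n_tissues = n_tissues, depth = depth, branching = branching,
                 extra_parent_frac = extra_parent_frac, quotas = full,
                 n_claims_terms = n_claims_terms, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic phenotype ontology
#'
#' Builds a complete `branching`-ary is-a tree of the requested depth below
#' a single root, then gives a random fraction of the deeper terms a second
#' parent drawn from a strictly shallower level (keeping the graph a DAG).
#' Fully deterministic given the spec's seed.
#'
#' @param spec a [fixture_spec]
#' @param seed overriding seed (defaults to `spec$seed`)
#' @return an [ontology]
#' @export
gen_ontology <- function(spec, seed = spec$seed) {
  set.seed(seed)
  levels <- list("HP:0000001")
  next_id <- 2L
  for (l in seq_len(spec$depth)) {
    n <- spec$branching ^ l
    ids <- sprintf("HP:%07d", seq(next_id, next_id + n - 1L))
    next_id <- next_id + n
    levels[[l + 1L]] <- ids
  }
  ids <- unlist(levels)
  parents <- stats::setNames(vector("list", length(ids)), ids)
  parents[["HP:0000001"]] <- character(0)
  for (l in seq_len(spec$depth)) {
    kids <- levels[[l + 1L]]
    up <- levels[[l]]
    for (i in seq_along(kids)) {
      parents[[kids[i]]] <- up[((i - 1L) %/% spec$branching) + 1L]
    }
  }
  deep <- unlist(levels[-(1:2)])
  extra <- deep[stats::runif(length(deep)) < spec$extra_parent_frac]
  for (t in extra) {
    lvl <- which(vapply(levels, function(x) t %in% x, TRUE))
    pool <- setdiff(unlist(levels[2:(lvl - 1L)]), parents[[t]])
    if (length(pool) > 0) {
      parents[[t]] <- c(parents[[t]], pool[sample.int(length(pool), 1L)])
    }
  }
  ontology(ids = ids, names = paste("synthetic term", seq_along(ids)),
           parents = parents, root = "HP:0000001")
}

#' Generate a synthetic knowledge base with planted structure
#'
#' Emits a [knowledge_graph] in which every simulatable disease is viable
#' for all six distractor gene modules (audited with
#' [audit_module_viability()] before returning), all five prevalence buckets
#' occur, and discovery dates are planted so that [classify_novelty()]
#' recovers exactly the novelty quotas in the spec. Claims prevalences decay
#' Zipf-like within each age stratum, mirroring heavy-tailed billing-code
#' frequencies; expression vectors are drawn from a small number of latent
#' tissue programs so cosine-similarity neighbourhoods are nontrivial.
#'
#' @param spec a [fixture_spec]
#' @return a [knowledge_graph], with attribute `"planted_novelty"` naming
#'   each disease's planted category
#' @export
gen_knowledge_base <- function(spec) {
  ont <- gen_ontology(spec)        # seeds the RNG stream
  n_d <- spec$n_diseases
  ts <- as.Date("2015-02-01")

  pool <- setdiff(ont$ids, ont$root)
  pool <- sample(pool)             # shuffle once; allocate disjoint slices
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  n_blocks <- ceiling(n_d / spec$block_size)
  block_of <- rep(seq_len(n_blocks), each = spec$block_size)[seq_len(n_d)]
  shared_weak <- take(n_blocks)    # one weak term shared by a whole block
  incidental_terms <- take(10L)    # annotated only to incidental genes

  disease_ids <- sprintf("ORPHA:%d", 1000L + seq_len(n_d))
  n_nd <- round(spec$frac_nondisease * spec$n_genes)
  gene_ids <- sprintf("ENSG%011d", seq_len(spec$n_genes))
  causal_genes <- gene_ids[seq_len(n_d)]
  nd_start <- spec$n_genes - n_nd
  nondisease <- gene_ids[(nd_start + 1L):spec$n_genes]
  m3_genes <- nondisease[seq_len(3L * n_d)]
  m4_genes <- nondisease[(3L * n_d + 1L):(3L * n_d + 10L)]
  other_genes <- gene_ids[(n_d + 1L):nd_start]

  # planted novelty categories, in fixed disease order
  cats <- rep(names(spec$quotas), spec$quotas)
  cats <- c(cats[cats == "known_disease_known_gene"],
            cats[cats != "known_disease_known_gene"])
  kdkg_ids <- disease_ids[cats == "known_disease_known_gene"]

  diseases <- vector("list", n_d)
  gene_disease <- list()
  gene_phenotype <- list()
  host_i <- 0L
  next_host <- function() {
    host_i <<- host_i + 1L
    kdkg_ids[((host_i - 1L) %% length(kdkg_ids)) + 1L]
  }

  for (i in seq_len(n_d)) {
    priv <- take(7L)
    phen <- stats::setNames(
      c(1.0, 0.895, 0.85, 0.545, 0.17, 0.25, 0.0, 0.1),
      c(priv, shared_weak[block_of[i]]))
    cat_i <- cats[i]
    d_date <- if (startsWith(cat_i, "novel")) {
      as.Date("2016-01-01") + sample.int(700L, 1L)
    } else {
      as.Date("2005-01-01") + sample.int(3000L, 1L)
    }
    e_date <- if (cat_i == "known_disease_known_gene") d_date
              else max(d_date, as.Date("2016-06-01") + sample.int(400L, 1L))
    g <- causal_genes[i]
    diseases[[i]] <- disease_record(
      id = disease_ids[i], name = paste("synthetic disease", i),
      classification = "disorder", genes = g, phenotypes = phen,
      ages = sort(sample(age_categories(), sample.int(3L, 1L))),
      date = d_date)
    gene_disease[[length(gene_disease) + 1L]] <-
      data.frame(gene = g, disease = disease_ids[i], date = e_date)
    if (cat_i %in% c("known_disease_new_gene_link", "novel_disease_known_gene")) {
      host <- next_host()
      gene_disease[[length(gene_disease) + 1L]] <-
        data.frame(gene = g, disease = host, date = as.Date("2010-06-01"))
    }
    # three insufficiently-explanatory genes: nonempty strict subsets of
    # the disease's three weak terms
    weak_terms <- names(phen)[bucket_prevalence(phen) == "weak"]
    gene_phenotype[[m3_genes[3L * i - 2L]]] <- weak_terms[1L]
    gene_phenotype[[m3_genes[3L * i - 1L]]] <- weak_terms[2L]
    gene_phenotype[[m3_genes[3L * i]]] <- sort(weak_terms[1:2])
  }
  names(diseases) <- disease_ids
  gene_disease <- do.call(rbind, gene_disease)
  # hosts gain the planted second causal gene
  for (j in seq_len(nrow(gene_disease))) {
    d <- gene_disease$disease[j]
    diseases[[d]]$genes <- sort(unique(c(diseases[[d]]$genes,
                                         gene_disease$gene[j])))
  }

  for (g in m4_genes) {
    gene_phenotype[[g]] <- sort(sample(incidental_terms, sample.int(2L, 1L)))
  }
  # causal genes inherit their disease's positive phenotype terms
  for (i in seq_len(n_d)) {
    phen <- diseases[[i]]$phenotypes
    terms <- sort(names(phen)[phen > 0])
    g <- causal_genes[i]
    gene_phenotype[[g]] <- sort(unique(c(gene_phenotype[[g]], terms)))
  }

  # expression: latent tissue programs + noise, TPM-like scale
  programs <- matrix(stats::runif(4L * spec$n_tissues, 0.05, 1), nrow = 4L)
  assign <- sample.int(4L, spec$n_genes, replace = TRUE)
  expr <- programs[assign, , drop = FALSE] *
    stats::rlnorm(spec$n_genes, meanlog = 3, sdlog = 1) +
    matrix(abs(stats::rnorm(spec$n_genes * spec$n_tissues, sd = 0.5)),
           nrow = spec$n_genes)
  rownames(expr) <- gene_ids
  colnames(expr) <- paste0("tissue_", seq_len(spec$n_tissues))

  flags_genes <- sort(sample(other_genes, min(6L, length(other_genes))))
  flags <- data.frame(gene = flags_genes,
                      count = 50 + stats::rpois(length(flags_genes), 150))

  # sparse interaction network, mean degree ~4
  n_edges <- 2L * spec$n_genes
  a <- sample(gene_ids, n_edges, replace = TRUE)
  b <- sample(gene_ids, n_edges, replace = TRUE)
  keep <- a != b
  ge <- unique(data.frame(a = pmin(a[keep], b[keep]),
                          b = pmax(a[keep], b[keep])))

  claims <- do.call(rbind, lapply(age_categories(), function(s) {
    vocab <- sample(ont$ids[ont$ids != ont$root], spec$n_claims_terms)
    data.frame(stratum = s, term = vocab,
               prevalence = 0.5 / seq_len(spec$n_claims_terms) ^ 0.8)
  }))

  kg <- knowledge_graph(
    ontology = ont, diseases = diseases, gene_phenotype = gene_phenotype,
    gene_disease = gene_disease, gene_gene = ge,
    nondisease_genes = nondisease, flags = flags, expression = expr,
    claims = claims, timestamp = ts)
  attr(kg, "planted_novelty") <- stats::setNames(cats, disease_ids)

  audit <- audit_module_viability(kg)
  if (any(audit[, -1] < 1)) {
    stop("infeasible spec: generated knowledge base failed the distractor ",
         "viability audit")
  }
  kg
}

#' Audit distractor-module viability per disease
#'
#' For each simulatable disease, counts the candidate pool available to each
#' of the six distractor gene modules (eligible phenotypically-similar
#' disease/gene pairs; phenotypically disjoint disease genes;
#' insufficiently-explanatory non-disease genes; incidental-phenotype
#' non-disease genes; expression neighbours of each causal gene; weighted
#' frequently-mutated genes). A generated knowledge base must have every
#' count >= 1.
#'
#' @param kg a [knowledge_graph]
#' @return data.frame with one row per simulatable disease and columns
#'   `disease`, `m1` .. `m6`
#' @export
audit_module_viability <- function(kg) {
  ctx <- build_distractor_context(kg)
  sims <- select_simulatable_diseases(kg)
  rows <- lapply(names(sims), function(id) {
    d <- sims[[id]]
    m5 <- min(vapply(d$genes, function(g) {
      length(expression_neighbours(ctx, g, exclude = g,
                                   overlap_excluded = ctx$m5_excluded[[id]])$gene)
    }, 1L))
    data.frame(disease = id,
               m1 = nrow(ctx$m1_pairs[[id]]),
               m2 = length(ctx$m2_genes[[id]]),
               m3 = length(ctx$m3_genes[[id]]),
               m4 = length(ctx$m4_genes[[id]]),
               m5 = m5,
               m6 = sum(kg$flags$count > 0))
  })
  do.call(rbind, rows)
}
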