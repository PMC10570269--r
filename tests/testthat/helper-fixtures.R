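# Shared fixtures and independent oracles.

# -- tiny hand-built ontologies -------------------------------------------

# root -> A -> B chain
chain_ontology <- function() {
  ontology(ids = c("HP:1", "HP:2", "HP:3"),
           names = c("root", "A", "B"),
           parents = list("HP:1" = character(0), "HP:2" = "HP:1",
                          "HP:3" = "HP:2"))
}

# root with two mid terms; leaf has both as parents (diamond)
diamond_ontology <- function() {
  ontology(ids = c("HP:1", "HP:2", "HP:3", "HP:4"),
           parents = list("HP:1" = character(0), "HP:2" = "HP:1",
                          "HP:3" = "HP:1", "HP:4" = c("HP:2", "HP:3")))
}

# random rooted DAG with n terms; every non-root term gets 1-2 parents
# among earlier terms (so term 1 is the root and the graph is acyclic)
random_dag <- function(n = 50, p_second_parent = 0.3) {
  ids <- sprintf("HP:%04d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  parents[[ids[1]]] <- character(0)
  for (i in 2:n) {
    ps <- ids[sample.int(i - 1L, 1L)]
    if (i > 2 && stats::runif(1) < p_second_parent) {
      ps <- unique(c(ps, ids[sample.int(i - 1L, 1L)]))
    }
    parents[[ids[i]]] <- ps
  }
  ontology(ids = ids, parents = parents)
}

# -- independent oracles ---------------------------------------------------

# ancestor closure by plain recursive DFS over the parent lists
bf_ancestors <- function(parents, term) {
  seen <- character(0)
  visit <- function(t) {
    if (t %in% seen) return(invisible(NULL))
    seen <<- c(seen, t)
    for (p in parents[[t]]) visit(p)
  }
  visit(term)
  sort(seen)
}

# reachability closure by boolean matrix powers
bf_closure_matrix <- function(o) {
  n <- length(o$ids)
  adj <- matrix(FALSE, n, n, dimnames = list(o$ids, o$ids))
  for (t in o$ids) adj[t, o$parents[[t]]] <- TRUE
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# information content by brute-force descendant counting: for each term,
# count entities annotated (raw) to the term or any of its descendants
bf_information_content <- function(entity_terms, o) {
  reach <- bf_closure_matrix(o)
  n <- length(entity_terms)
  ic <- c()
  for (t in o$ids) {
    descendants <- o$ids[reach[, t]]  # terms whose closure contains t
    m <- sum(vapply(entity_terms,
                    function(ts) any(ts %in% descendants), TRUE))
    if (m > 0) ic[t] <- -log2(m / n)
  }
  ic
}

# Phrank similarity by explicit enumeration of the two ancestor closures
bf_phrank <- function(set_a, set_b, entity_terms, o) {
  ic <- bf_information_content(entity_terms, o)
  cl <- function(ts) {
    sort(unique(unlist(lapply(ts, function(t) bf_ancestors(o$parents, t)))))
  }
  shared <- intersect(cl(set_a), cl(set_b))
  sum(ic[intersect(shared, names(ic))])
}

# -- shared generated knowledge base --------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

fixture_kg <- function(seed = 101) {
  key <- as.character(seed)
  kg <- get0(key, envir = .fixture_cache, ifnotfound = NULL)
  if (is.null(kg)) {
    kg <- gen_knowledge_base(fixture_spec(seed = seed))
    assign(key, kg, envir = .fixture_cache)
  }
  kg
}

first_simulatable <- function(kg) {
  select_simulatable_diseases(kg)[[1]]
}

# -- Alstrom/Wolfram-style eligibility fixture -----------------------------
#
# A true disease and a distractor disease overlapping in 5 terms, 3 of them
# weak for the distractor (the other 2 strong). The distractor has 5 strong
# and 33 weak terms and no obligate or excluded terms, so module-1
# eligibility can only hold through the weak-overlap clause, under which
# only the weak overlap terms are added to the patient.
alstrom_style_kb <- function() {
  n <- 60
  ids <- sprintf("HP:%04d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  parents[[ids[1]]] <- character(0)
  for (i in 2:n) parents[[ids[i]]] <- ids[1]
  o <- ontology(ids = ids, parents = parents)

  strong_terms <- ids[2:6]     # distractor: 5 strong
  weak_terms <- ids[7:39]      # distractor: 33 weak
  overlap <- c(weak_terms[1:3], strong_terms[1:2])  # 5-term overlap, 3 weak
  true_only <- ids[40:45]

  distractor_phen <- c(stats::setNames(rep(0.9, 5), strong_terms),
                       stats::setNames(rep(0.1, 33), weak_terms))
  true_phen <- c(stats::setNames(rep(0.8, length(overlap)), overlap),
                 stats::setNames(rep(1.0, length(true_only)), true_only))

  diseases <- list(
    disease_record("ORPHA:T", "true disease", genes = "G_TRUE",
                   phenotypes = true_phen, ages = "adult",
                   date = as.Date("2004-01-01")),
    disease_record("ORPHA:D", "distractor disease", genes = "G_DIST",
                   phenotypes = distractor_phen, ages = "adult",
                   date = as.Date("2001-01-01")))
  knowledge_graph(
    ontology = o, diseases = diseases,
    gene_disease = data.frame(gene = c("G_TRUE", "G_DIST"),
                              disease = c("ORPHA:T", "ORPHA:D"),
                              date = as.Date(c("2004-01-01", "2001-01-01"))),
    claims = data.frame(stratum = "adult", term = ids[46:55],
                        prevalence = 0.5 / (1:10)),
    timestamp = as.Date("2015-02-01"))
}
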