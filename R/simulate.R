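#' Cohort simulation configuration
#'
#' Bundles everything a cohort run needs: replicates per disease, the
#' imprecision and distractor parameters, component toggles for ablations,
#' and the master seed. Per-patient random substreams are derived from the
#' master seed, the disease id, and the replicate index, so cohorts are
#' reproducible and independent of iteration order.
#'
#' @param patients_per_disease replicates per simulatable disease (>= 1)
#' @param imprecision an [imprecision_params]
#' @param distractor a [distractor_params]
#' @param dropout,obfuscation,noise enable the phenotype-altering operators
#' @param distractor_phenotypes allow the distractor modules to add
#'   phenotype terms (when `FALSE` the modules run gene-only)
#' @param modules_enabled logical vector of length 6: which distractor
#'   modules are active (disabled modules are backfilled with random genes)
#' @param uniform_module_weights ablation flag: give all enabled modules
#'   equal sampling probability
#' @param seed master seed (integer)
#' @return an object of class `sim_config`
#' @export
sim_config <- function(patients_per_disease = 20,
                       imprecision = imprecision_params(),
                       distractor = distractor_params(),
                       dropout = TRUE, obfuscation = TRUE, noise = TRUE,
                       distractor_phenotypes = TRUE,
                       modules_enabled = rep(TRUE, 6L),
                       uniform_module_weights = FALSE, seed = 1L) {
  if (patients_per_disease < 1) stop("patients_per_disease must be >= 1")
  if (length(modules_enabled) != 6L) {
    stop("modules_enabled must have length 6")
  }
  structure(list(patients_per_disease = as.integer(patients_per_disease),
                 imprecision = imprecision, distractor = distractor,
                 dropout = isTRUE(dropout), obfuscation = isTRUE(obfuscation),
                 noise = isTRUE(noise),
                 distractor_phenotypes = isTRUE(distractor_phenotypes),
                 modules_enabled = as.logical(modules_enabled),
                 uniform_module_weights = isTRUE(uniform_module_weights),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Stable 31-bit hash of (master seed, disease id, replicate) for
# order-independent per-patient random substreams.
substream_seed <- function(seed, disease, replicate) {
  key <- sprintf("%d|%s|%d", as.integer(seed), disease, as.integer(replicate))
  h <- 7
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Effective distractor params under the config's ablation flags.
effective_distractor_params <- function(config) {
  par <- config$distractor
  if (config$uniform_module_weights) {
    w <- as.numeric(config$modules_enabled)
    if (sum(w) == 0) w <- rep(1, 6)
    par$weights <- w / sum(w)
  }
  par$gene_only <- par$gene_only || !config$distractor_phenotypes
  par
}

#' Simulate one patient
#'
#' Runs the full per-patient pipeline: initialization from the disease
#' record, then (as enabled) phenotype dropout, obfuscation, and claims
#' noise, then distractor gene attachment, and finally novelty
#' classification of the causal gene-disease pair against the knowledge
#' graph's timestamp.
#'
#' @param d a simulatable [disease_record]
#' @param kg a [knowledge_graph]
#' @param config a [sim_config]
#' @param ctx optional precomputed [build_distractor_context()]
#' @param id patient identifier
#' @return a [simulated_patient]
#' @export
simulate_patient <- function(d, kg, config = sim_config(), ctx = NULL,
                             id = paste0(d$id, "_p1")) {
  patient <- init_patient(d, kg, id = id)
  if (config$dropout) patient <- apply_dropout(patient, config$imprecision)
  if (config$obfuscation) {
    patient <- apply_obfuscation(patient, kg$ontology, config$imprecision)
  }
  if (config$noise) patient <- apply_noise(patient, kg$claims,
                                           config$imprecision)
  patient <- attach_distractors(patient, kg,
                                params = effective_distractor_params(config),
                                ctx = ctx, enabled = config$modules_enabled)
  patient$novelty <- classify_novelty(kg, patient$gene, patient$disease)
  patient
}

#' Simulate a cohort
#'
#' Simulates `patients_per_disease` replicates for every simulatable
#' disease. Each patient runs in its own random substream seeded from
#' (master seed, disease id, replicate index), so two runs with the same
#' master seed produce identical cohorts regardless of disease ordering.
#'
#' @param kg a [knowledge_graph]
#' @param config a [sim_config]
#' @return list of [simulated_patient]s, ordered by disease id then
#'   replicate
#' @export
simulate_cohort <- function(kg, config = sim_config()) {
  diseases <- select_simulatable_diseases(kg)
  ctx <- build_distractor_context(kg)
  out <- vector("list", length(diseases) * config$patients_per_disease)
  i <- 0L
  for (id in names(diseases)) {
    for (rep in seq_len(config$patients_per_disease)) {
      set.seed(substream_seed(config$seed, id, rep))
      i <- i + 1L
      out[[i]] <- simulate_patient(diseases[[id]], kg, config, ctx = ctx,
                                   id = sprintf("%s_p%d", id, rep))
    }
  }
  out
}

#' Write patients as JSON Lines
#'
#' One JSON object per line with fields `id`, `disease`, `gene`, `age`,
#' `novelty`, `positives`, `negatives`, and `candidates` (array of
#' \{`gene`, `provenance`\} objects, order preserved). Lossless against
#' [read_patients()].
#'
#' @param patients list of [simulated_patient]s
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_patients <- function(patients, path) {
  lines <- vapply(patients, function(p) {
    jsonlite::toJSON(list(
      id = jsonlite::unbox(p$id), disease = jsonlite::unbox(p$disease),
      gene = jsonlite::unbox(p$gene), age = jsonlite::unbox(p$age),
      novelty = jsonlite::unbox(p$novelty),
      positives = p$positives, negatives = p$negatives,
      candidates = data.frame(gene = p$candidates$gene,
                              provenance = p$candidates$provenance)),
      null = "null", na = "null")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con)
  invisible(path)
}

#' Read patients from JSON Lines
#'
#' @param path file written by [write_patients()]
#' @return list of [simulated_patient]s
#' @details A malformed or schema-violating line raises an error naming the
#'   line number.
#' @export
read_patients <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[lines != ""]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("line ", i, ": invalid JSON: ",
                           conditionMessage(e), call. = FALSE)
                    })
    need <- c("id", "disease", "gene", "age", "novelty", "positives",
              "negatives", "candidates")
    missing <- setdiff(need, names(rec))
    if (length(missing) > 0) {
      stop("line ", i, ": missing fields: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    cand <- as.data.frame(rec$candidates)
    if (!all(c("gene", "provenance") %in% names(cand))) {
      stop("line ", i, ": candidates must have gene and provenance",
           call. = FALSE)
    }
    tryCatch(
      simulated_patient(
        id = rec$id, disease = rec$disease, gene = rec$gene, age = rec$age,
        positives = as.character(unlist(rec$positives)),
        negatives = as.character(unlist(rec$negatives)),
        candidates = data.frame(gene = as.character(cand$gene),
                                provenance = as.character(cand$provenance),
                                stringsAsFactors = FALSE),
        novelty = rec$novelty),
      error = function(e) stop("line ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  })
}
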