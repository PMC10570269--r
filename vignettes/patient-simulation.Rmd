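---
title: "Simulating difficult-to-diagnose rare-disease patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating difficult-to-diagnose rare-disease patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Automated gene-prioritization tools for suspected Mendelian disorders are
usually benchmarked on patients whose causal gene–disease association is
already well documented, which overstates how useful the tools are for the
patients who need them most: those with atypical presentations or novel
genetic conditions. `phenosim` simulates such difficult-to-diagnose
patients. Each simulated patient is an age category, a set of *positive*
phenotype terms (symptoms exhibited), a set of *negative* terms (assessed
and absent), and a list of candidate genes of which exactly one is causal.
The package also re-implements two information-content phenotype-similarity
rankers and the evaluation/ablation harness needed to study them on the
simulated cohorts.

## The simulation model

### Initialization

A patient is assigned a disease drawn from the knowledge base, restricted
to *simulatable* diseases: not a bare classification category, at least one
phenotype annotation and at least one causal gene (subtypes missing exactly
one of these inherit it from their parent disease first). The causal gene
is a uniform draw from the disease's causal genes — the knowledge bases we
model do not say which gene a multi-gene disease patient should carry, so
uniform is the least-informative choice — and the age category is a uniform
draw from the disease's age-of-onset ranges. Every annotated term `t` then
lands in the positive set with probability `P(t | disease)` (its annotated
prevalence) and in the negative set otherwise, so at this stage
`positives ∪ negatives` is exactly the annotation set. Sex is not modelled.

Qualitative Orphanet-style frequency classes are mapped at load time to
representative point fractions (Obligate 1.0, Very frequent 0.895, Frequent
0.545, Occasional 0.17, Very rare 0.025, Excluded 0.0) because Bernoulli
sampling needs point probabilities.

### Diagnostic imprecision

Three operators degrade the initialized patient, in a fixed order chosen to
mirror a clinical workup (symptoms are partially observed, then recorded
imprecisely, then mixed with unrelated complaints):

1. **Dropout** — each positive term is removed with probability 0.7, each
   negative with 0.2. Removal is unconditional and independent; a patient
   may lose every disease phenotype, and no re-draw is performed.
2. **Obfuscation** — each surviving term is replaced, with probability 0.15
   per set, by one uniformly chosen parent term ("arachnodactyly" becomes
   "long fingers"). The ontology root is never used as a replacement — that
   would erase the observation rather than generalize it — so a term whose
   only parent is the root stays unchanged. Collisions deduplicate (term
   sets, not multisets), and a replacement already asserted negative stays
   out of the positive set: negatives represent clinician-asserted
   absences and always win conflicts.
3. **Noise** — `1 + Poisson(λ_pos)` new positive terms are drawn without
   replacement from the patient's age stratum of a claims-derived
   prevalence table, with probability proportional to prevalence, and
   `1 + Poisson(λ_neg)` negative terms uniformly from the same stratum's
   vocabulary, always excluding terms already present. The five age strata
   (infant 0–1 y, child 2–11, adolescent 12–18, adult 19–64, senior 65+)
   map one-to-one onto the claims table's strata.

The "1 + Poisson" form guarantees the operator always does something while
keeping the count distribution simple; defaults `λ_pos = 2`, `λ_neg = 1`
were chosen once so that fixture-scale cohorts end with positive/negative
counts in the mid-teens range typical of deeply phenotyped rare-disease
patients, and are exposed in `imprecision_params()`.

### Distractor candidate genes

The candidate list holds the causal gene plus `1 + N_G` noncausal genes,
`N_G ~ Poisson(λ_G)`. The default `λ_G = 12` gives a mean list length of
14, matching the candidate counts reported for deeply investigated
undiagnosed patients. Each noncausal slot is assigned one of six modules by
a categorical draw with default weights (0.33, 0.42, 0.05, 0.09, 0.08,
0.03):

1. **Phenotypically-similar disease genes** — a gene causing another
   disease whose annotations overlap the true disease's (overlap is
   computed on raw annotated term sets with positive prevalence, no
   ancestor expansion, because the motivating overlap counts are stated at
   the term level). Overlapping terms join the positives. To guarantee the
   gene is definitively noncausal, some of the distractor's *excluded*
   (prevalence 0) terms join the positives and some of its *obligate*
   (prevalence 1) terms join the negatives. A distractor with neither
   obligate nor excluded terms qualifies only through its *weak*
   (prevalence 1–29%) overlapping terms: then only the weak overlap terms
   are added, and some strong non-overlapping terms join the negatives
   instead.
2. **Phenotypically-distinct disease genes** — a gene all of whose
   diseases share no terms with the true disease. No phenotype
   side-effects.
3. **Insufficiently explanatory genes** — a non-disease gene annotated to
   a nonempty strict subset of the true disease's weak terms. Some of its
   terms join the positives, but only when none of them are already
   positive (if any is, the patient already "explains" the gene and adding
   more would overstate it).
4. **Incidental-phenotype genes** — a non-disease gene annotated only to
   terms disjoint from the true disease; some of its terms join the
   positives.
5. **Similarly expressed genes** — expression vectors are min-max
   normalized per tissue across all genes; one of the causal gene's top
   100 cosine-similarity neighbours is sampled with probability
   proportional to similarity, excluding disease genes that phenotypically
   overlap the true disease. No phenotype side-effects.
6. **Common false-positive genes** — a frequently-mutated-gene drawn with
   probability proportional to its rare functional variant count.

Every phenotype side-effect adds `1 + Poisson(λ_P)` terms (default
`λ_P = 1`), truncated to availability. Only modules 1, 3 and 4 ever touch
phenotype sets; an ablation flag (`gene_only`) suppresses even those.

A slot whose module has no candidate left is redrawn from the renormalized
module weights up to 10 times and then backfilled with a uniformly random
unused gene labelled `random_backfill` — this keeps the candidate-list
length distribution exactly `2 + N_G` without biasing the viable modules.
Disabled modules backfill immediately, so module-removal ablations hold the
list length constant. The final list is shuffled with provenance labels
retained.

### Novelty with respect to a time-stamped knowledge graph

Gene–disease edges and diseases carry discovery dates; the knowledge graph
carries a timestamp (2015-02-01 by default, the freeze date this line of
benchmarking standardizes on). A causal pair is classified into one of five
categories — known disease/known gene, known disease/new gene link, known
disease/undiscovered gene, novel disease/known gene, novel
disease/undiscovered gene — using only edges dated at or before the
timestamp. Records without dates raise an error rather than silently
counting as "known", because these labels drive the headline evaluation.
Causal genes imputed into a subtype inherit the parent's edge dates, since
the association was discovered through the parent disease.

## Gene prioritization

`annotation_corpus()` propagates entity→term annotations through the
ancestor closure and defines the information content
`IC(t) = −log2(|entities annotated to t or any descendant| / |entities|)`,
so `IC(root) = 0` and IC never increases toward ancestors. The
Phrank-style similarity of two term sets is the summed IC over the
intersection of their ancestor closures; genes are ranked either against
their own annotations (`gene` mode) or against the best of their associated
diseases (`disease` mode). The Phenomizer-style score is the one-sided
best-match average: the mean over patient terms of the IC of the most
informative common ancestor with any disease term, with an empirical
p-value from 10,000 random term sets of the same cardinality using the
add-one convention `(b + 1)/(n + 1)` (p is never exactly 0). Disease term
sets used for scoring exclude prevalence-0 annotations: an "excluded" term
is an assertion of absence, not an annotation.

All scorers see only the knowledge view at the timestamp. Tied scores
receive the mean of their rank positions, which makes ranks independent of
candidate order and unbiased for mean-rank reporting.

## The synthetic knowledge base

No external downloads are required: `gen_knowledge_base()` emits a complete
knowledge base (OBO ontology plus all TSV tables) with planted structure,
and `write_knowledge_graph()`/`load_knowledge_graph()` round-trip it
byte-deterministically for a fixed seed.

Diseases are organised into phenotype-overlap blocks: the diseases of a
block share one weak term (so phenotypically-similar distractors always
exist) while different blocks are disjoint (so phenotypically-distinct
distractors always exist). Each disease carries all five prevalence buckets
(one obligate, two strong, one moderate, three weak including the shared
one, one excluded). Per disease, three non-disease genes are annotated to
strict subsets of its weak terms, and a shared pool of non-disease genes is
annotated only to terms no disease uses. Expression vectors are drawn from
four latent tissue programs with lognormal scale and positive noise, so
cosine neighbourhoods are informative; claims prevalences decay Zipf-like
within each age stratum, mirroring heavy-tailed billing-code frequencies.
Novelty quotas are planted by assigning post-timestamp dates; genes for the
"known gene" categories receive an additional pre-timestamp edge to a host
disease.

The default sizes (36 diseases in three blocks of 12, 200 genes, a depth-3
breadth-7 ontology) were chosen so that every module's candidate pool
comfortably exceeds its expected per-patient draw count under the default
weights — otherwise pool exhaustion would systematically distort the
provenance mix — and so that full test and evaluation runs remain a matter
of seconds to minutes. `audit_module_viability()` verifies the guarantee
and the generator refuses to emit an infeasible knowledge base.

What the generator does *not* emulate: real HPO/Orphanet marginal
statistics (term-set sizes, annotation depth, disease-category structure),
correlated comorbidity patterns in claims data, or realistic
protein-interaction topology. Passing tests therefore demonstrate the
correctness and internal consistency of the simulation and scoring
machinery, not that any particular external snapshot will reproduce
cohort-level statistics.

## Determinism and numerical choices

* Every patient runs in its own random substream seeded by a stable hash
  of (master seed, disease id, replicate index); cohorts are byte-identical
  across runs and independent of disease iteration order.
* Weighted sampling without replacement is sequential (draw, remove,
  renormalize); zero-weight items are never drawn.
* Degenerate inputs fail loudly: prevalences outside [0, 1], cyclic is-a
  graphs, multiple ontology roots, missing discovery dates, claims strata
  smaller than a requested draw (truncated with a warning).
* Evaluation problem sizes used by the packaged checks: cohorts of 20
  patients per disease for distribution checks, 10,000 patients for
  dropout-retention and provenance-frequency estimates, 1,000 random-DAG
  comparisons against brute-force closure oracles, and ablation grids of
  3 patients per disease across 5 matched seeds.

## Known limitations

* Patients are monogenic; multi-gene (or multi-disease) patients are out
  of scope.
* Candidate genes abstract away variant-level evidence (inheritance,
  consequence, allele frequency); the simulation assumes candidates were
  shortlisted because compelling variants lie in them.
* External tools (likelihood-ratio or interaction-network rankers) are not
  re-implemented; their pre-computed per-patient score tables can be
  ingested with `make_scorer(method = "external")` and evaluated
  identically.
* The Phenomizer-style score is one-sided (patient → disease); symmetric
  best-match averaging is a possible variant not currently exposed.
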