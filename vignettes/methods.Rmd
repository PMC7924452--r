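---
title: "Similarity-fusion drug repurposing and FAIR workflow provenance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-fusion drug repurposing and FAIR workflow provenance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repurpose)
```

## The prediction problem

Drug repurposing asks which approved drugs might treat which diseases. The
guilt-by-association heuristic behind this package is that *similar drugs
treat similar diseases*: a candidate pair (d, s) is promising when some
known indication (d', s') pairs a drug similar to d with a disease similar
to s. The package scores candidate pairs by

1. computing five drug–drug similarity matrices — chemical fingerprints
   (Tanimoto/Jaccard on bit-sets), shared side effects (Jaccard on term
   sets), target protein sequences (normalised Smith–Waterman), target GO
   annotations (Resnik best-match-average), and target closeness in the
   protein–protein interaction network (exponential decay of shortest-path
   length) — and two disease–disease matrices — description term vectors
   (cosine) and phenotype-ontology annotations (Resnik best-match-average);
2. fusing each of the 5 × 2 measure combinations into one feature per
   candidate pair: the maximum over known associations (d', s') of the
   weighted geometric mean `S_drug(d, d')^w * S_disease(s, s')^(1-w)`;
3. training an L2-regularised logistic classifier on the 10 features with
   sampled negatives, and
4. evaluating with repeated 10-fold cross-validation, either *drug-wise*
   (10% of drugs and all their indications hidden per fold) or *pair-wise*
   (10% of individual associations hidden).

## Functional forms and their defaults

The upstream description of this method names the seven measures but not
their formulas, so the functional forms here are package design decisions,
each implemented in the conventional way for its field:

* **Tanimoto/Jaccard** `|A∩B| / |A∪B|`; two empty sets score 0.
* **Sequence similarity** `SW(s1,s2) / sqrt(SW(s1,s1)·SW(s2,s2))` with
  local alignment under BLOSUM62, gap open 10, gap extend 0.5 (a gap of
  length L costs `10 + 0.5·L`). Self-normalisation puts scores in [0,1];
  alignments that never score positive give 0.
* **Semantic similarity** Resnik-style: term information content is
  `-ln(count/count(root))` in natural-log units from annotation counts
  propagated to ancestors (pseudo-count 1 for unannotated terms); a term
  pair scores the IC of its most-informative common ancestor normalised by
  the maximum corpus IC; term *sets* score the best-match average (mean of
  each term's best match, averaged over both directions). Note the semantic
  self-similarity of a term set is the mean normalised IC of its terms, not
  1 — two different proteins sharing one annotation set are only as similar
  as those terms are informative. Entity-vs-itself entries of a similarity
  matrix are 1 by convention.
* **Network closeness** `exp(-b·d)` with `d` the unweighted shortest-path
  length and decay `b = 1`; `d = 0` (shared target) gives 1, disconnected
  pairs give 0.
* **Cosine** of the nonnegative description count vectors; zero vectors
  score 0.
* **Drug-level aggregation** over multiple targets takes the maximum over
  target pairs — the strongest evidence — keeping values in [0,1].
* **Missing modalities** score 0 against every other entity in that measure
  (diagonal kept at 1) with a warning, so matrices stay total.

Fusion uses `w = 0.5` (the plain geometric mean) by default; the weight is
exposed in `fusion_config()` because nothing upstream fixes it. Aggregation
over known associations is `max` by default, with `mean` offered; `max`
preserves the strongest single piece of evidence and is directly testable
against enumeration. During training, a known positive pair's own entry is
excluded from its evidence set (`exclude_self`), the leakage guard that
keeps a positive from explaining itself; during drug-wise evaluation the
evidence set is the training-fold positives only, so hidden drugs
contribute nothing.

## Classifier and metrics

`train_logistic()` minimises the mean negative log-likelihood plus
`lambda/2 · ||beta||^2` (intercept unpenalised) by exact damped Newton
iterations; the 11×11 Hessian solve makes the optimum reproducible to
machine precision, which the test suite cross-checks against glmnet at the
same penalty and against glm in the unpenalised limit. The penalty sits on
the *per-observation* scale, so duplicating a data set leaves the decision
function unchanged; the default `lambda0 = 1e-3` is a light ridge chosen to
stabilise near-separable folds without visible coefficient bias (the
generate-and-refit test recovers known coefficients within ±0.15 at
n = 5000). Classification metrics use threshold 0.5; ROC AUC is the
mid-rank statistic and AUPR is step-wise average precision.

Negative pairs are drawn uniformly without replacement from the
drug × disease lattice minus the gold standard, at a 1:1
negative:positive ratio by default (exposed as `neg_ratio`). In drug-wise
folds, test negatives are drawn among pairs whose drug is a held-out drug
and train negatives among training-drug pairs, mirroring the "respective
sets" reading of the evaluation protocol; how test negatives were drawn in
the drug-hiding scheme is not specified upstream, so this interpretation is
a documented choice.

## The synthetic knowledge base

Because the original input datasets are external and large, evaluation runs
on a generated knowledge base with *planted* signal. Entities are assigned
to latent clusters; members of a cluster share modality prototypes — a
random fingerprint bit-set, a side-effect term set, a protein pool with a
common ancestral sequence (length 120 over the 20-residue alphabet), GO
annotation sets, phenotype term sets and description count vectors — each
copied with per-feature perturbation rate `modality_noise`. The
protein–protein network is dense within clusters (edge probability 0.3) and
sparse across (0.01). Gold associations link a drug to a disease of its own
cluster with probability `signal_strength` and to a uniformly random
cluster otherwise; each drug receives at least one indication
(`associations_per_drug` has mean 2, the sparse regime typical of
indication gold standards). Ontologies are random rooted trees (a
guaranteed chain keeps depth ≥ 4) plus ~10% extra is-a edges, sized 200
(GO-like) and 150 (HPO-like), so most-informative common ancestors are
non-trivial.

Defaults — 120 drugs, 80 diseases, 150 proteins, 10 clusters, fingerprint
length 166 (MACCS-like), signal 0.9, noise 0.05 — are the fixed study
conditions for the package's evaluation experiments: large enough that
10-fold drug-wise CV holds out 12 drugs per fold, small enough that a full
5-knowledge-base, 10×10-fold experiment runs in minutes on one CPU.

What the generator does *not* emulate: realistic fingerprint bit
correlations, sequence domain structure, scale-free interaction topology,
ontology term depth distributions, or the extreme sparsity and bias of real
indication data. Passing tests therefore demonstrate that the pipeline
recovers recoverable signal and is internally consistent — not that it
attains any particular accuracy on real pharmacological data.

A permutation control reruns the identical pipeline with labels shuffled
within each fold's training and test sets; its AUC sits at chance (0.45 to
0.55), showing the recovered signal is not an artifact of the evaluation
plumbing.

## Workflow provenance model

The provenance layer describes the pipeline itself in RDF, combining
P-PLAN (plans, steps, variables, activities), DUL (workflow typing,
`dul:precedes`, `dul:isDescribedBy`), PWO (`pwo:hasFirstStep`), BPMN-derived
task classes (`bpmn:ManualTask` / `bpmn:ScriptTask` as step subclasses),
DCAT (dataset distributions with download URLs and media types), PROV
(qualified usage, generation, association, revision) and ML-Schema
(model evaluations and measures):

* **Prospective**: `describe_workflow()` emits the recipe — a versioned
  `dul:Workflow`/`p-plan:Plan` whose steps are lightweight ordering objects,
  each described by (`dul:isDescribedBy`) a reusable instruction plan;
  variable bindings to dataset distributions are reified `prov:Usage`
  nodes; agent roles are reified `prov:Association` nodes carrying
  `prov:agent`, `prov:hadRole` and `prov:hadPlan` (the endurant reading of
  the association pattern), alongside plain `dc:creator` properties.
* **Retrospective**: `record_execution()` emits one `p-plan:Activity` per
  executed step (`p-plan:correspondsToStep`), generating one
  `mls:ModelEvaluation` artifact per evaluation measure whose value is a
  plain string literal in `dc:description` (matching the shape of published
  examples, e.g. `"0.833336"`), with a `prov:qualifiedGeneration` node
  holding an ISO-8601 millisecond timestamp.
* **Versioning**: `dc:hasVersion` literals on every versionable node and
  `prov:wasRevisionOf` links between workflow versions and between revised
  instruction plans (declared via the `revises` field of `step_spec()`).

Namespaces use the canonical URIs where they exist; `bpmn:` and
`opredict:` have none and are minted under a configurable base defaulting
to `https://w3id.org/fair/plex`.

### RDF engine

No RDF library is available to R here, so the package carries its own
minimal triple store: a data frame of expanded-IRI triples plus a prefix
map, a deterministic Turtle serializer, and a parser for the emitted
subset (prefix declarations, prefixed names, IRIs, string literals with
optional datatypes, predicate/object lists). The emitters never mint blank
nodes, so graph isomorphism is set equality of expanded triples — what
`rdf_isomorphic()` checks and what the 100-random-graph round-trip property
test exercises. Competency questions are implemented as native R
triple-pattern queries (`answer_cq()`), with row sets sorted for
determinism; the equivalent SPARQL 1.1 queries ship under
`inst/sparql/` for use against external triple stores.

### Competency questions

Thirteen questions cover manual steps (CQ1.1–1.4), abstraction levels
(CQ2.1–2.4) and versioning (CQ3.1–3.5). Two required interpretation:
CQ2.4 (who instantiated a higher-level description?) is answered through
the association pattern attached to plans participating in
plan-describes-plan links, since no worked example exists upstream; CQ3.4
diffs the dataset distributions reachable from each version's instruction
plans. `diff_versions()` classifies instruction plans as *changed* (new
plans revision-linked to old ones), *removed* (old plans neither reused nor
revised) and *added* (new plans neither reused nor revising); the three
sets are disjoint by construction.

The worked-example graph from `build_paper_fixture()` reproduces published
listing content (the manual DrugBank-download step with its qualified
usage and distribution, execution 1546302862 with its six evaluation
artifacts, and the v0.1/v0.2 version chain) plus the minimal glue that
makes all thirteen questions answerable on one graph. Reported step counts
for the original full-size graphs (42 or 60 steps for v0.1 — the published
numbers disagree with each other) depend on external RDF and are out of
scope; the fixture reproduces listing content, not corpus statistics.

## Numerical and degenerate-input choices

* Similarity values are clipped into [0,1] after floating-point arithmetic.
* Empty evidence sets fuse to 0; empty term/target sets score 0 with a
  warning; both-empty Jaccard is 0.
* `sample_negatives()` errors when fewer non-forbidden pairs exist than
  requested, rather than silently under-sampling.
* Permuted-label folds resample (bounded retries) if a permutation leaves a
  single-class training set at tiny n.
* Fold assignment, negative sampling and label permutation all derive from
  one master seed through an isolated RNG scope, so every run is exactly
  reproducible and callers' RNG state is untouched.
* `step_order()` is Kahn's algorithm seeded with the declared first step,
  breaking remaining ties lexicographically; cycles raise an error.

## Problem sizes used by the checks

The test suite exercises unit oracles at ≤ 8 entities (exhaustive
enumeration), mid-size properties at 24–60 drugs, and the evaluation
experiment at the full study conditions: five knowledge bases (seeds 1–5)
at 120 drugs × 80 diseases, each cross-validated 10 × 10-fold drug-wise
plus the permutation control. `scripts/acceptance.R` repeats that
experiment (both CV strategies and the null) from a caller-supplied seed
and also re-derives the feature count, the fixture's queried accuracy
value and the emitted prospective step count.

## Known limitations

* The seven similarity formulas are conventional reconstructions; the
  method's original feature code is not public, so exact numerical parity
  with it is untestable.
* The Turtle parser covers only the subset the serializer emits (no blank
  nodes, collections, numeric shorthand literals or `base` declarations).
* `answer_cq()` operates on in-memory graphs; it is not a SPARQL engine,
  and the shipped `.rq` files are equivalents for external stores, not the
  executed code path.
* Real-data ingestion is limited to the tabular loaders (gold standard,
  interaction list, phenotype annotations); fingerprints, side effects and
  sequences must already be tabulated. Records missing a modality are
  tolerated (scored 0) but not imputed.
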