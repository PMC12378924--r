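---
title: "Knowledge-constrained anomaly detection for clinical event trajectories: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-constrained anomaly detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kganomaly)
```

This vignette is the package's own account of its science: the models and
penalties it implements, the parameters that matter and their defaults,
what the synthetic-data generator does and does not emulate, and the
places where the design was genuinely open and a choice had to be made.

## Problem and data model

A patient record is an ordered sequence of visits at strictly increasing
timestamps. Each visit is a set of coded clinical events from a fixed
vocabulary `E` partitioned into semantic types (diagnosis, medication,
lab, procedure); lab events carry a numeric value. The state at a visit is
the multi-hot indicator `x(t)` over `E` with a sparse value map attached.
Three knowledge structures constrain what trajectories are plausible:

* an **is-a hierarchy** (a DAG) whose strict transitive closure `T` marks
  ancestor-descendant pairs;
* a **relation matrix** `R`, symmetric with zero diagonal, marking
  semantically valid co-occurrences;
* a **causal matrix** `C`, an acyclic set of directed cause-precedes-effect
  edges.

An anomaly, for this package, is a patient whose record conflicts with
that knowledge or with the cohort's temporal regularities: an event with
no valid partner in its visit, an effect observed before its cause, or an
abrupt move to an unrelated region of the ontology.

## Masking implausible co-occurrences

The hard mask keeps an active event iff some co-active event is related to
it under `R`; the typed variant additionally requires type agreement, and
is therefore never more permissive. The normalized relational confidence
`s_i = (1/||x||_1) sum_j R_ij x_j` feeds a sigmoid gate
`x_i * sigma(alpha s_i)` when a differentiable mask is needed. Two edge
conventions matter. The diagonal of `R` is forced to zero on load so an
event cannot support itself — otherwise the mask would be vacuous. And an
empty visit would make the confidence normalization divide by zero; the
package returns zero confidence and skips masking with a warning, because
rejecting would break streaming over real records, where empty encounters
occur. The gate temperature defaults to `alpha = 4`, which maps a
half-supported event (`s = 0.5`) to a gate of about 0.88 — strong but not
saturated; the parameter is exposed because no principled value exists.

The typed mask is implemented literally: cross-type support (a medication
justified by a diagnosis) does not satisfy it. That is clinically
over-restrictive, which is why the plain hard mask is the pipeline's
default and the typed rule is an opt-in strictness level.

## Ontology-aware embeddings

Concept embeddings start from Xavier-uniform draws (seeded), from the
Laplacian eigenmap of the ontology, or from an adapted matrix (below).
Context vectors are attention-weighted neighbor sums with scaled
dot-product similarity by default (cosine by flag; the two are both
admissible and scaled dot-product needs no norm guards). Relation-specific
propagation applies the residual update
`e_i <- e_i + ReLU(sum_r sum_{j in N_r(i)} alpha_ij^(r) W_r e_j)`. The
relation-specific attention weights use keys `W_r e_j`, and the softmax is
taken jointly over all (relation, neighbor) pairs of a node rather than
per relation, so each node's weights form a single probability
distribution — the alternative (per-relation normalization) would weight
relation types by their neighbor counts in an uncontrolled way. Isolated
concepts keep their own embedding as context, which makes them neutral
under the structural reconstruction penalty `sum_i ||e_i^(L) - e~_i||^2`.

Hierarchy edges feed the neighbor structure in both directions (an `is_a`
label upward, a `has_child` label downward) so information can flow down
the hierarchy as well as up.

## Temporal encoder and disentangled factors

Each patient becomes a temporal event graph: one node per (visit, active
event), an intra-visit clique, complete bipartite edges between
consecutive visits, and ontology-labelled edges between co-present related
concepts. The encoder runs the same relation-aware residual layer over
this graph with edge labels `{intra, inter, ontology}`, pools same-visit
nodes (mean pooling by default — exactly permutation invariant and
amenable to exact expected values; multi-head attention pooling is
available), and projects to a latent `z(t)` of dimension
`K x factor_dim`. Empty visits yield a zero latent rather than an error.

The reference configuration is 4 layers, 256 hidden units, 8 attention
heads, 6 factors of 64 dimensions (384-dimensional latent), dropout 0.3
on projections (training mode only; all scoring paths are deterministic),
Adam at learning rate 1e-4 with weight decay 1e-5, and regularization
coefficients of 0.01. The pipeline used in the package's tests and
reproduction script keeps the factor count and all training rules but
shrinks widths to 2 layers x 32 hidden and 6 factors x 8 dimensions — the
package's choice of problem size for a 200-patient synthetic cohort, where
wider encoders add runtime without adding information.

Three regularizers act on the factors. The covariance penalty is the sum
of squared cosines over ordered factor pairs (zero-norm factors contribute
nothing; the penalty is invariant to positive rescaling). The temporal
penalty `sum_t sum_k ||dz_k(t)||^2` equals the whole-vector form for any
complete partition (a Pythagorean identity, tested exactly). Mutual
information between 64-dimensional blocks is not estimable at desk scale,
so the package uses a Gaussian canonical-correlation surrogate,
`-1/2 sum log(1 - rho^2)` over canonical correlations per ordered pair
(clipped at `rho^2 = 1 - 1e-6`): zero iff the blocks are uncorrelated,
which matches the intent of the penalty under the Gaussian assumption. It
is computed per batch of pooled timesteps; per-sample computation and
averaging is the convention wherever a batch dimension exists.

## Knowledge-guided refinement

Latents map to soft concept assignments `s(t) = softmax(P' z(t))`. Hinge
penalties `sum_ij M_ij max(0, s_j - s_i)` with `M = T` (hierarchy) or
`M = C` (causal) are zero exactly when the assignment respects the partial
order; a multi-step variant compares `s_j(t+1)` against `s_i(t)` to catch
cascaded causal violations across consecutive visits. Alignment to a
frequency- or uniform prior uses `sum q_i log(q_i / (s_i + eps))` with
`eps = 1e-8`; the epsilon introduces a negative bias bounded below by
`-log(1 + eps |E|)`, which is documented rather than hidden because the
bound is tiny and the guard prevents infinite penalties on empty support.

Refinement descends on `z(t)` against `lambda_1` times the hierarchy
penalty plus `lambda_2` times the causal penalties (defaults 1 and 1;
global weighting belongs to the composite objective). Although the
procedure is often described as projected gradient descent, the only
constraint — that `s(t)` stay on the simplex — is enforced structurally by
the softmax, so no explicit projection exists; the package therefore runs
plain gradient descent with an optional step-halving safeguard (up to 20
halvings per step) that guarantees a monotonically non-increasing
objective. Gradients are analytic (hinge subgradient chained through the
softmax Jacobian) and are verified against central finite differences in
the test suite. The per-timestep causal scale is reparameterized
`gamma_t = exp(g_t)` with `g_t = 0` initially, and can be co-optimized;
it is off by default because joint descent drives `gamma_t` toward zero —
the objective's cheapest escape — rather than learning anything useful.
Refinement is per-timestep with the multi-step term coupling consecutive
steps, so a whole trajectory is refined jointly.

At scoring time the refiner runs few steps (10, step 1.0) deliberately:
the post-refinement residual is the anomaly signal, and running to
convergence would erase the very violations being measured.

## Population-level embedding adaptation

The binary patient-event matrix `B` is factorized by alternating least
squares on `||B - UV'||^2 + gamma(||U||^2 + ||V||^2) + lambda Tr(V'LV)`,
where `L` is the Laplacian of the NMI co-occurrence graph
(`MI / sqrt(H_i H_j)` with plug-in entropies; constant columns give zero
by convention). ALS was chosen over joint gradient descent because each
half-step is an exact linear solve — the U-step is ridge regression and
the V-step is a Sylvester-type system solved exactly in the eigenbasis of
`L` — giving provable monotone descent that the tests assert directly.
Plug-in entropies carry no bias correction; cohort sizes in the tests are
controlled, and the graph only regularizes. The closed-form ridge
alignment `W = (V'V + alpha I)^{-1} V' V_pre` is checked against an
iterative minimizer. Adapted factors can serve as the embedding
initialization (`init = "adapted"`).

## The fitted pipeline and the anomaly score

No scoring formula for anomalies follows from the constraint machinery
alone, so the package defines one with the property that every component
is individually testable against constructed instances:

1. **mask** — the fraction of the patient's active events rejected by the
   hard mask;
2. **violation** — the combined hierarchy+causal objective after
   refinement;
3. **jump** — the largest per-step factor shift `max_t sum_k ||dz_k(t)||^2`;
4. **forecast** — the mean one-step error (binary cross-entropy over the
   vocabulary) of a linear decoder predicting the next visit's indicator
   from `z(t)`. This deterministic one-step forecast stands in for a full
   posterior over next states, which is out of scope.

Each component is rank-normalized to `[0, 1]` across the scored cohort
(midranks, so a patient at the cohort mode lands mid-interval) and
combined with uniform weights. Rank normalization makes the score
invariant to monotone rescaling of any component and bounds it in
`[0, 1]` without distributional assumptions.

Training fits the differentiable heads: the forecast decoder (a
per-concept logistic readout, trained full-batch with Adam for up to 400
epochs, early stopping on a 10% validation split with patience 40 —
patience is generous because the full-batch loss surface is smooth and
stopping early mostly returns an under-fitted decoder) and, when outcome
labels exist, a logistic risk head
`sigma(sum_t w'z(t) + b)` on the summed latents. The graph encoder and
embeddings are a deterministic, seeded feature extractor: embeddings
concatenate a spectral block (Laplacian eigenmap of the ontology, scale
1.5) that grounds latent distances in ontology geometry with a random
near-orthogonal block (32 dimensions) that keeps individual concepts
distinguishable in the soft assignments. The concept projection `P` is
built from the encoder images of each concept as a singleton visit, scaled
(temperature 20) so assignments are peaked on a visit's events rather than
near-uniform — with unscaled logits the hinge penalties lose almost all
contrast between active and inactive concepts. The composite objective
assembles all penalties with named weights (regularizers 0.01, supervised
task 1.0) and reports a breakdown that sums to the total; the logit-scale
hierarchy penalty is kept distinct from the softmax-scale one and is off
by default so the hierarchy is not penalized twice.

The event transition tensor records `A[t, i, j] = 1` when `i` is active at
`t` and `j` at `t+1` — the only reading that makes the tensor temporal; a
within-visit variant exists behind a flag but is not used by the pipeline.

## The synthetic study

The generator emulates the full input contract with known ground truth.
The ontology is a four-level tree: a root, two branches, ten cluster
parents (split between branches), and leaf concepts assigned round-robin
to parents (1-2 parents each, second parent within the same branch with
probability 0.15). Relation edges make all concepts under one branch
pairwise compatible — the "service line" reading of clinical
compatibility — plus ancestor pairs and random lateral edges at density
0.01. This is broader than sibling-only compatibility for a reason: causes
persist across visits (chronic-condition semantics), and a chronic
diagnosis must remain plausible anywhere in its branch or the clean cohort
would trip its own mask. Causal edges (two per cluster) connect leaves
inside a cluster, oriented by concept index, hence acyclic.

Each of 200 patients follows a first-order Markov chain over 5 health
states (self-transition 0.7, remainder uniform), one state per cluster in
the first branch; the second branch is reserved as jump territory. A visit
emits its cluster parent plus 2-4 leaves; an effect is only emitted once
its cause has appeared at a strictly earlier visit, and causes persist
once emitted. Lab values are Gaussian with state-dependent means and unit
variance. By construction the clean cohort has hard-mask rejection exactly
zero and no causal inversions.

Exactly `round(0.1 * 200)` patients get one planted anomaly, the mix
uniform over three classes aligned one-to-one with detector components:
`cooccurrence` injects an event with no related partner in its visit;
`causal` removes a realized cause from the record's early visits and
reinjects it (supported by a related partner) after its effect; `jump`
replaces one visit with the cluster at maximal mean ontology distance
(undirected shortest-path in the hierarchy) from the previous visit.

What the generator does **not** emulate: coding noise and missingness,
irregular visit spacing, concept frequency heavy tails, cross-type causal
chains, co-morbid state mixtures, and any statistical fidelity to a real
EHR corpus. Passing tests therefore show that each detector component
responds to the violation class it targets under controlled conditions —
not that the pipeline would achieve comparable detection on real records.

On this study (five replicate seeds) the pipeline's mixed-anomaly AUROC is
about 0.82, with co-occurrence patients perfectly separated on the mask
component, jump patients detected near-perfectly by the jump and forecast
components, and causal inversions the hardest class (about 0.7): their
trace — an effect without its cause at the immediately preceding visit —
is intrinsically subtle under one-step penalties, and the refinement
residual mixes it with hierarchy violations of much larger scale. These
numbers are recomputed, not asserted, by `scripts/acceptance.R` and the
test suite.

## Numerical conventions

Eigen-decompositions use LAPACK's symmetric solver; eigenmap ties among
equal eigenvalues follow the solver's deterministic ordering, reversed to
ascending. The eigenmap keeps the trivial near-constant eigenvector by
default (the literal optimum of the spectral program) with a flag to skip
near-zero eigenvalues for classical eigenmap usage. All randomness flows
from one master seed through named substreams (knowledge base, cohort,
anomalies, embeddings, training), so components are independently
reproducible; two runs with the same seed are bit-identical in
single-threaded R. Hinge gradients at exact score ties take the
lower subgradient (the tie contributes nothing), which is measure-zero
under the randomized tests. Lab values are z-scorable per concept via
`lab_standardizer()`; raw values are preserved in the state's value map.

## Known limitations

The encoder is a fixed feature extractor: only the forecast decoder, risk
head and (optionally) the projection are trained, with hand-derived
analytic gradients — there is no end-to-end backpropagation through the
message-passing layers. The causal anomaly class is detected at about 0.7
AUROC for the reasons above. The typed mask's same-type requirement is
stricter than clinical practice. NMI uses plug-in entropies without
small-sample correction. None of the components model measurement error
in lab values; values ride along for audit but only presence/absence
drives detection.
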