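---
title: "Methods: ligand-based screening for dual-target inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-based screening for dual-target inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `dualscreen`, and what the synthetic benchmarks do and do
not demonstrate about real screening data.

## The screening model

The pipeline treats virtual screening as binary classification. Known
inhibitors of the target (curated to one representative per chemical
series) form the positive class; property-matched decoys form the negative
class. Molecules are featurized as fixed-length bit vectors and a
classifier's positive-class probability, thresholded at p ≥ 0.5, defines
the candidate list. The working assumption is the similarity principle:
molecules sharing substructure-level topology with known actives are more
likely to share their activity. The decoy construction deliberately breaks
the shortcut of classifying on bulk physicochemistry — decoys match the
actives' property profile while being topologically dissimilar — so the
classifier must learn topology, not size or lipophilicity.

## Curation

* `mw_max = 500` Da and `potency_max_nM = 500` nM, both strict
  inequalities ("smaller than", "more potent than"): boundary values are
  excluded. Potency is accepted as either Ki or IC50; when a molecule
  carries several measurements the minimum (most potent) is kept. This
  merge rule is a package decision — exports from public databases do not
  say how repeated assays should be reconciled — and it is deliberately
  optimistic: a molecule is as potent as its best measurement.
* Salt stripping keeps the largest covalent fragment by heavy-atom count;
  no neutralization is applied, because the decoy matcher treats net
  charge as a hard property and protonation is resolved later by rule.
* Cluster representatives: sphere-exclusion clustering at TC ≥ 0.6, then
  the minimum-potency member per cluster, ties broken by lexicographic
  molecule id for determinism. One-per-cluster selection keeps a single
  chemical series from dominating the positive class.

## Fingerprints

`ECFP4`/`ECFP6` here are Morgan-style circular fingerprints of bond radius
2 and 3 computed by the package itself on the OpenBabel molecule graph:
atom invariants (element, heavy degree, total bond order, formal charge,
implicit H count, ring membership) are iteratively combined with sorted
(bond order, neighbour invariant) pairs and every environment from radius
0 up is folded modulo 1024 bits. Implementing the fingerprint internally
makes downstream results independent of toolkit hash revisions; it matches
the behaviour, not the exact bits, of any particular toolkit's ECFP, so
published TC values computed with other software are reproduced only
approximately. MACCS uses OpenBabel's 166 structural keys directly. Ring
membership comes from bridge detection (an edge lies in a ring iff it is
not a bridge), and implicit hydrogens from default valences adjusted by
formal charge; kekulized aromatic rings yield stable bond-order sums in
the invariant, so the two kekulé forms of a benzene ring collide as
intended.

## Clustering

Sphere exclusion (Butina-style): neighbour counts at TC ≥ cutoff are
computed once; molecules are visited by descending neighbour count (ties
by index); an unassigned visitee becomes a centroid and absorbs its
unassigned neighbours; leftovers end as singletons. The algorithm choice
is the package's — the curation protocol only fixes the 0.6 cutoff — and
this variant was chosen because it is deterministic, order-independent
given the tie rules, and cheap at library scale.

## Decoy generation

Six matched properties: MW, cLogP, rotatable bonds, H-bond acceptors,
H-bond donors, and net charge at pH 7.4 from rule-based protonation
(carboxylic acids −1, aliphatic amines +1, otherwise formal charge;
anilines, amides and sulfonamides stay neutral). Default windows are
±25 Da, ±1.0 cLogP, ±2 rotatable bonds, ±1 HBA, ±1 HBD, exact charge.
When an active cannot fill its quota the windows widen by ×1.5 for up to
three rounds; the similarity ceilings (TC < 0.6 to every active, < 0.8
pairwise among decoys) never relax — under-filled actives are reported as
shortfalls instead, which mirrors how real decoy services return fewer
decoys than requested. Candidates are ranked by the sum of
window-normalized absolute property deltas, ties by id; actives are
processed in input order. All of this makes generation a pure function of
the inputs.

## Classifiers and selection

The seven algorithms run with pinned defaults
(`default_hyperparameters()`): KNN k = 5; Bernoulli naive Bayes with
Laplace α = 1 (implemented in closed form — the natural likelihood for
binary bits); logistic regression with an L2 penalty λ = 1/n fitted down a
warm-started path (an unregularized fit separates perfectly on scaffold
data and diverges); CART defaults; random forest 100 trees; a
single-hidden-layer MLP (tanh, 16 units, L2 decay 1e-4) trained full-batch
with Adam — the trainer is implemented in the package with dense matrix
ops because quasi-Newton MLP fitters scale quadratically in the weight
count and are intractable at 1024 inputs, and a wider layer adds nothing
at these problem sizes; XGBoost 100 rounds. Cross-validation is
stratified 5-fold, repeated over 5 independent repartitions (25 fold
evaluations): at ~2.5% positive prevalence unstratified folds would often
lack positives entirely. Model selection maximizes mean MCC; exact ties
fall to the simpler model (NB < Logit < KNN < DT < RF < XGBoost < MLP),
since a simpler model with equal discrimination carries less overfitting
risk. AUC is computed per validation fold and averaged (not pooled);
fold-level ACC means differ from pooled-confusion ACC only by fold-size
weighting, which the tests bound explicitly.

## LogAUC

Early enrichment is measured as the area under TPR versus log10(FPR) over
[0.001, 1], normalized by the three-decade range and reported in percent.
The ROC is piecewise linear between vertices and each segment is
integrated analytically in log space (∫(a + b·f)/f df), with the first
segment interpolated at the 0.001 floor, so the implementation agrees with
the closed forms: 100 for a perfect ranker and
(1 − 0.001)/(3 ln 10) × 100 ≈ 14.47% for a random one.

## External validation

Before calling an annotated external set, every training active with max
TC ≥ 0.6 to any external molecule is removed together with exactly its
linked decoys, and the model is retrained. This prevents the validation
from being won by near-duplicates of the externals sitting in the
training set. Calls use the same p ≥ 0.5 rule and are tabulated as TP/FP
against the annotations.

## Assay fitting

*Dose-response.* Two-parameter logistic with asymptotes fixed at 1 and 0
(the data are normalized to control activity before fitting; fixing the
asymptotes is the package's choice and keeps 5-point curves identifiable),
Hill slope free but reported. Fitting is Levenberg–Marquardt in
log10(IC50) with multi-start over 7 log-spaced IC50 values spanning the
concentration range; the best converged start by RSS wins, and the
convergence flag is propagated honestly. A warning fires when responses do
not decrease with concentration (Spearman ρ > −0.3).

*Cheng–Prusoff.* `Ki = IC50/(1 + [S]/Km)`. Km is a required user input per
enzyme — the conversion silently assuming a Km would bias every reported
Ki, so a missing Km is an error. Consequently absolute Ki values depend on
the user's Km; the identities (Ki = IC50/2 at [S] = Km, Ki → IC50 as
[S] → 0) are exact.

*Monte-Carlo uncertainty.* 100 cycles; each perturbs responses with
multiplicative Gaussian noise of SD `max(0.05 · response, replicate SD)` —
a floored 5% relative uncertainty — refits and converts. More than 50%
non-converged cycles is an error, not a silent mean over survivors.

*DSF.* Only 40–68 °C data are used (outside this window dye artifacts and
post-unfolding aggregation dominate real curves); the windowed signal is
min-max normalized and fit to the Boltzmann sigmoid with box constraints
keeping Tm inside the window; Tm within half a degree of the boundary is
flagged `at_edge`. Significance of a shift: |ΔTm| > 3 × SD of ≥3 reference
replicates (n−1 SD).

## Synthetic benchmarks

The generator builds actives as one shared scaffold (default a
para-substituted benzenesulfonamide, echoing the zinc-binding
pharmacophore of carbonic anhydrase inhibitors) with substituent chains
enumerated from a fixed vocabulary; backgrounds and decoy candidates come
from eight unrelated scaffold families with the same substituent
machinery. This guarantees the structure the analysis assumes — elevated
within-active TC, a shared substructure, property overlap between
background and actives — with potencies log-uniform on 1–500 nM (the
curated potency range) and assay curves drawn from exactly the models the
fitters assume with 5% (dose-response) and 1% (DSF) noise.

What passing on these benchmarks shows: the bookkeeping, constraints,
metrics and fits are correct, and the pipeline recovers planted truth when
its assumptions hold. What it does not show: performance on real
databases, where activity cliffs, assay noise, series bias and
protonation/tautomer ambiguity violate the generator's clean structure,
and where dose-response curves need not be logistic. Scaled-down sizes are
used throughout (60 training actives, 500-molecule libraries,
3000–5000-candidate pools, 100-curve simulations), chosen as the smallest
sizes at which the class-imbalance and constraint-interaction effects are
visible.

## Known limitations

* Net-charge protonation is rule-based (two SMARTS rules plus formal
  charge); pKa-aware protonation is out of scope.
* The internal circular fingerprint does not deduplicate identical
  substructure environments before folding; bit collisions differ from
  other toolkits', so absolute TC values are backend-specific (similarity
  *orderings* are stable in practice).
* `external_validation()` requires a user-supplied annotated external set;
  there is no database client.
* KNN probabilities are vote fractions over k = 5 neighbours and take only
  six distinct values; they are usable with the p ≥ 0.5 rule but too
  coarse for fine threshold tuning.
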