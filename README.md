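# dualscreen

Ligand-based virtual screening for discovering dual-target inhibitors —
molecules that inhibit two unrelated protein classes (the motivating case:
kinase inhibitors that also block carbonic anhydrases through their
benzenesulfonamide zinc-binding group). The package implements the full
desk-side analysis as an R workflow: active-library curation,
property-matched decoy generation, fingerprint-based classifier selection,
library screening, similarity-ensemble comparison of hits, and quantitative
fitting of the wet-lab validation data.

## What it computes

**Curation.** Potency-annotated molecules (BindingDB-export style tables or
SDF) are standardized (canonical SMILES, largest-fragment salt stripping,
potencies in nM), restricted to MW < 500 Da and potency < 500 nM (strict),
clustered by sphere exclusion at Tanimoto coefficient
TC(A,B) = |A∩B| / |A∪B| ≥ 0.6, and reduced to the most potent
representative per cluster.

**Decoys (negative class).** For each active, candidates are ranked by
closeness in six properties (MW, cLogP, rotatable bonds, HBA, HBD, net
charge at pH 7.4) and selected greedily subject to two hard constraints:
TC < 0.6 to *every* active and pairwise TC < 0.8 among all selected decoys
(default 40 per active). A post-hoc audit re-verifies every constraint.

**Classifier selection and screening.** Seven classifiers (KNN, Bernoulli
NB, L2 logistic regression, decision tree, random forest, MLP, XGBoost)
over three fingerprints (1024-bit circular ECFP4/ECFP6 analogues, 166-bit
MACCS keys) are compared by 5-fold × 5-run stratified cross-validation.
Selection uses the Matthews correlation coefficient

    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))

because ACC and AUC saturate near 1 on screening-style class imbalance.
The winner is refit on all data and applied to a library at p ≥ 0.5, each
hit annotated with its nearest training active (max TC). LogAUC (ROC area
over log10 FPR ∈ [0.001, 1], normalized to percent; random ≈ 14.47%) is
available as an early-enrichment metric.

**Assay analysis.** Dose-response curves are fit to
`response = 1/(1 + ([I]/IC50)^h)`, converted to the inhibition constant by
Cheng–Prusoff `Ki = IC50 / (1 + [S]/Km)`, with uncertainty from 100
Monte-Carlo refit cycles at a ≥5% noise floor. DSF melt curves are fit to
the Boltzmann sigmoid `F(T) = B + (A−B)/(1 + exp((Tm−T)/s))` inside the
40–68 °C window; a thermal shift is called significant when
|ΔTm| > 3 × SD of the reference replicates.

A synthetic-benchmark module generates scaffold-derived actives, diverse
background libraries, decoy candidate pools and assay curves, so the whole
pipeline runs and is tested without any database downloads.

## Worked example

```r
library(dualscreen)

bench <- generate_screening_benchmark(
  benchmark_spec(n_actives = 30, n_background = 150, n_planted = 10, seed = 11))
pool <- generate_decoy_pool(600, seed = 12)

decoys  <- generate_decoys(bench$actives, pool, n_per_active = 10)
dataset <- assemble_dataset(bench$actives, decoy_records(decoys),
                            "ECFP4", seed = 3)
cross_validate(dataset, model_spec("Logit", seed = 5), k = 5, runs = 2)
#> <cv_report Logit/ECFP4: ACC 1.000+-0.000 AUC 1.000+-0.000 MCC 1.000+-0.000 (5x2 folds)>

model <- train_final(dataset, model_spec("Logit", seed = 5))
hits  <- screen_library(model, bench$library, p_threshold = 0.5)
nrow(hits)          # 10 candidates at p >= 0.5 ...
sum(bench$truth$is_active[match(hits$molecule_id, bench$truth$molecule_id)])
#> 10               # ... and all 10 planted actives are among them
```

The cross-validation report shows the scaffold signal is fully separable
at this scale (MCC 1.0); screening the held-out library recovers all ten
planted actives with no false candidates at p ≥ 0.5. Each hit row also
carries `nearest_active_id`/`nearest_active_tc`, the novelty annotation
used to judge whether a candidate is a trivial analog of the training set.

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `09_fit_dsf.R`); each script is a thin narrative driver
over these functions that prints what it found and writes its tables under
`results/run/`.

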