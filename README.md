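# polybiodeg

Structure-based prediction of polyester biodegradability, with the
safeguards a 48-sample model needs to be usable: an applicability domain
that refuses predictions outside the model's competence, and exact Shapley
explanations mapped down to individual trimer atoms.

## Who this is for

Polymer chemists screening candidate polyesters (e.g. amphiphilic,
surfactant-type polymers for liquid formulations) before synthesis, and
cheminformaticians who want a small, fully-tested reference pipeline for
trimer-based polymer ML. The package ships a 48-polyester dataset from a
high-throughput enzymatic assay — a polymer is called biodegradable when
lipase-driven ester hydrolysis pulls the endpoint pH below 5.4 within
18.5 h — plus a synthetic-library generator with planted structure→label
rules so every stage is testable against known ground truth.

## The method in brief

1. **Trimer representation.** Each polymer is a canonical SMILES of three
   repeat units joined head-to-tail with one alcohol and one carboxylic
   acid end group. Repeat units come from condensing the diol with the
   diacid/diester (eliminating water or methanol) or from lactone
   ring-opening.
2. **Featurisation.** Hashed subgraph fingerprints (all connected subgraphs
   of 1–`max_path` bonds, canonical fragment strings, two bits per fragment)
   with a full bit → fragment/atom trace, or a molecular-descriptor battery.
   Zero-variance features are masked per training fold.
3. **Benchmarking.** Stratified 5×5 nested cross-validation tuning
   featurisation and model jointly (random forest or a small MLP), metrics
   including ROC-AUC and Brier score, and Friedman/Conover–Holm comparison
   of configurations.
4. **Applicability domain.** Validity (bounding box over fingerprint bits),
   reliability (mean Tanimoto to the 5 nearest training neighbours, binned
   at 0.8/0.9 with similarity-resolved calibration curves), decidability
   (|p − 0.5| gate). Predictions are gated in that order.
5. **Explanation.** Exact tree-path-dependent Shapley values (per-leaf
   coalition enumeration), decomposed onto atoms through the fingerprint
   trace; global ranking, bit-collision report, interaction scan.
6. **Transfer.** A chained model (external model's probability appended as
   a feature) and three-phase neural-network fine-tuning, exercised on
   synthetic source/target pairs with controlled domain shift.

## Worked example

```r
library(polybiodeg)

polymers <- build_dataset_trimers(load_table1())
polymers[1, c("monomer1", "monomer2", "trimer_smiles")]
#> 1 Isosorbide  Dimethyl furan-2,5-dicarboxylate
#>   OC1COC2C1OCC2OC(=O)c1ccc(o1)C(=O)OC1COC2C1OCC2OC(=O)c1ccc(o1)C(=O)OC1CO...

cv <- nested_cv(polymers, algorithm = "rf", features = "fingerprint", seed = 1)
glance(cv)[, c("accuracy", "accuracy_sd", "f1", "roc_auc", "brier")]
#>   accuracy accuracy_sd    f1 roc_auc brier
#> 1    0.787       0.141  0.82   0.726 0.188
```

Accuracy is the mean over the five outer folds (each fold holds out ~10 of
the 48 polymers, so single-seed means move by several points; the
reproduction script below averages ten seeds). The fitted model is then wrapped in its
applicability domain and explained:

```r
fm  <- final_model(polymers, "rf", "fingerprint", seed = 1)
rel <- reliability_scores(fm$fp$matrix, ad_config(), mode = "loo")
table(rel$similarity_group)
#>  low  mid high
#>   19   10   19

rep <- feature_report(shap_values(fm))
glance(rep)
#>   n_features top_share     k top_k_share
#> 1        936    0.0317    20       0.281
```

Nineteen polymers sit below 0.8 mean Tanimoto similarity to their five
nearest neighbours — their probability estimates are poorly calibrated and
`gate()` rejects them — and no single fingerprint bit holds more than a few
percent of the model's total attribution: the chemistry signal is spread
over many fragments, not one magic substructure.

## Layout

- `R/`, `src/` — implementation (graph/chemistry layer, featurisation,
  benchmarking, applicability domain, Shapley kernels in C++, transfer).
- `inst/extdata/` — monomer registry, the 48-polymer table, the
  assay-agreement confusion matrix.
- `inst/cli/polybiodeg.R` — thin command-line wrapper (build-trimers,
  benchmark, synth, pipeline).
- `vignettes/polyester-biodegradability.Rmd` — the methods vignette:
  model assumptions, parameter choices, numerical decisions, limitations.
- `tests/testthat/` — unit, property and end-to-end suites with brute-force
  oracles for the fingerprint enumeration and the Shapley kernels.
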