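# trspredict

Multimodal prediction of treatment resistance in first-episode psychosis
from clinical variables, grey-matter morphometry (VBM) and inter-subject
correlation (ISC) of naturalistic fMRI.

## The problem

About a third of patients presenting with a first psychotic episode do not
respond to first-line antipsychotics and eventually need clozapine, but
the decision is typically reached only after repeated treatment failures.
A classifier that flags likely treatment-resistant patients at first
presentation — from data that can be collected at baseline — could
fast-track that decision. `trspredict` implements such a prediction
pipeline end to end, together with a synthetic-cohort generator that makes
every stage testable without access to any clinical dataset.

## What the package computes

**ISC maps.** During identical naturalistic stimulation (movie viewing), a
subject's voxel time course is correlated with the same voxel's time
course in each member of an independent reference group; the Pearson
correlations are Fisher z-transformed (z = artanh r) and averaged:

    z̄(v) = (1/J) Σ_j artanh( corr(x_v, y_v^(j)) )

The per-subject map stays in z space.

**Region pooling.** Each voxel map (per-subject ISC and grey-matter
concentration) is reduced against an integer-labelled parcellation to four
statistics per region — min, max, mean, sample SD — giving 8 imaging
blocks; with a 274-region whole-brain atlas that is 8 × 274 = 2192 imaging
features next to the 81 clinical variables.

**Sparse per-modality network.** Each input feeds 10 dedicated
logistic-activation nodes in the first hidden layer; all first-layer nodes
of a modality block feed that block's single second-layer node; the
second-layer nodes feed one common output node. There are no cross-modality
connections before the output, so unequal feature counts cannot bias the
fusion. Training is ADAM on binary cross-entropy (10 000 mini-batch steps
of size 10 at learning rate 1e-4 at full scale). A linear soft-margin SVM
(cost 1) is the baseline.

**Randomized-pair cross-validation.** Each run holds out one random
subject per class, balances the training classes by subsampling the
majority, refits the clinical preprocessor (training-rows-only imputation
and 0–1 scaling — mean for scalar/ordinal, mode/unknown for
binary/categorical, a conditional zero for the nicotine-dependence score
of non-smokers) and retrains from scratch; run accuracy is 0, 50 or 100 %.
Accuracy is summarized as the mean over runs (bootstrap CI) and as
ensemble hard voting per subject. Significance comes from re-running the
analysis under permuted labels with the add-one convention
p = (1+k)/(1+P), floor 1/(P+1) (0.000999 at P = 1000); two analyses are
compared by permuting per-run accuracies between them. Feature importance
is layer-wise relevance propagation (epsilon rule) toward each test
subject's true class, summed over runs.

## Worked example

```r
library(trspredict)

cfg <- cohort_config(n_subjects = 20, n_positive = 8, n_reference = 10,
                     n_clinical = 12, grid_shape = c(6, 6, 6), n_regions = 5,
                     n_timepoints = 80, n_missing_vars = 4,
                     clinical_effect_sizes = c(0, 0, 1.5, 1.5, 1.5, rep(0, 7)),
                     isc_attenuation = c(0.2, 0.2, 0.2, 1, 1),
                     vbm_effects = c(-0.1, -0.1, 0.1, 0, 0), seed = 11)
cohort <- generate_cohort(cfg)
report <- run_analysis(cohort, modalities = c("clinical", "vbm", "isc"),
                       model = "nn", n_runs = 100,
                       train_cfg = train_config(iterations = 2000),
                       n_perm = 30, n_runs_perm = 20, n_boot = 2000, seed = 5)
print(report)
#> Multimodal prediction report (NN, modalities: clinical+vbm+isc)
#>   mean accuracy over 100 runs: 80.50 % (95 % CI [75.50, 85.01])
#>   voted: accuracy 100.00 %, sensitivity 100.00 %, specificity 100.00 %, precision 100.00 %
#>   confusion: TP=8 FN=0 TN=12 FP=0
#>   permutation p = 0.0322581 (30 permutations)
```

The cohort plants strong group structure — ISC coupling attenuated to 0.2
in three of five regions for positive subjects, 1.5-SD shifts on three
clinical variables, grey-matter shifts of two noise SDs — and the
three-modality network recovers it: pairwise-run accuracy 80.5 % (chance
is 50 %), every subject voted to its true class, and the label-permutation
test rejects chance at p ≈ 0.03. `save_report()` writes the run records,
importance tables and the resolved configuration to disk;
`save_cohort()`/`load_cohort()` round-trip cohorts through
NIfTI + CSV/YAML + JSON with checksummed manifests.

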