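---
title: "Methods: multimodal prediction of treatment resistance with trspredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal prediction of treatment resistance with trspredict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trspredict` predicts a binary clinical outcome — an indication for
clozapine, i.e. treatment-resistant psychosis — in a first-episode cohort
from three data modalities: a mixed-type clinical table, voxel-based
grey-matter concentration maps (VBM), and inter-subject correlation (ISC)
maps of fMRI acquired under identical naturalistic stimulation. This
vignette describes the statistical model, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## Inter-subject correlation maps

For subject $s$ with voxel time courses $x_v(t)$ and a reference group of
$J$ subjects who experienced the same stimulus, the per-voxel map is

$$\bar z_s(v) = \frac{1}{J}\sum_{j=1}^{J}
  \operatorname{artanh}\, r\!\left(x_v,\, y^{(j)}_v\right),$$

the Fisher z-transformed Pearson correlations averaged over the reference
group. Only subject-versus-reference pairs are computed; reference-internal
correlations never enter. The map is kept in z space — averaging is done
after the variance-stabilizing transform and no back-transform is applied.

Numerical choices the definition itself does not settle:

* correlations are clamped to $|r| \le 1 - 10^{-7}$ before `artanh`, so
  numerically identical time courses produce a large finite z rather than
  infinity;
* a voxel whose time course has zero variance (typical at mask edges)
  yields $r = 0$ rather than an error; the count of such voxels is
  reported via a message.

The vectorized implementation is tested against a per-voxel, per-pair
brute-force loop at $10^{-10}$.

## Feature construction

Each voxel map (one VBM map and one ISC map per subject) is pooled
region-wise against an integer-labelled parcellation: minimum, maximum,
mean and standard deviation of the voxels in each region. SD is the sample
standard deviation ($n-1$ denominator), the R convention; a hypothetical
one-voxel region would report 0. With $R$ regions this gives
$8R$ imaging features (at the whole-brain scale $R = 274$, i.e. 2192),
stacked next to the clinical block into one feature vector per subject
with an explicit modality layout.

Clinical preprocessing is fitted on training rows only, inside every
cross-validation run:

* scalar/ordinal variables impute the training mean; binary and
  categorical variables impute the training mode;
* categorical variables are integer-coded against the levels observed in
  training (one column per variable, preserving the input-node count of
  the network); unseen levels map to an explicit "unknown" code 0;
* the nicotine-dependence score is structurally absent for non-smokers
  and follows a conditional rule: absent + non-smoker imputes 0, absent +
  smoker imputes the training mean of observed scores;
* each clinical column is min–max scaled with the training range, so
  training rows land in $[0,1]$; test values outside the range are
  clipped to $[0,1]$ (keeps sigmoid inputs bounded), and a degenerate
  range (max = min, an information-free column) maps to 0.

Imaging features are passed through unscaled: ISC z values and grey-matter
concentrations are naturally order-1, and only the clinical variables are
normalized. Metamorphic tests assert that no test-row perturbation can
change any fitted preprocessing quantity.

## The sparse per-modality network

Every input of every block connects to 10 dedicated first-hidden-layer
nodes; all first-layer nodes of block $b$ connect to block $b$'s single
second-layer node; the second-layer nodes (one per block, 9 with all
modalities at full scale) connect to one output node. All activations are
logistic. Modalities therefore never interact before the output layer:
the unequal feature counts per modality cannot bias the fusion, and each
second-layer activation is a direct per-modality summary. The sparsity is
structural — only existing edges are stored, so absent connections cannot
acquire weight during training (verified by a modality-isolation test).

Training: binary cross-entropy (the canonical pairing with a logistic
output; no loss is otherwise implied by the architecture) minimized by
ADAM with decay 0.9/0.999 and stabilizer $10^{-8}$. One *iteration* is
one mini-batch step — the batch size (10) only makes sense per step — and
batches are drawn uniformly without replacement at each step. Full-scale
defaults: 10 000 iterations, learning rate $10^{-4}$. Weights initialize
uniformly in $\pm\sqrt{6/(\text{fan-in}+\text{fan-out})}$ per connection
group, biases at zero; everything is deterministic given a seed. When a
cohort is so small that the balanced training set is below the batch
size, the cross-validation driver caps the batch at the training-set
size. Analytic gradients are verified against central finite differences
at $10^{-5}$.

The baseline classifier is a linear soft-margin SVM with cost 1, fitted
on the identical feature matrices.

### Prediction and relevance

The output activation is the score; class 1 is called at score ≥ 0.5.
Feature importance uses layer-wise relevance propagation with the epsilon
rule: at each layer a node's relevance is shared among its inputs in
proportion to the contributions $z_j = a_j w_j$, stabilized by
$\varepsilon\,\mathrm{sign}(\sum_j z_j)$ with $\varepsilon = 10^{-6}$.
Two choices make the rule well-behaved in this architecture:

* biases are excluded from the denominator, so total relevance is
  conserved from the output down to the inputs up to $O(\varepsilon)$;
* a first-layer node has exactly one incoming edge, so it hands its whole
  relevance to that input — unless the contribution is exactly zero
  (structurally silent edge), which receives exactly zero.

Relevance toward class 0 starts from $1 - a_3$ with the output weights
sign-flipped (the class-0 logit is the negated class-1 logit). Per run,
relevance is recorded for each test subject toward its *true* class,
correct or not, and summed over runs; per-map means over regions estimate
each imaging map's contribution, and top-10 lists per block (pooled per
modality as the union over its four maps' lists) rank individual features.

## Cross-validation and inference

Randomized-pair cross-validation without resampling: each run tests one
random subject per class and trains on all remaining minority-class
subjects plus an equal-size random subset of the majority class, so
training is always balanced. Run accuracy is 0, 50 or 100 %. The analysis
reports (i) the mean over runs with a percentile-bootstrap CI (10 000
resamples at full scale) and (ii) ensemble hard voting: each subject's
final class is its majority prediction across the runs where it was
tested. Voting ties resolve to the positive class — the costlier miss is
an undetected treatment-resistant patient. Subjects never drawn into any
test pair (possible at very small run counts) are excluded from the voted
confusion with a warning. Confusion metrics with a zero denominator are
reported as NA, never 0.

Significance is a one-sided permutation test on the mean accuracy: the
entire cross-validation is re-run under uniformly shuffled labels, and
$p = (1+k)/(1+P)$ with $k$ the number of permuted means at least as large
as the observed one, so the smallest attainable $p$ at $P = 1000$ is
$1/1001 = 0.000999$. Two analyses (e.g. three-modality versus
clinical-only, or network versus SVM) are compared two-sidedly by
permuting the per-run accuracies between them and referencing the
absolute mean difference, same convention and floor. At desk scale the
number of CV runs inside each permutation is configurable below the
true-label run count; permuted means then have a wider spread than the
observed one, which is conservative for the null-calibration use and
documented wherever used.

## The synthetic cohort generator

The generator exists so that every downstream stage has a testable input
with known ground truth. Defaults mirror the study design: 38 subjects of
whom 7 are positive (18.4 % prevalence), a 44-subject reference group, 81
mixed-type clinical variables with 4.2 % of cells missing completely at
random across 27 designated columns, and a smoking pair (binary flag +
conditionally absent nicotine score) that exercises the conditional
imputation rule.

Imaging emulates exactly the structure the analysis assumes. Each atlas
region has one shared latent "stimulus" signal (standard Gaussian white
noise over time) drawn once per cohort; a subject's voxel time course is
$\kappa \cdot s_r(t) + \sigma\epsilon$ with reference coupling fixed at 1
and positive subjects' coupling multiplied by a per-region attenuation in
$[0,1]$ — so attenuation directly lowers their expected ISC there
(coupling 1 with noise SD 1 gives an expected subject–reference
correlation of 0.5). Grey-matter volumes are a per-region base level
(uniform in 0.35–0.65) plus a per-region group shift for positives plus
voxel noise (SD 0.05). Clinical group effects are standardized mean
shifts, applied on the latent scale for ordinal/binary/categorical
variables. The default effect pattern is moderate (four ~1-SD clinical
shifts of mixed sign, coupling halved in the first quarter of regions,
1-noise-SD grey-matter deficits in three regions); zeroing all three
effect families gives an exact null cohort. The toy parcellation tiles
the grid with contiguous equal-size blocks; the default 20 regions keep
objects desk-sized, with $R = 274$ available for full-scale emulation.

What the generator does **not** emulate: spatial autocorrelation and
smoothing, head motion and physiological artefacts, scanner drift,
hemodynamics (the latent signal is white), realistic marginal
distributions of specific clinical instruments, and correlations among
clinical variables. Passing tests therefore demonstrate that the
machinery recovers the statistical structure it assumes — not that real
acquisitions meet those assumptions.

## Problem sizes used in the shipped checks

The package's own test suite and the reproduction script run at desk
scale, chosen once as the smallest sizes at which each property is
informative:

* null calibration: 20 cohorts (16 subjects, 8 positive, 4 clinical
  variables, 2 regions, 30 timepoints, no planted effects), 200 CV runs
  each at 1000 training iterations, permutation p from 19 permutations of
  20 runs;
* signal recovery: one cohort of 20 subjects (8 positive, 12 clinical
  variables, 5 regions, 80 timepoints) with strong planted effects
  (attenuation 0.2 in three regions, three 1.5-SD clinical shifts,
  2-noise-SD grey-matter shifts), 100 runs at 2000 iterations, 50
  permutations;
* the reproduction script: the full study design (38/7/44, 81 clinical
  variables, 20 regions) with 150 runs at 1500 iterations, 40
  permutations of 20 runs, 2000 bootstrap resamples.

At these training lengths the network is deliberately undertrained
relative to the full-scale 10 000-iteration configuration; the linear SVM
baseline can therefore outperform it at desk scale even where the
network dominates at full training length.

## Known limitations

* The generator's whiteness assumptions make ISC estimation easier than
  on real, autocorrelated fMRI; effective sample sizes per correlation
  are optimistic.
* Integer coding of categorical variables imposes an arbitrary order
  inside the unit interval; one-hot coding would break the fixed
  input-node count of the architecture and is deliberately not offered.
* The permutation test at reduced per-permutation run counts is
  conservative rather than exact.
* With very small run counts, voted labels can be undefined for subjects
  never tested; they are excluded from the confusion counts rather than
  imputed.
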