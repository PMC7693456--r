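---
title: "Methods: salience-network connectivity analysis with snconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salience-network connectivity analysis with snconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patients with end-stage renal disease (ESRD) show cognitive decline whose
network basis is commonly studied through resting-state functional
connectivity (FC) of the salience network (SN) — a set of regions around
the anterior insulae and dorsal anterior cingulate cortex that coordinates
large-scale networks during cognition. A typical study design compares
ROI-to-ROI FC between a patient group and matched healthy controls,
asks whether the altered edges can discriminate the groups, and whether
connectivity mediates the effect of a clinical variable (for instance
hemoglobin, since anemia is near-universal in ESRD) on a cognitive score.

`snconn` implements that full analysis chain as testable, seeded R code:

1. time-series cleaning and Fisher-z FC matrices (`clean_timeseries()`,
   `fc_matrix()`, `framewise_displacement()`);
2. demographic/behavioral group comparison with effect sizes
   (`group_table()`, `two_sample_t()`, `cohens_d_from_t()`);
3. edge-wise group inference with the network-based statistic
   (`nbs()`, `threshold_components()`, `extract_significant_z()`);
4. leave-one-out linear-SVM classification with permutation significance
   and discriminative-weight ranking (`loocv_svm()`,
   `svm_permutation_test()`, `aggregate_weights()`,
   `top_fraction_edges()`);
5. normality-gated Pearson/Spearman association analysis
   (`choose_method()`, `correlate()`, `associate_edges()`);
6. percentile-bootstrap single-mediator mediation with
   suppression-effect detection (`mediate()`, `fit_model4()`,
   `bootstrap_indirect()`, `classify_effect()`);
7. a synthetic cohort generator with planted ground truth
   (`generate_cohort()`) and a pipeline driver (`run_pipeline()`).

Real patient data of this kind are not publicly deposited, so the package
is validated end to end against its own synthetic cohorts, whose ground
truth is known by construction.

## Connectivity model

Each subject contributes a timepoints-by-nodes matrix of ROI signals on
the 19-node SN atlas (`sn_atlas()`: 7 anterior, 12 posterior nodes, MNI
coordinates where published; node order is fixed and shared by all
matrices). FC between two nodes is the Pearson correlation of their
cleaned series, variance-stabilized by Fisher's z = atanh(r). Correlations
are clipped to ±(1 − 1e−7) before the transform so degenerate
(duplicated-signal) inputs stay finite; the matrix diagonal is stored as 0
on both scales so that mask multiplication is well defined.

Cleaning applies, in order, a 4th-order Butterworth low-pass at 0.1 Hz run
forward and backward (zero phase), then one joint least-squares projection
removing intercept, linear trend, and any nuisance regressors. The cited
preprocessing lists detrending and nuisance regression *before* filtering;
we project last because the contract on the output — an exactly zero
fitted trend and exact orthogonality to every nuisance regressor — only
holds if no filter touches the data afterwards (filtering a regression
residual re-introduces small components of the removed signals). The
"bandpass (< 0.1 Hz)" specification is implemented as a low-pass only,
reading the stated upper bound literally. Note that the zero-phase
Butterworth has passband gain slightly below one, so the full cleaning
operator is idempotent only approximately; the projection stage alone
(`cutoff_hz = NULL`) is exactly idempotent, and is tested as such.

Framewise displacement uses the Power formulation: at each frame, the sum
of absolute translation increments (mm) plus the rotation increments
(radians) converted to arc length on a 50 mm sphere. The variant is not
named in the source description ("mean FD power" suggests Power), so the
radius and formula are exposed as arguments.

## Network-based statistic

Edge-wise mass-univariate testing with cluster-level inference on the
graph: (1) a pooled two-sample t statistic per edge (patients minus
controls); (2) a primary threshold, strict inequality, default 3.1 —
one-sided by default in the patients-below-controls direction, i.e. an
edge survives when t < −3.1; (3) connected components of the
supra-threshold graph, with component size measured in edges (the
reference implementation's default, and the natural unit when results are
reported as edge tables); (4) a permutation null for the maximal component
size, re-running steps 1–3 under random exchanges of the group labels
(default N = 5000). Each observed component receives the FWER-corrected
p-value (1 + #{null max ≥ size})/(N + 1), which can never be zero; when
the number of distinct label assignments is below 10^5 and not above N,
the null is enumerated exactly instead. Components with p below alpha
(default 0.05) define the significant-edge mask; the mask multiplied into
each subject's matrix yields the per-subject z table consumed by the
classifier, association, and mediation stages, with edges in a stable
(i, j) lexicographic order.

Two consequences of this construction are worth stating plainly. First,
FWER control is *conservative*: component sizes are small integers, and at
threshold 3.1 on 19 nodes the null maximal size puts roughly 27%
probability on ≥ 1 and well under 1% on ≥ 2, so no attainable rejection
rule has size near 0.05 — the realized family-wise error on null cohorts
is far below the nominal level, which the test suite checks as an upper
bound rather than a two-sided band. Second, cluster-level inference cannot
detect isolated single-edge effects: a size-1 component rarely beats the
null maximum. Planted effects in the generator therefore default to a
*connected* edge set (see below).

## Classifier

A linear soft-margin SVM (LIBSVM via `e1071`, cost 1 by default; the
original analysis names no value) is trained under leave-one-out
cross-validation on the significant-edge z values, patients coded +1 and
controls −1. Features are standardized by each training fold's mean and SD
(practice varies for LIBSVM pipelines; switchable via `standardize`).
Pooled held-out predictions give the confusion counts and the five
proportions (accuracy, sensitivity, specificity, PPV, NPV; patient is the
positive class); pooled decision values give the AUC, computed by the
rank/Mann–Whitney identity and checked in the tests against an explicit
pairwise count. Permutation significance re-runs the entire LOOCV under
label permutation with p = (1 + #{null ≥ observed})/(N + 1) per metric.

Each feature's discriminative weight is the average of the absolute value
of its SVM coefficient across folds; features whose mean absolute weight
strictly exceeds the column mean plus one sample SD are flagged as highly
contributing, and a separate top-20% rule (floor of fraction × count, at
least one) ranks edges by their t values. Published weight tables print
signed values while the averaging rule is defined on absolute values; the
table here stores both, and ranking uses the absolute mean.

Under permuted labels, LOOCV accuracy is *below* 50% in expectation at
small n (the held-out subject's class is under-represented in its training
fold); the chance-level check in the tests uses 30 subjects per class,
where the bias sits inside a ±5-point band.

## Association analysis

For each significant edge × variable pair (patients only, matching the
study design), Shapiro–Wilk at alpha 0.05 on each variable decides the
method: Pearson if both pass, Spearman's rank-order correlation (average
ranks for ties) otherwise. Following the source analysis, raw two-sided
p-values are reported uncorrected; Benjamini–Hochberg q-values over all
tested pairs are added alongside, with a default reporting flag at
p < 0.01.

## Mediation

Model-4 single-mediator mediation of X (clinical variable) on Y
(behavioral score) through M (one edge's Fisher-z connectivity), with age,
gender (0/1 indicator, 1 = male), and education as default covariates.
Three OLS fits on the complete cases — Y ~ X + cov (total effect c),
M ~ X + cov (path a), Y ~ X + M + cov (paths b and c′) — give
indirect = a·b, and the decomposition c = c′ + a·b holds to machine
precision because all three regressions share one sample. Inference on the
indirect effect uses a percentile bootstrap (default 5000 resamples of
subjects with replacement, seeded; BCa is deliberately not the default,
matching the most common usage of the PROCESS macro, and "corrected" in
the source description is ambiguous). Effect classification: *no effect*
if the CI covers 0; *suppression* if the CI excludes 0 while both total
and direct effects are non-significant (OLS t-test at alpha 0.05); *full
mediation* if additionally the total effect is significant and the direct
is not; *partial mediation* otherwise.

When both a = 0 and b = 0, the percentile bootstrap CI of a product is
well known to over-cover: the exclusion-of-zero rate is far below the
nominal 5% (about 1% in this package's coverage simulations). The test
suite therefore asserts that the CI is valid (not anticonservative) rather
than exactly calibrated at the joint null.

## The synthetic cohort generator

`cohort_config()` defaults encode the emulated study conditions: 43
patients vs 43 controls, 19 nodes, 230 retained volumes at TR = 2 s
(240 acquired minus 10 discarded), 24M/19F per group, patient-only
clinical variables with the published marginal means and SDs (hemoglobin
89.7 (22.3) g/L, etc.), and per-group behavioral score distributions from
the published demographics table.

**Population connectivity.** Controls follow a block-structured Fisher-z
matrix: 0.30 within each subnetwork, 0.15 across, and 0.60 on a strongly
connected insula/dACC core — the six edges used for default deficits and
mediation. The strong core is a feasibility requirement as much as a
scientific one: subtracting 0.5 from a weakly positive edge inside an
otherwise positively coupled network demands a negative correlation that
no valid correlation matrix can deliver, and the repair step would then
systematically undo part of the plant. With the core at z = 0.6, planted
deficits land at z = 0.1 and the patient population matrix remains
positive definite.

**Planted deficits.** The default plant subtracts delta_z = 0.5 on five
edges forming a single connected component through the anterior insulae
(dACC–AIS_L, AIS_L–AIS_R, AIS_R–SMG_R, AIS_L–PIS_L, PIS_L–MCC_R), all of
them edges reported by the emulated between-group comparison.
Connectedness is deliberate: the NBS detects clusters, and scattered
single-edge plants would be undetectable by design.

**Between-subject variability.** Each subject's base connectivity is the
sample correlation matrix of m latent Gaussian draws from the group
population matrix, with m = round(1/subject_z_sd²) + 3 (m = 47 at the
default subject_z_sd = 0.15). This Wishart-type construction keeps every
subject's matrix a valid correlation matrix by construction, gives each
edge a Fisher-z SD of about 1/sqrt(m − 3) = subject_z_sd around its
population value, and induces realistic positive dependence among edges.
(Its rejected alternative — independent Gaussian jitter per edge — places
every subject far outside the positive-definite cone, and the repair then
shrinks planted single-edge signals substantially.)

**Mediation structure.** When a `mediation_spec()` is supplied, the
designated edge of each *patient* is overridden by
M = i_M + a·X* + g′cov + e_M, and the designated behavioral score by
Y = i_Y + c′·X* + b·M + g′cov + e_Y, where X* is the standardized clinical
variable (raw hemoglobin has SD 22.3 g/L; structural coefficients on the
raw scale would be meaninglessly small). The mediation fit itself is
scale-equivariant, so analyses may use either scale; recovery checks
standardize X before fitting. Defaults a = 0.5, b = 0.4, c′ = 0.1,
noise SDs 0.2 (mediator, z units) and 0.5 (outcome, score units);
covariate effects default to zero since only marginal distributions are
published. The strength of the hemoglobin–connectivity coupling is not
published at all; a is therefore a free parameter of the generator, not an
asserted quantity.

**Realization.** In time-series mode, each subject's target z matrix is
mapped through tanh, repaired to the nearest positive-definite correlation
matrix by eigenvalue clipping (floor 1e−6) if the mediation override broke
feasibility, and realized as stationary Gaussian series whose sample FC
then carries genuine correlation sampling noise. In matrix mode
(`timeseries = FALSE`), Fisher-z matrices are emitted directly with
emulated sampling noise of SD 1/sqrt(T − 3); this mode is orders of
magnitude faster and is used for the large replication studies in the test
suite. Motion traces are Gaussian random walks on six rigid-body
parameters with step SDs chosen to give mean FD near 0.18 mm, the
published group level.

**What the generator does not emulate.** No hemodynamic response,
physiological noise, scanner drift or spatial structure; stationary
Gaussianity throughout; clinical variables mutually independent unless
configured otherwise. Passing tests on these cohorts demonstrate that the
statistical machinery is correct and calibrated under the declared model —
not that the published patient-data results are reproduced, which would
require the original scans.

## Validation problem sizes

The test suite checks calibration and power at sizes chosen to keep the
whole run in minutes while leaving comfortable statistical margins:
family-wise error on 200 null cohorts of 20 + 20 subjects with 500
permutations each (asserted at or below the upper exact-binomial bound
around 0.05); recovery of the planted connected deficit (delta_z = 0.5,
40 + 40 subjects) in at least 80% of 50 replicates; mediation path
recovery within ±3 SE at 200 patients; and null bootstrap coverage over
500 replicates of 100 patients at 1000 resamples. Worked examples pin the
effect-size, weight-selection, top-fraction, and confusion-metric
arithmetic to published table values, and brute-force oracles (BFS
reachability, pairwise AUC counts, rank-correlation) guard the graph,
AUC, and Spearman paths.

## Known limitations

- The NBS FWER is conservative at these dimensions (see above); reported
  component p-values are honest but the procedure under-rejects at the
  nominal level.
- Structural mediation targets far outside the feasible correlation range
  (a strong coupling on an edge whose endpoints are strongly connected
  elsewhere) are partially absorbed by the positive-definiteness repair;
  with the default planted-deficit geometry the override stays feasible.
- LOOCV metrics on small cohorts are noisy and the permutation test
  inherits the LOOCV pessimism under the null.
- Percentile-bootstrap mediation inference is conservative at the joint
  null; suppression classification depends on OLS path p-values and so
  inherits their assumptions (linearity, homoscedastic errors).
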