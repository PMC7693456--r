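# snconn

Salience-network (SN) functional-connectivity analysis for two-group
resting-state fMRI studies, built around the design used to study
cognitive impairment in end-stage renal disease (ESRD): 43 patients vs 43
healthy controls, ROI-to-ROI connectivity on a 19-node SN atlas (7
anterior, 12 posterior nodes), cluster-level edge inference, machine
classification, and mediation linking a clinical variable to cognition
through connectivity.

The package is for methodologists and neuroimaging analysts who want this
analysis chain as reviewed, seeded, unit-tested code rather than a chain
of point-and-click tools — and who need to validate it against synthetic
cohorts with known ground truth, since patient data of this kind are not
publicly deposited.

## What it computes

- **Connectivity**: cleaned ROI time series (zero-phase 4th-order
  Butterworth low-pass at 0.1 Hz, then one joint projection removing
  intercept, linear trend and nuisance regressors), Pearson ROI-to-ROI
  correlation, Fisher z = atanh(r); Power-formula framewise displacement
  with a 50 mm head radius.
- **Group statistics**: pooled two-sample t, Cohen's
  d = t·sqrt(1/n1 + 1/n2) with a normal-approximation CI, chi-square for
  gender.
- **Network-based statistic (NBS)**: per-edge pooled t (patients minus
  controls), primary threshold |t| or −t > 3.1 (one-sided,
  patients < controls, by default), connected components sized by edge
  count, and a permutation null (N = 5000) of the maximal component size
  giving family-wise-error-corrected component p-values
  (1 + #{null ≥ size})/(N + 1).
- **Classification**: leave-one-out cross-validated linear SVM (LIBSVM
  via e1071, cost 1) on the significant-edge z values; accuracy,
  sensitivity, specificity, PPV, NPV, rank-based AUC; permutation
  p-values per metric; discriminative weights = mean |w| across folds,
  with the mean + 1 SD selection rule and a top-20% edge ranking.
- **Association**: Shapiro–Wilk-gated Pearson/Spearman correlations
  between each significant edge and clinical/behavioral variables in the
  patient group, raw p plus Benjamini–Hochberg q.
- **Mediation (model 4)**: X → M → Y with covariates; three OLS fits give
  a, b, c, c′ with c = c′ + a·b exactly; percentile-bootstrap CI (5000
  resamples) for the indirect effect a·b; effect classification including
  suppression (indirect significant, total and direct not).
- **Synthetic cohorts**: `generate_cohort()` plants connectivity deficits
  on a connected edge set and a hemoglobin → connectivity → digit-span
  mediation structure in a Wishart-type subject model, in either genuine
  time-series or fast connectivity-matrix form.

## Worked example

Simulate a cohort at the study scale with the default planted deficits
plus the mediation edge, and run the full pipeline:

```r
library(snconn)

planted <- rbind(default_planted_edges(0.5),
                 data.frame(i = 1L, j = 3L, delta_z = 0.5))
cohort <- generate_cohort(cohort_config(n_per_group = 43,
                                        timeseries = FALSE,
                                        planted_edges = planted,
                                        mediation = mediation_spec(),
                                        seed = 1))
report <- run_pipeline(list(nbs = list(n_permutations = 1000),
                            classifier = list(n_permutations = 0),
                            mediation = list(m = "dACC--anterior_insula_R",
                                             n_bootstrap = 1000),
                            seed = 1),
                       cohort = cohort)
print(report)
```

```
== Salience-network connectivity pipeline report ==
Synthetic cohort: 43 patients vs 43 controls, 19 nodes, connectivity matrices
Planted deficit on 6 edge(s), delta_z = 0.5
Planted mediation: hemoglobin -> edge(1,3) -> FDST (a=0.5, b=0.4, c'=0.1)

-- NBS --
Network-based statistic (threshold 3.1, one_sided_group1_lt_group2, 1000 permutations)
  component 1: 6 edge(s), 6 node(s), FWER p = 0.000999 *

-- Classifier --
LOOCV linear SVM (cost 1): accuracy 100.00%, sensitivity 100.00%, specificity 100.00%,
  PPV 100.00%, NPV 100.00%, AUC 1.0000
Confusion (patient positive): TP 43, FN 0, TN 43, FP 0

-- Mediation (patients) --
Mediation model 4: hemoglobin -> dACC--anterior_insula_R -> FDST (covariates: age, gender, education), n = 43
        path estimate       se         p
    a (X->M)  0.02062 0.001261 8.650e-19
  b (M->Y|X)  0.25110 0.395400 5.293e-01
   c (total)  0.01572 0.003050 8.155e-06
 c' (direct)  0.01054 0.008716 2.341e-01
indirect a*b = 0.005179
95% percentile bootstrap CI (N = 1000): [-0.01171, 0.02364]
effect class: no_effect
```

Reading the output: the NBS finds one significant component containing
exactly the six planted edges at the permutation floor
p = 1/(1000 + 1); the classifier separates the groups perfectly (a
delta-z of 0.5 against a between-subject SD of 0.15 is a very large
effect); the mediation stage recovers a strong X → M path
(a = 0.0206 per g/L of hemoglobin, i.e. 0.46 per SD of 22.3 g/L) but at
n = 43 the M → Y path is too noisy for the indirect-effect CI to exclude
zero — small mediation designs are underpowered, which is precisely the
kind of behavior the synthetic framework makes visible.

Worked arithmetic examples against published summary tables:

```r
cohens_d_from_t(3.927, 43, 43)        # 0.847  (MoCA row)
unlist(classifier_metrics(35, 8, 27, 16))
#  accuracy sensitivity specificity         ppv         npv
# 0.7209302   0.8139535   0.6279070   0.6862745   0.7714286
```

## Design notes

The methods vignette (`vignettes/salience-network-pipeline.Rmd`) documents
the statistical model of every stage, the generator's Wishart-type subject
model and feasibility-aware planted effects, the conservativeness of NBS
FWER control and of percentile-bootstrap product inference at the joint
null, and all numerical choices (clipping, thresholds, tie-breaks,
permutation-p estimators).
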