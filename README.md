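# bshape

Statistical shape modelling and **B-score** analysis of femoral bone shape
in knee osteoarthritis (OA), with a calibrated synthetic generator for a
paired bilateral-knee trial.

Pathological OA bone change is directional: condyles broaden and flatten
and osteophytes grow at the cartilage-plate rim. The B-score turns a whole
corresponded femoral surface into one number along that direction. Given a
training set of corresponded surfaces x (rigidly aligned by generalized
Procrustes analysis) with non-OA and OA labels, the package fits a PCA
shape space and an *OA vector*

    d = (mean_OA - mean_nonOA) / ||mean_OA - mean_nonOA||

and scores any shape by its standardized orthogonal projection

    B(x) = (c(x)·d - mu_s) / sigma_s

where `c(x)` are the shape-space coordinates of x and `mu_s`, `sigma_s`
are the mean and SD of the non-OA projections for sex *s*. So B = 0 is the
mean non-OA femur of that sex and 1 unit is 1 non-OA SD along the vector;
larger is more pathological.

Around this core the package provides:

* mesh I/O for corresponded triangle surfaces (ascii/binary-LE PLY, OBJ)
  and per-triangle area-change maps along the OA vector;
* a synthetic-cohort generator (`generator_config()`,
  `generate_training_population()`, `generate_trial_cohort()`,
  `generate_test_retest()`) whose defaults are calibrated to the published
  summary statistics of a 78-subject bilateral-knee placebo-controlled
  trial (each subject's contralateral knee is its paired control);
* longitudinal metrics: per-annum OLS slopes, the Bland-Altman smallest
  detectable difference (SDD = 1.96 × SD of test-retest differences), and
  progressor classification (`slope × 4 yr > 0.95 × SDD`);
* the trial statistics: paired and Welch t-tests, Pearson correlations
  with Fisher-z CIs, ICRS-grade subgroups, and quartile stratification of
  cartilage-thickness change by B-score change;
* one-call orchestration: `run_all()` executes simulate → align → PCA →
  OA vector → score → analyze, in a fast score-level mode or a full
  shape-level (mesh) mode, deterministically per seed.

## Worked example

```r
library(bshape)
report <- run_all(list(seed = 7, mode = "score"))
print(report)
```

```
Paired-knee trial report

Per-arm B-score change from baseline (t-based 95% CI):
    knee timepoint_months  n mean_change  ci95_low ci95_high
   index                6 78     0.06067 -0.007405    0.1287
 control                6 78     0.15387  0.088820    0.2189
   index               12 78     0.09792  0.035400    0.1604
 control               12 78     0.20189  0.138728    0.2651

Paired index vs control comparisons (difference = control - index):
  6 months: paired t-test: mean diff 0.0932 (95% CI 0.0107, 0.1757), t = 2.249, df = 77.00, p = 0.02738 (n = 78/78)
  12 months: paired t-test: mean diff 0.1040 (95% CI 0.0265, 0.1814), t = 2.674, df = 77.00, p = 0.009149 (n = 78/78)
```

This simulated replicate behaves like the study it is calibrated to:
both arms drift toward OA (positive mean change), placebo-exposed control
knees roughly twice as fast, and the within-subject paired comparison
favours the treated knee at 6 and 12 months (difference ≈ 0.09 and 0.10
B-score units, p < 0.05). The full report also carries the ICRS-grade
subgroup table, per-region thickness-change correlations for each arm, the
12-month quartile stratification, trajectory summaries against the 0.04
and 0.24 /yr reference slopes, and SDD-based progressor counts. Shape-level
mode (`mode = "shape"`) measures every B-score through the actual mesh
pipeline (template deformation → Procrustes → PCA projection → OA-vector
standardization) instead of using latent scores directly.

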