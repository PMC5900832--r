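# hdpolymarker

Premanifest Huntington's disease (HD) gene carriers can be identified long
before clinical diagnosis, but the standard genetic clock — expected years
to onset from CAG repeat length and age — is unreliable for individuals.
`hdpolymarker` implements an imaging-based alternative: a multimodal
"polymarker" classifier that combines resting-state network coupling,
cortical thickness and subcortical volumes, and whose distance to the
decision hyperplane acts as an individual prognostic score for
phenoconversion within a 5-year follow-up.

The package is aimed at researchers who want to (i) reproduce this style of
analysis end-to-end on simulated cohorts with known ground truth, or (ii)
run the identical pipeline on their own tabular imaging summaries.

## What it computes

* **Genetic clocks** — disease burden `age x (CAG - 35.5)`, estimated years
  to diagnosis `21.54 + exp(9.556 - 0.146 CAG) - age`, the CAP score
  `age (CAG - 33.66)/432.3326`, and the near/far median split.
* **Network coupling** — for each pair of network time courses x, y the
  coupling strength is the mean of the two GLM slopes `beta(y ~ x + nuisance)`
  and `beta(x ~ y + nuisance)` on z-scored series; 19 networks give 171
  couplings per subject. Edges are screened by uncorrected two-sample t
  tests (p < 0.02, two-tailed) into hypo-/hyper-connectivity sets and
  averaged into composite scores.
* **Univariate battery** — mixed-design ANOVA (Type III, centered
  covariate) with generalized eta-squared, one-way ANOVA + Tukey HSD,
  Spearman and partial Spearman with CIs, the Steiger z test for dependent
  correlations, Mann-Whitney with Hodges-Lehmann shift estimates, and a
  Monte-Carlo Lilliefors normality check.
* **Classifier** — per-fold preprocessing (standardize, residualize on age
  and site, rank-based inverse normal), an imbalance-weighted linear SVM
  solved by SMO (C = 1), leave-one-out F1 with the patient class positive,
  a label-permutation null with add-one empirical p
  `(1 + #{null >= obs}) / (1 + n_perm)`, hyperplane-distance conversion
  prediction, and external-cohort validation of the structural classifier.
* **Synthetic cohorts** — a generator planting proximity-to-onset gradients
  in coupling, volumes and thickness, with age and site confounds and a
  heavy-tailed dissociation between estimated and true onset (the source of
  "unexpected converters"). Same seed + config reproduces a cohort
  bit-exactly.

See `vignettes/polymarker-methods.Rmd` for the model, its assumptions and
all numerical choices.

## Worked example

```r
library(hdpolymarker)

cfg <- sim_config()            # 21 controls, 19 carriers, seed 1
report <- run_experiment(cfg, n_perm = 199)
print(report)
```

```
Polymarker experiment report (config hash 413c7506 )
  edge screen at alpha = 0.02: 10 hypo, 8 hyper edges
  classification (199 permutations):
   feature_set  contrast p_value null_mean_f1    f1  n
1         rest     preHD   0.295       0.4470 0.514 40
2         rest      near   0.005       0.2051 0.750 31
3         rest       far   0.565       0.1466 0.143 30
4         rest converted   0.005       0.0262 0.750 26
...
14  polymarker      near   0.005       0.1620 0.824 31
15  polymarker       far   0.010       0.1087 0.571 30
16  polymarker converted   0.005       0.0274 1.000 26
  conversion: MW p = 0.001403, median-split accuracy = 0.74
  external validation (SCV):
   contrast    f1 p_value
1     preHD 0.718   0.010
2      near 0.800   0.005
3       far 0.348   0.695
4 converted 1.000   0.005
```

Reading this: the edge screen recovered the ten planted hypoconnectivity
edges; carriers near onset are classified from controls well above their
permutation null (e.g. polymarker F1 = 0.82 vs a null mean of 0.16,
p = 0.005) while far-from-onset carriers mostly are not; converters are
ranked deeper on the patient side of the hyperplane than nonconverters
(Mann-Whitney p = 0.0014), and a median split of that distance calls
conversion with 74% accuracy in this cohort. The external block trains on
a larger simulated multi-site cohort and validates on this one using
subcortical volumes only.

`render_report(report, "out/")` writes the classification table, screened
edge list, per-subject decision values, null draws, a JSON mirror and a
markdown summary. `write_cohort_bundle()` / `read_cohort_bundle()` move
cohorts through plain CSV/TSV files with provenance headers, and real data
in the same schemas run through the identical pipeline. A thin CLI lives at
`inst/scripts/hdpoly.R`.

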