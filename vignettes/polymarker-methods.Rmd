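---
title: "Methods: simulating and classifying premanifest HD imaging polymarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying premanifest HD imaging polymarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdpolymarker)
```

## The problem

Huntington's disease (HD) gene carriers can be identified decades before
motor diagnosis, but the standard genetic clock — expected years to onset
as a parametric function of CAG repeat length and age — is unreliable for
individuals. This package implements an imaging-based alternative: a
"polymarker" that combines resting-state network coupling, cortical
thickness (CT) and subcortical volumes (SCV) in one imbalance-weighted
linear support-vector machine (SVM), evaluated by leave-one-out (LOO) F1
against a label-permutation null, with the signed distance to the decision
hyperplane serving as an individual prognostic score for phenoconversion
within a 5-year follow-up.

Because no patient-level data are public, the package pairs the analysis
stack with a synthetic-cohort generator whose parameters were chosen once
to emulate the published cohort structure. Everything downstream of the
generator accepts real data in the same tabular schemas.

## Genetic clocks

Three deterministic scores are provided. The disease burden score is
`age * (CAG - 35.5)`. Estimated years to diagnosis uses the parametric
expected-onset form `21.54 + exp(9.556 - 0.146 * CAG) - age`; the
constants come from the standard published CAG-onset model (the
probabilistic survival form of that model is out of scope). The CAP score
is `age * (CAG - 33.66) / 432.3326`, approximately 1 at expected onset.
Scores outside the model's validated CAG range 36--56 are computed but
flagged. Carriers are median-split on estimated years to diagnosis into
`near` and `far` subgroups; ties and the median element go to `near`, so
19 carriers split 10/9.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; `simulate_cohort()` draws a
cohort from them. The defaults describe a single-site cohort of 21
controls and 19 carriers, 19 networks x 300 timepoints (TR 2 s), and a
5-year follow-up.

The central modelling choice is how the *true* (latent) years to onset
relate to the genetic estimate. We use a multiplicative heavy-tailed
error, `latent = est * exp(0.4 * t)` with `t` Student-t (3 df). Two
properties motivated this over an additive error. First, onset-model
uncertainty grows with predicted distance, so proportional errors are the
natural scale; second, additive heavy-tailed errors give genuinely
far-from-onset carriers near-onset pathology at rates that would make the
far subgroup separable from controls — contradicting the robust empirical
pattern that far carriers look like controls on imaging. The heavy tail
still produces occasional drastic misestimates, which is what creates
"unexpected converters" (carriers who convert despite estimates of 10-30
years). Cohort draws are conditioned on containing at least
`min_converters = 3` converters (the emulated study observed 8 of 19), so
a conversion analysis is always well defined; set `min_converters = 0`
for unconditioned draws.

Pathology follows a convex latent-proximity gradient
`g = min(max(1 - latent/16, 0)^2, 1.5)`: zero beyond 16 years from true
onset, accelerating toward onset, capped for overdue onsets. Feature
deficits scale linearly with `g`:

* **Coupling.** Ten designated network pairs lose up to 0.45 coupling
  (baseline 0.3) and five pairs gain up to 0.25 (baseline 0.05); all
  other pairs are uncoupled. Per-subject edge jitter (SD 0.03) adds
  biological variability, and targets are repaired toward the identity if
  jitter pushes them off the positive-definite cone. Time courses are
  drawn from the target correlation via its Cholesky factor, then six
  motion-like and one white-matter-like AR(1) nuisance series are mixed
  in; the coupling estimator removes them by regression.
* **SCV.** Six bilateral structures with baselines around literature
  values (caudate 7,000 mm^3, putamen 9,600 mm^3, ...), full-gradient
  losses of 3,100/4,100/1,020 mm^3 for caudate/putamen/pallidum (smaller
  elsewhere), an age slope of -20 mm^3/yr, and noise SDs (caudate 400
  mm^3, ...) consistent with the group-difference confidence intervals
  reported for such cohorts.
* **CT.** 74 parcels x 2 hemispheres around 2.5 mm with a sinusoidal
  parcel profile, a global per-subject thickness factor (SD 0.05 mm),
  thinning up to 0.36 mm x a per-parcel loading, age slope -0.004 mm/yr,
  parcel noise 0.08 mm.

Site effects are additive per-feature offsets drawn once per site (scaled
by each feature's noise SD), which makes site residualization testable;
sites are assigned round-robin so no site has fewer than two subjects.

What the generator does *not* emulate: image space (no volumes or
surfaces), longitudinal scans, somatic CAG instability, motion-group
interactions, non-Gaussian signal artifacts, and any spatial correlation
structure among CT parcels beyond the shared subject factor. Passing
tests therefore demonstrate that the *pipeline* recovers planted
structure under realistic noise, not that real HD data carry that
structure.

These parameters were calibrated once against the published cohort table
and result pattern by measuring replicate rates over 30-40 seeded cohorts
per candidate setting, then frozen. At the frozen defaults the
qualitative pattern — hypoconnectivity composite ordered near < far <=
control; near-vs-control classifiable while far-vs-control is not;
converters ranked deeper than nonconverters on hyperplane distance —
held in roughly 100%, ~90% and ~92% of replicate cohorts respectively,
which is why the packaged checks evaluate the pattern over several
replicate cohorts and require the majority, rather than betting a binary
outcome on one draw.

## Network coupling

For a network pair (x, y), both series are z-scored and two GLMs are fit:
y on x and x on y, each with an intercept and the nuisance series. The
coupling strength is the mean of the two slope betas. Z-scoring first
makes the average scale-free — without it the two betas differ by the
variance ratio and their mean is unit-dependent. With no nuisance the
estimator reduces exactly to the Pearson correlation, and it is symmetric
by construction. Whether the original analysis z-scored is unstated; the
vectorized implementation exposes the same convention everywhere, and the
equality-to-correlation property pins the behaviour down.

Edges are screened by per-pair pooled-variance two-sample t tests at an
uncorrected two-tailed threshold (default 0.02), split into hypo- and
hyper-connectivity by the sign of the patient-minus-control difference.
No multiplicity correction is applied — deliberately, mirroring the
original screening procedure; the composites it feeds are descriptive.
The composite scores (unweighted means over each direction's edges) are
*never* given to the cross-validated classifier, which consumes the full
coupling vector; this keeps the circular composite definition out of the
CV loop. An empty direction yields an explicit "no composite defined"
result rather than a zero.

## The statistical battery

`rm_anova()` implements the univariate mixed-design ANOVA with Type III
sums of squares (sum-to-zero contrasts, centered covariate), computed
from the multivariate linear model with an orthonormal within-subject
contrast basis. Reported dfs are the uncorrected ones: a 171-level within
factor with 2 groups of 40 subjects gives (170, 6460), a 6-level factor
with an age covariate gives (5, 185), and the covariate costs one
denominator df (n - G - 1). Greenhouse-Geisser corrections are computed
on request but off by default, since the designs of interest report
uncorrected dfs; with more within levels than subjects the error SSP is
singular and no sphericity correction exists. Generalized eta-squared
follows the observed-factor rules with the covariate as the only observed
factor: measured-effect sums of squares join every error stratum in the
denominator.

Other members: one-way ANOVA with classical eta-squared; Tukey HSD with
studentized-range p values and simultaneous CIs; Spearman correlations
with t-approximation p values and Fisher-z CIs (bootstrap optional —
published CIs for such data are inconsistent with Fisher-z widths at
n = 19 and the method behind them is unstated, so no attempt is made to
reverse-engineer them); partial Spearman as the correlation of rank
residuals; the Steiger Z1* test on correlation magnitudes (signs are
absorbed by reflecting variables, which also reflects the
predictor-predictor correlation); Mann-Whitney with both U conventions
*and* the rank sum W (published "U" values for these designs exceed
n1*n2 and are only consistent with a rank sum), exact p for n1*n2 <= 64
without ties, tie-corrected normal approximation otherwise, and the
Hodges-Lehmann shift (median of all pairwise differences) with an
order-statistic CI; and a Lilliefors-style normality check whose p value
is simulated because parameter estimation invalidates the textbook KS
null.

## Classifier preprocessing and evaluation

Features pass through standardize -> residualize on age and site
indicators -> rank-based inverse normal (Blom scores,
`qnorm((r - 3/8)/(n + 1/4))`, average ranks for ties). All parameters,
including the reference values for the normal-score mapping, come from
the training subjects only; held-out subjects are mapped by linear
interpolation into the reference scores, clamped at the extremes. One
contract cannot survive the final step exactly: residualization makes
features exactly uncorrelated with the covariates on the fit population,
but the rank-inverse-normal step is a monotone *nonlinear* transform, so
after it the correlation is only approximately zero. The exact-zero
property is therefore exposed and tested at the residualized stage
(`apply_preprocess(..., rin = FALSE)`).

The SVM solves the standard soft-margin dual by sequential minimal
optimization (maximal-violating-pair working-set selection) with
per-sample costs proportional to inverse class frequency, normalized to
mean 1, at fixed C = 1 (no tuning loop). The solver is validated against
an independent SVM implementation on toy problems; the contract is the
optimum, not the algorithm.

Evaluation is leave-one-out with the preprocessing refit inside every
fold, pooled into one confusion matrix, summarized by F1 with the patient
class positive (F1 = 0 when there are no positive predictions). The
permutation test shuffles labels (class counts preserved), recomputes the
full LOO F1 each time, and reports the add-one empirical p,
`(1 + #{null >= observed}) / (1 + n_perm)`, which can never be zero. All
permutations are drawn up front from one seed, so results are independent
of execution order. Because the preprocessing chain never sees labels,
per-fold transformed features and Gram matrices are computed once and
reused across permutations — bit-identical to refitting, three orders of
magnitude faster. A `paper_mode` flag reproduces the leakier convention
of fitting the preprocessing once on the full sample, for comparability;
fold-safe is the default. An `engine = "r"` reference path reimplements
the whole loop from the exported building blocks and is tested to agree
with the fast path to 1e-8.

Hyperplane distances are `(w.x + b)/||w||`; carriers are ranked by
distance and median-split into predicted converters/nonconverters. For
conversion prediction the model is trained on a low-dimensional
multimodal summary (six SCVs, mean CT, and the two composites) rather
than the full polymarker: with p = 325 >> n = 40 the preprocessed classes
are linearly separable and the SVM pins most carriers exactly on the
margin, collapsing the distance ranking into ties; with p < n the
distances stay graded. The model remains blind to conversion outcomes.

External validation trains preprocessing and SVM on one cohort and scores
a second cohort once; the null comes from shuffling the *test* labels
against the fixed predictions (the original description does not state
what was permuted; retraining per permutation would multiply cost without
changing the fixed-model question being asked). Site effects cannot be
transported across cohorts with disjoint site sets, so the test cohort's
site offsets are removed by site-wise centering of its standardized,
age-adjusted features, while scale, age coefficients and the
normal-score reference stay with the training cohort.

## Numerical choices and degenerate inputs

Constant series, constant features in a fold, rank-deficient designs
(reported with the offending regressor names), single-class folds, unseen
sites, sub-minimal sample sizes and non-positive-definite coupling
targets are all hard errors, not silent repairs. SMO uses a KKT tolerance
of 1e-6 with a deterministic selection rule, so repeated fits are
identical. Median splits send ties toward the near/converter side. The
subcortical structure set is fixed at caudate, putamen, pallidum,
thalamus, hippocampus, amygdala (hemispheres summed; per-hemisphere entry
is a configuration away but collapsed is the default).

## Problem sizes in the packaged checks

The packaged tests run the chance-level check at n = 40 with 199
permutations over 20 seeds, the calibration check over 200 null
replicates at n = 20, and the pattern checks over five replicate default
cohorts at 199 permutations; these sizes give the binomial and KS
assertions enough resolution while keeping a full test run on one CPU in
minutes. The full-scale analysis (1,000 permutations, all four feature
sets and contrasts, external validation at 118/121) is one
`run_experiment(n_perm = 1000)` call.

## Known limitations

The generator's independence assumptions (noise independent across
features and subjects) make the classification task easier than real
multi-scanner data; absolute F1 levels on synthetic cohorts are not
comparable to published values and are not asserted anywhere — only
structural, calibration and qualitative-pattern properties are. The
far-vs-control "at chance" pattern has an irreducible ~5% false-positive
rate by construction of the permutation test, which is why it is checked
by majority over replicates. Regression-on-years-to-onset variants,
nonlinear kernels, feature selection and probability calibration are out
of scope.
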