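---
title: "Methods: expert-weighted biopsychosocial prioritization of surgical waiting lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expert-weighted biopsychosocial prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopriority)
```

## The problem and the model

Elective surgical waiting lists are commonly served first-come, first-served,
which ignores how urgent, severe, or socially burdened individual patients
are. `biopriority` implements a hybrid prioritization framework for this
setting, developed for a high-complexity ENT unit but generic in its
machinery. It combines four ingredients:

1. **Expert weight aggregation.** A panel of $M$ physicians rates the
   importance of each of $n$ decision variables on a 0–10 scale. The weight
   of variable $i$ is its share of the total rating mass,
   $$w_i = \frac{1}{W}\sum_{m=1}^{M} \mu_{i,m}, \qquad
     W = \sum_{i=1}^{n}\sum_{m=1}^{M} \mu_{i,m},$$
   so that $\sum_i w_i = 1$. This is a direct-rating variant of AHP-style
   multi-criteria weighting: there are no pairwise comparison matrices or
   eigenvector consistency machinery, by design — the elicitation is a
   single direct rating per (variable, rater). Inter-rater agreement is
   summarized by mean pairwise Cohen's $\kappa$ after discretizing ratings
   into equal-width bins (5 by default; the discretization of a continuous
   0–10 scale is not canonical, so the bin count is exposed).

2. **Expert-share normalization.** Raw patient values are mapped to
   $\alpha_{i,p} \in [0,1]$ as shares of a variable's total clinical impact:
   for ordinal/categorical variables, $\alpha = \rho_c / \sum_j \rho_j$
   where $\rho_c$ is the expert impact score of the observed level; for
   continuous variables the same applied to clinically meaningful intervals
   (half-open $[lo, hi)$, last interval closed — the boundary convention is
   ours, the clinical definitions do not state one); for binary variables
   the two-score share $\rho_{\mathrm{present}} /
   (\rho_{\mathrm{present}} + \rho_{\mathrm{absent}})$. Shares over a
   variable's levels sum to exactly 1, so a multi-level variable's
   attainable maximum is below 1 — the $[0,1]$ statement is an upper bound,
   not an attained range. Per-level scores elicited from several raters are
   averaged arithmetically before normalization.

3. **Weighted-sum scoring and stratification.** The composite priority
   score is $s_p = \sum_i w_i\,\alpha_{i,p}$ ($s = w^\top \alpha$), linear
   by construction so each variable's contribution $w_i \alpha_{i,p}$ is
   exactly traceable. Patients are stratified three ways: empirical
   tertiles of $s$; fixed operational thresholds ($s > 0.29$ High,
   $s < 0.18$ Low, defaults institution-overridable); or k-means clusters
   labeled High/Medium/Low by their mean member score. Score ties at a
   tertile boundary go to the higher-priority group, favoring earlier care.

4. **Stochastic clinical-impact simulation.** A waiting-list simulator
   compares chronological and score-based scheduling under a common
   clinical model: latent risk at waiting time $t$ is
   $\Gamma(\alpha_0 + \delta e^{\lambda t},\, \beta_0)$ truncated to
   $[0, 10]$; urgent hospitalization is a per-day Bernoulli with logistic
   probability $1/(1+e^{-(\gamma R - \theta)})$; admitted patients occupy
   $\mathrm{Poisson}(\lambda_D)$ bed days. Outcomes are summarized over
   Monte-Carlo replicates with 95% percentile confidence intervals.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `missing_threshold` | 0.10 | fraction | patients missing strictly more than this share of variables are excluded; comparison is strict, so exactly 2 of 20 missing is retained |
| `n_bins` (kappa) | 5 | bins | equal-width discretization of 0–10 ratings |
| `perturbation` | 0.10 | fraction | one-at-a-time weight perturbation for the stability analysis |
| `high/low thresholds` | 0.29 / 0.18 | score units | operational cutoffs (30-day scheduling / deferrable) |
| `k` | 3 | clusters | clinical High/Medium/Low target; validated by silhouette and elbow |
| `gamma`, `theta` | 1.8, 4.5 | — | logistic hospitalization model, calibrated values from the originating ENT unit |
| `alpha0`, `beta0`, `delta`, `lambda_t` | 2.0, 1.0, 0.5, 0.05/d | — | Gamma-risk progression; free parameters, institution-calibratable |
| `lambda_D` | 3.8 | days | mean urgent length of stay |
| `capacity`, `horizon` | 2/day, 180 d | — | queue service rate and simulated span (see below) |
| `n_iterations` | 1000 | replicates | Monte-Carlo precision of the CIs |

## Design choices where the design was genuinely open

**Weight renormalization in the sensitivity analysis.** Perturbing one
weight by ±10% breaks the unit sum; we renormalize the whole vector. Only
relative weights matter for ranking, and renormalization keeps the
weighted-sum score on its original scale.

**What gets clustered.** Centroid-based k-means is defined on the numeric
profile vectors. We cluster the *unweighted* normalized profiles by
default: all entries share the $[0,1]$ impact-share scale, and scaling
rows by weights that span 0.023–0.081 distorts the geometry enough that
the k-means optimum stops tracking the latent severity structure (we
verified this empirically: on synthetic cohorts the truth-aligned
partition has a strictly higher objective than the k-means optimum in
weighted geometry). A `weighted` flag flips either choice; the
weight-stability analysis defaults to weighted clustering, since
otherwise cluster assignments cannot respond to weight perturbations at
all and its cluster-stability fraction would be vacuously 1.

**Gower vs. Euclidean.** The mixed-type motivation for Gower dissimilarity
conflicts with centroid-based k-means, which Gower geometry does not
support. Default: Lloyd k-means (k-means++ seeding, 10 restarts, fixed
seed, empty clusters re-seeded at the farthest point) on the normalized
profiles, where Euclidean distance is well defined. A `gower` mode runs
PAM k-medoids on the Gower matrix for users who prefer raw mixed-type
records; `select_k()` computes silhouettes on whichever geometry was used.
In the Gower matrix, continuous variables are range-scaled by their
*declared* clinical domain rather than the sample range, so
dissimilarities are comparable across cohorts; ordinal variables use
rank-normalized positions; categorical and binary use simple mismatch.

**Separation testing.** Cluster separation is tested with a
Wilks'-lambda-style statistic $\det(W)/\det(W+B)$ under a label
permutation null instead of the classical MANOVA F approximation: the
permutation version is exact by construction and remains valid at the
small cluster sizes of toy instances. Mahalanobis centroid distances use
the pooled within-cluster covariance, ridge-regularized if singular.

**PCA.** Computed on centered, unscaled profiles (entries already share a
scale), with the sign convention that each loading's largest-magnitude
entry is positive; rank-deficient inputs report a zero-variance second
component rather than failing.

**Queue mechanics.** The scheduling contract is: per day, up to `capacity`
patients leave for surgery (chronological: ascending entry day, ties by
id; prioritized: descending score, ties by entry day); each still-waiting
patient draws a risk at their elapsed wait and can experience at most one
urgent admission, after which they are escalated to the front of the
queue; patients still waiting at the horizon are censored and flagged.
Entry dates are treated as a waiting-list *snapshot*: the latest entry is
day 0 and earlier entries carry accrued waiting time, so the queue is
congested from the start as a real list is. "Risk at decision time" is
the risk drawn on the day of surgery (or at the horizon when censored);
bed days per patient are reported both per hospitalized patient and per
patient overall. Defaults `capacity = 2`/day with a 180-day horizon let a
205-patient list clear in about 103 days — a persistently loaded but
fully served queue.

**Risk calibration.** The Gamma-risk constants are free parameters. The
shipped defaults (2.0, 1.0, 0.5, 0.05/day) make expected untruncated risk
grow from 2.5 at listing to the top of the scale within a few months.
Note a calibration property: combined with the logistic defaults
($\gamma = 1.8$, $\theta = 4.5$), the *per-day* admission probability is
already ≈0.5 at listing, so over long waits nearly every simulated
patient is admitted once and the percentage-hospitalized indicator
saturates; the indicator differentiates policies only under shorter waits
or a recalibrated risk curve. All constants are exposed in
`simulation_config()` / scenario YAML for institutional calibration.

**Common random numbers.** Both policy arms of a replicate share a seed
(variance reduction when differencing arms); disable with
`use_crn = FALSE`.

## The synthetic-cohort generator

`generate_cohort()` emulates the study conditions: 205 patients, 20
mixed-type biopsychosocial variables, a latent High/Medium/Low severity
structure with equal proportions, a 20×7 expert rating matrix
(`generate_ratings()`: latent consensus uniform on $[0,10]$ plus clipped
Gaussian rater noise, SD 1), MCAR missingness (2% per cell by default),
binary demographic attributes with group-independent prevalences (the
null fairness scenario), and entry dates uniform over a 120-day listing
window.

Group-conditional level distributions are a softmax over the variable's
normalized impact shares with a Gaussian kernel around a group-specific
target, $P(c \mid g) \propto \exp(-\tau(\alpha_c - m_g)^2)$ with
$\tau = 50$. Because this is a linear exponential-family tilt in
$\alpha_c$, group mean profiles are strictly ordered High > Medium > Low
whenever the targets are. The symmetric target offset is solved per
variable so that *adjacent* groups' mean normalized values differ by
`effect_size` (default 0.25); variables whose impact-share range cannot
support the requested separation are clipped to their attainable maximum
with a warning. We chose the kernel form over a plain linear tilt because
it separates two concerns: the target offset controls between-group
separation while $\tau$ controls within-group spread.

What the generator deliberately does **not** emulate: the real cohort's
marginal distributions (unpublished), informative missingness (the
imputation remedy is specified, not the missingness mechanism, so MCAR is
the neutral choice), correlations between variables beyond those induced
by the latent group, and demographic attributes that depend on severity.
Passing tests on synthetic cohorts therefore demonstrate that the
machinery recovers planted structure under clean conditions — not that
the clinical conclusions transfer to any particular real cohort.

## Numerical choices, degenerate inputs, tie-breaks

* Weight aggregation rejects an all-zero rating matrix ($W = 0$).
* A rater pair constant in the same bin has chance agreement 1; $\kappa$
  is defined as 1 by convention and the pair is flagged.
* Imputation mode ties break by declared level order; binary order is
  (present, absent). Subgroups are decade age bands × diagnosis, falling
  back to the whole cohort when a subgroup has no donors.
* All-identical scores under tertile labeling yield all-Medium with a
  warning; tied cluster mean scores break by the higher maximum member
  score, with a warning.
* Zero-range numeric variables contribute 0 to Gower dissimilarity and
  are flagged.
* Lloyd iterations stop when the objective improvement and centroid
  movement fall below `tol` ($10^{-6}$); the per-iteration objective trace
  is retained and asserted non-increasing in the test suite.
* Permutation p-values use the add-one estimator
  $(1 + \#\{\lambda^* \le \lambda\})/(1 + B)$, never exactly zero.
* The parity test switches to a Monte-Carlo exact test when any expected
  cell count is below 5; a constant attribute returns $p = 1$, flagged.

## Problem sizes used by the shipped checks

The test suite and acceptance script run entirely on synthetic data at the
study scale: cohorts of 205 patients (smaller for toy fixtures), 50-seed
cluster-recovery sweeps, $10^5$ draws for closed-form distributional
checks, 99–999 permutations for the separation test, and 1000 replicates
for type-I-error calibrations. These sizes give Monte-Carlo standard
errors comfortably inside the asserted tolerances (3-SE bands throughout).

## Known limitations

* Expert weights inherit the subjectivity of the panel; $\kappa$ and the
  ±10% stability analysis quantify but do not remove it.
* k-means assumes roughly spherical groups in profile space; strongly
  non-convex or overlapping populations would need model-based or
  density-based alternatives.
* The simulator's headline indicators depend on unpublished calibration
  constants wherever a real unit is concerned; shipped defaults are
  structurally sensible, not institution-specific.
* The fairness audit tests demographic parity of label assignment only;
  it is a diagnostic for structural imbalance, not an equalized-odds or
  counterfactual analysis.

## Worked example

```{r example, eval = FALSE}
reg <- default_registry()
cfg <- synthesis_config()
ratings <- generate_ratings(cfg, reg, seed = 7)
cohort  <- generate_cohort(cfg, reg, seed = 8)

pl <- run_pipeline(cohort$cohort, ratings$ratings, reg, seed = 42)
pl
head(sort(pl$scores, decreasing = TRUE))
contribution_report(pl$weights, pl$alpha, names(which.max(pl$scores)))

fairness_audit(pl$cluster_labels, pl$cohort)
oc <- monte_carlo_compare(pl$cohort, pl$scores, pl$cluster_labels,
                          simulation_config(n_iterations = 200, seed = 42))
oc
```
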