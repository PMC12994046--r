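# biopriority

Expert-weighted, biopsychosocial prioritization of surgical waiting lists.

Public surgical waiting lists are usually served first-come, first-served,
which ignores how urgent, severe, or socially burdened individual patients
are. `biopriority` is an R implementation of a hybrid multi-criteria
prioritization framework for this setting — built around the workflow of a
high-complexity ENT unit, but generic: it takes a registry of mixed-type
decision variables (ordinal, categorical, continuous, binary), a panel of
expert ratings, and a patient cohort, and produces transparent composite
priority scores, a High/Medium/Low stratification, and simulated estimates
of the clinical impact of scheduling by priority instead of by arrival.

It is intended for health-services researchers and hospital analytics teams
who need prioritization that is traceable variable-by-variable rather than
a black box.

## The model

* **Weights** (direct-rating AHP variant): each of *M* experts rates each of
  *n* variables on 0–10; `w_i = Σ_m μ_im / W` with `W = Σ_i Σ_m μ_im`, so
  `Σ w_i = 1`. Agreement is summarized by mean pairwise Cohen's κ.
* **Normalization** (expert-impact shares): a raw value maps to
  `α_ip = ρ_c / Σ_j ρ_j`, the share of the variable's total expert impact
  attributable to the observed level/interval; binary variables use the
  two-score share. All `α ∈ [0, 1]`.
* **Score**: `s_p = Σ_i w_i α_ip` (`s = wᵀα`), with exact per-variable
  contribution reports, tertile or fixed-threshold labels (defaults 0.29 /
  0.18), and k-means stratification (Gower/k-medoids as an alternative
  mode) validated by silhouette, PCA projection, and a permutation-MANOVA
  centroid-separation test.
* **Simulation**: latent clinical risk `R(t) ~ Γ(α₀ + δe^{λt}, β₀)` capped
  at 10; urgent hospitalization per day with probability
  `1/(1+exp(−(γR−θ)))` (γ = 1.8, θ = 4.5); `Poisson(λ_D = 3.8)` urgent bed
  days; chronological vs. prioritized scheduling compared over Monte-Carlo
  replicates with 95% percentile CIs.

A synthetic-cohort generator (205 patients, 20 variables, latent 3-group
severity structure, 7-rater panel, demographic attributes) makes the whole
pipeline testable without access to any real cohort; a demographic-parity
fairness audit checks label assignment against protected attributes.

## Worked example

```r
library(biopriority)
reg     <- default_registry()                       # the 20-variable framework
cfg     <- synthesis_config()
ratings <- generate_ratings(cfg, reg, seed = 7)     # 20 x 7 expert panel
cohort  <- generate_cohort(cfg, reg, seed = 8)      # 205-patient cohort

pl <- run_pipeline(cohort$cohort, ratings$ratings, reg, seed = 42)
pl
#> Prioritization pipeline: 204 patients, 20 variables
#>   excluded: 1 | score range: 0.137-0.571
#>   cluster sizes: 69, 68, 67 | separation p = 0.005
```

One patient was excluded for missing more than 10% of variables; the rest
were imputed within age-band × diagnosis subgroups. Scores span 0.137–0.571
and the three clusters separate significantly (permutation MANOVA,
p = 0.005). Each score decomposes exactly into per-variable contributions:

```r
head(contribution_report(pl$weights, pl$alpha, names(which.max(pl$scores))), 3)
#>   variable_id     weight     alpha contribution
#> 1        Olim 0.09497626 0.7500000   0.07123219
#> 2         Com 0.10995967 0.5625000   0.06185231
#> 3       Dtras 0.10982691 0.5333333   0.05857435
```

The fairness audit finds no association between priority labels and the
(group-independent, by construction) demographic attributes:

```r
fairness_audit(pl$cluster_labels, pl$cohort)
#>   attribute       test statistic   p_value p_adjusted
#> 1   dem_ses chi-square 0.0584100 0.9712173          1
#> 2 dem_rural chi-square 0.9311761 0.6277658          1
```

Simulating both scheduling policies (here 200 Monte-Carlo replicates):

```r
monte_carlo_compare(pl$cohort, pl$scores, pl$cluster_labels,
                    simulation_config(n_iterations = 200, seed = 42))
#>                  indicator        policy   mean ci_low ci_high
#>                  mean_risk chronological  10.00  10.00   10.00
#>         wait_high_priority chronological 110.00 110.00  110.00
#>                  mean_risk   prioritized   9.47   9.37    9.57
#>         wait_high_priority   prioritized  74.40  74.40   74.40
```

(abridged): prioritized scheduling cuts the High-priority group's mean wait
from 110 to 74 days and lowers mean exit risk; bed-day indicators
(≈ 3.8 days/admission) are policy-independent here because nearly all
simulated patients are eventually admitted under the default risk
calibration — see the methods vignette
(`vignettes/prioritization-methods.Rmd`) for the calibration discussion.

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","biopriority.R",package="biopriority"))')" \
  weights --ratings ratings.csv --out weights.csv --kappa
```

Subcommands: `weights`, `normalize`, `score`, `cluster`, `simulate`,
`synth`, `fairness`.

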