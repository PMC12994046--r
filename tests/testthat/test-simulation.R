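test_that("risk draws follow the time-inhomogeneous Gamma model", {
  # delta = 0: constant shape alpha0, mean alpha0/beta0
  cfg <- simulation_config(alpha0 = 2, beta0 = 1, delta = 0, risk_cap = 100)
  set.seed(1)
  x <- sample_risk(rep(5, 1e5), cfg)
  se <- sqrt(2) / sqrt(1e5)           # Gamma(2,1) sd = sqrt(2)
  expect_lt(abs(mean(x) - 2), 3 * se)

  # lambda_t = 0: time-invariant shape alpha0 + delta
  cfg2 <- simulation_config(alpha0 = 1, delta = 0.5, lambda_t = 0,
                            beta0 = 1, risk_cap = 100)
  set.seed(2)
  a <- sample_risk(rep(0, 2e4), cfg2)
  b <- sample_risk(rep(300, 2e4), cfg2)
  expect_lt(abs(mean(a) - mean(b)), 4 * sqrt(1.5) / sqrt(2e4))

  # truncation: the cap binds at large t
  cfg3 <- simulation_config()
  set.seed(3)
  expect_true(all(sample_risk(rep(200, 1000), cfg3) <= cfg3$risk_cap))
  expect_error(sample_risk(-1, cfg3), ">= 0")
})

test_that("risk grows with elapsed waiting time", {
  cfg <- simulation_config(risk_cap = 1000)  # uncapped view
  set.seed(4)
  means <- sapply(c(0, 30, 60, 90), function(t) mean(sample_risk(rep(t, 5000), cfg)))
  expect_true(all(diff(means) > 0))
})

test_that("the logistic hospitalization model matches closed forms", {
  # midpoint: risk = theta / gamma
  expect_equal(hospitalization_prob(4.5 / 1.8), 0.5)
  expect_equal(hospitalization_prob(2.5, gamma = 2, theta = 5), 0.5)
  # direct evaluations at the calibrated parameters
  expect_equal(hospitalization_prob(4.5), 1 / (1 + exp(-3.6)), tolerance = 1e-12)
  expect_equal(round(hospitalization_prob(4.5), 4), 0.9734)
  expect_equal(hospitalization_prob(0), 1 / (1 + exp(4.5)), tolerance = 1e-12)
  expect_equal(round(hospitalization_prob(0), 4), 0.0110)
  # strict monotonicity in risk
  r <- seq(0, 10, by = 0.5)
  expect_true(all(diff(hospitalization_prob(r)) > 0))
})

test_that("bed days are Poisson: mean and variance both near lambda_D", {
  cfg <- simulation_config()
  set.seed(5)
  d <- sample_bed_days(1e5, cfg)
  expect_lt(abs(mean(d) - 3.8), 3 * sqrt(3.8 / 1e5))
  # equidispersion: Var(s^2) ~ (lambda + 2 lambda^2)/n for Poisson
  expect_lt(abs(stats::var(d) - 3.8), 3 * sqrt((3.8 + 2 * 3.8^2) / 1e5))
})

test_that("instant clearance: enough capacity means zero waits and no admissions", {
  cohort <- data.frame(patient_id = paste0("p", 1:8), entry_date = 0)
  cfg <- simulation_config(capacity = 8, horizon = 10)
  traj <- with_seed(1, simulate_policy(cohort, policy = "chronological",
                                       config = cfg))
  expect_true(all(traj$wait == 0))
  expect_false(any(traj$hospitalized))
  expect_false(any(traj$censored))
})

test_that("the prioritized policy operates the higher score first", {
  cohort <- data.frame(patient_id = c("lo", "hi"), entry_date = c(0, 0))
  s <- c(lo = 0.1, hi = 0.9)
  cfg <- simulation_config(capacity = 1, horizon = 5)
  traj <- with_seed(2, simulate_policy(cohort, s, "prioritized", cfg))
  expect_equal(traj$surgery_day[traj$patient_id == "hi"], 0)
  expect_equal(traj$surgery_day[traj$patient_id == "lo"], 1)
  # chronological: ties on entry day broken by id
  traj2 <- with_seed(2, simulate_policy(cohort, policy = "chronological",
                                        config = cfg))
  expect_equal(traj2$surgery_day[traj2$patient_id == "hi"], 0)
})

test_that("hospitalization frequency matches the logistic probability", {
  # gamma ~ 0 makes the per-day admission probability a known constant
  p0 <- 1 / (1 + exp(4.5))
  cohort <- data.frame(patient_id = sprintf("p%03d", 1:201), entry_date = 0)
  cfg <- simulation_config(gamma = 1e-9, capacity = 1, horizon = 1)
  set.seed(6)
  events <- sum(replicate(50, {
    traj <- simulate_policy(cohort, policy = "chronological", config = cfg)
    sum(traj$hospitalized)
  }))
  n_trials <- 50 * 200            # one Bernoulli per still-waiting patient
  se <- sqrt(n_trials * p0 * (1 - p0))
  expect_lt(abs(events - n_trials * p0), 3 * se)
})

test_that("undercapacity censors instead of erroring and flags patients", {
  cohort <- data.frame(patient_id = paste0("p", 1:10), entry_date = 0)
  cfg <- simulation_config(capacity = 1, horizon = 4)
  traj <- with_seed(7, simulate_policy(cohort, policy = "chronological",
                                       config = cfg))
  expect_equal(sum(traj$censored), 6L)
  expect_true(all(is.na(traj$wait[traj$censored])))
  expect_true(all(!is.na(traj$exit_risk)))
})

test_that("equivalent policies produce identical outcomes under common random numbers", {
  set.seed(8)
  cohort <- data.frame(patient_id = sprintf("p%02d", 1:30),
                       entry_date = sample(0:29))
  # scores that reproduce the chronological order exactly
  s <- stats::setNames(1 - cohort$entry_date / 100, cohort$patient_id)
  lab <- assign_priority_labels(s, "tertile")
  cfg <- simulation_config(capacity = 1, horizon = 60, n_iterations = 10,
                           seed = 11)
  oc <- monte_carlo_compare(cohort, s, lab, cfg)
  expect_equal(oc$replicates$chronological, oc$replicates$prioritized,
               tolerance = 1e-12)
})

test_that("Monte-Carlo comparison is bit-reproducible for a fixed master seed", {
  set.seed(9)
  cohort <- data.frame(patient_id = sprintf("p%02d", 1:25),
                       entry_date = sample(0:60, 25))
  s <- stats::setNames(runif(25), cohort$patient_id)
  lab <- assign_priority_labels(s, "tertile")
  cfg <- simulation_config(capacity = 1, horizon = 40, n_iterations = 5,
                           seed = 123)
  oc1 <- monte_carlo_compare(cohort, s, lab, cfg)
  oc2 <- monte_carlo_compare(cohort, s, lab, cfg)
  expect_identical(oc1$summary, oc2$summary)
  expect_identical(oc1$replicates, oc2$replicates)
  # CI bounds bracket the mean
  expect_true(all(oc1$summary$ci_low <= oc1$summary$mean + 1e-12))
  expect_true(all(oc1$summary$mean <= oc1$summary$ci_high + 1e-12))
  expect_error(monte_carlo_compare(cohort, s, lab,
                                   simulation_config(n_iterations = 1)),
               "n_iterations >= 2")
})

test_that("prioritization shortens the High group's wait in nearly all replicates", {
  reg <- default_registry()
  cfg <- synthesis_config(n_patients = 80, missing_rate = 0)
  coh <- suppressWarnings(generate_cohort(cfg, reg, seed = 51))
  rat <- generate_ratings(cfg, reg, seed = 52)
  pl <- run_pipeline(coh$cohort, rat$ratings, reg, seed = 51)
  scfg <- simulation_config(capacity = 1, horizon = 120, n_iterations = 30,
                            seed = 77)
  oc <- monte_carlo_compare(pl$cohort, pl$scores, pl$cluster_labels, scfg)
  wc <- oc$replicates$chronological[, "wait_high_priority"]
  wp <- oc$replicates$prioritized[, "wait_high_priority"]
  expect_gte(mean(wp <= wc), 0.95)
})

test_that("scenario YAML round-trips into a simulation configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("gamma: 2.0", "theta: 5.0", "lambda_D: 2.5", "horizon: 30",
               "capacity: 4", "n_iterations: 10", "seed: 9"), path)
  cfg <- read_scenario(path)
  expect_equal(cfg$gamma, 2.0)
  expect_equal(cfg$lambda_D, 2.5)
  expect_equal(cfg$capacity, 4)
  expect_error(simulation_config(lambda_D = -1), "> 0")
  expect_error(simulation_config(capacity = 0), ">= 1")
})
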