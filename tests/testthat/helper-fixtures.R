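# Small in-code fixtures shared across tests.

toy_registry <- function() {
  variable_registry(list(
    variable_spec("sev", "ordinal", levels = c("low", "medium", "high"),
                  impact_scores = c(2, 5, 9)),
    variable_spec("wait", "continuous", breaks = c(0, 6, 12, 24),
                  impact_scores = c(1, 3, 6)),
    variable_spec("comorb", "binary", binary_scores = c(8, 2)),
    variable_spec("area", "categorical", levels = c("ear", "nose", "throat"),
                  impact_scores = c(3, 4, 6))
  ))
}

toy_cohort <- function(registry = toy_registry()) {
  cohort_table(data.frame(
    patient_id = c("p1", "p2", "p3", "p4"),
    sev = c("high", "low", "medium", "high"),
    wait = c(2, 14, 7, 20),
    comorb = c(1, 0, 0, 1),
    area = c("ear", "throat", "nose", "ear"),
    age = c(34, 36, 62, 65),
    diagnosis = c("dx1", "dx1", "dx2", "dx2"),
    entry_date = c(0, 10, 20, 30),
    dem_ses = c(1, 0, 1, 0),
    stringsAsFactors = FALSE), registry)
}

# labeling object from a named label vector, for fairness tests
make_labeling <- function(labels) {
  structure(list(labels = factor(labels, levels = c("High", "Medium", "Low")),
                 method = "fixed", thresholds = NULL),
            class = "priority_labeling")
}

# three well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 10, d = 2, sep = 10, sd = 0.3, seed = 1) {
  set.seed(seed)
  centers <- diag(sep, 3, d)
  X <- do.call(rbind, lapply(1:3, function(k)
    matrix(stats::rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[k, ], n_per, d, byrow = TRUE)))
  list(X = X, truth = rep(1:3, each = n_per))
}
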