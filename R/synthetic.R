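# Synthetic study generator: expert rating matrices and patient cohorts with
# a latent three-group severity structure, so the full pipeline is testable
# without any real data.

#' Synthesis configuration
#'
#' Defines the emulated study conditions: a cohort of `n_patients` over the
#' registry's mixed-type variables with a latent High/Medium/Low severity
#' structure, an `n_raters`-expert rating matrix, MCAR missingness, and
#' binary demographic attributes for the fairness audit.
#'
#' @param n_patients Cohort size (default 205).
#' @param n_raters Expert panel size (default 7).
#' @param group_proportions Latent group mix, High/Medium/Low (default equal
#'   thirds; must sum to 1).
#' @param effect_size Target separation between adjacent priority groups'
#'   mean normalized values, per variable, in normalized (alpha) units (so
#'   High and Low group means differ by twice this; default 0.25, a large,
#'   well-separated structure).
#' @param rating_sd Rater noise SD around the latent consensus, on the 0-10
#'   rating scale (default 1).
#' @param missing_rate MCAR missingness rate per (variable, patient) cell
#'   (default 0.02).
#' @param concentration Softmax concentration of group-conditional level
#'   distributions, in alpha^-2 units (default 50); larger values tighten
#'   within-group spread.
#' @param listing_window Days over which list entries are spread (default 120).
#' @param demographics Named list of binary attribute prevalences; either a
#'   single number (group-independent, the null fairness scenario) or one
#'   prevalence per group c(High, Medium, Low).
#' @return List of class `"synthesis_config"`.
#' @export
synthesis_config <- function(n_patients = 205, n_raters = 7,
                             group_proportions = c(High = 1, Medium = 1, Low = 1) / 3,
                             effect_size = 0.25, rating_sd = 1,
                             missing_rate = 0.02, concentration = 50,
                             listing_window = 120,
                             demographics = list(dem_ses = 0.35,
                                                 dem_rural = 0.30)) {
  if (abs(sum(group_proportions) - 1) > 1e-8)
    stop("group proportions must sum to 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  structure(list(n_patients = n_patients, n_raters = n_raters,
                 group_proportions = group_proportions,
                 effect_size = effect_size, rating_sd = rating_sd,
                 missing_rate = missing_rate, concentration = concentration,
                 listing_window = listing_window, demographics = demographics),
            class = "synthesis_config")
}

#' Generate a synthetic expert rating matrix
#'
#' Draws a latent consensus importance score per variable uniformly on
#' `[0, 10]`; each rater reports the consensus plus Gaussian noise
#' (`rating_sd`), clipped to `[0, 10]`. The latent truth is returned so
#' recovery of the consensus ordering by weight aggregation can be tested.
#'
#' @param config A [synthesis_config()].
#' @param registry A [variable_registry()] fixing variable count and order.
#' @param seed RNG seed.
#' @return List: `ratings` (a [rating_matrix()]), `consensus` (named latent
#'   truth vector).
#' @export
generate_ratings <- function(config, registry, seed = 1L) {
  ids <- registry_ids(registry)
  with_seed(seed, {
    consensus <- stats::runif(length(ids), 0, 10)
    noise <- matrix(stats::rnorm(length(ids) * config$n_raters,
                                 sd = config$rating_sd),
                    length(ids), config$n_raters)
    m <- pmin(pmax(consensus + noise, 0), 10)
    dimnames(m) <- list(ids, paste0("R", seq_len(config$n_raters)))
    list(ratings = rating_matrix(m, registry),
         consensus = stats::setNames(consensus, ids))
  })
}

# Group-conditional level distribution: softmax over normalized impact scores
# with a Gaussian kernel around a group-specific target mean,
# P(level c | target m) proportional to exp(-tau (alpha_c - m)^2). The tilt is
# linear in alpha_c (exponential family), so the realized mean alpha is
# strictly increasing in m: group means are ordered by construction.
.level_probs <- function(alpha_c, m, tau) {
  w <- exp(-tau * (alpha_c - m)^2)
  w / sum(w)
}

.mean_alpha <- function(alpha_c, m, tau) sum(alpha_c * .level_probs(alpha_c, m, tau))

# Solve the symmetric target offset s so that the realized mean separation
# between adjacent groups equals effect_size (High-Low = 2 * effect_size);
# clip (with the offending variable reported) when the variable's attainable
# alpha range cannot support it.
.solve_offset <- function(alpha_c, effect_size, tau) {
  if (length(unique(alpha_c)) < 2L || effect_size == 0)
    return(list(s = 0, clipped = FALSE))
  m0 <- (min(alpha_c) + max(alpha_c)) / 2
  sep <- function(s) .mean_alpha(alpha_c, m0 + s, tau) -
                     .mean_alpha(alpha_c, m0 - s, tau) - 2 * effect_size
  s_max <- 3 * diff(range(alpha_c)) + 1
  if (sep(s_max) < 0) return(list(s = s_max, clipped = TRUE))
  list(s = stats::uniroot(sep, c(1e-9, s_max), tol = 1e-10)$root,
       clipped = FALSE)
}

#' Generate a synthetic patient cohort with latent severity groups
#'
#' Each patient is assigned a latent High/Medium/Low group; per variable, the
#' patient's level (or interval, sampled uniformly within) is drawn from a
#' group-conditional softmax over the variable's normalized impact scores,
#' centered on a group-specific target chosen so that adjacent groups' mean
#' normalized profiles differ by `effect_size` in every variable (clipped
#' with a warning when a variable's score range cannot support the requested
#' separation). Missingness is applied completely at random at
#' `missing_rate`; binary demographic attributes are drawn with the
#' configured (possibly group-specific) prevalences; entry dates are uniform
#' over the listing window. True group labels are returned for
#' cluster-recovery tests.
#'
#' @param config A [synthesis_config()].
#' @param registry A [variable_registry()].
#' @param seed RNG seed.
#' @return List: `cohort` (a [cohort_table()] with `age`, `diagnosis`,
#'   `entry_date` and `dem_*` columns), `groups` (factor of true labels,
#'   High/Medium/Low).
#' @export
generate_cohort <- function(config, registry, seed = 1L) {
  with_seed(seed, {
    n <- config$n_patients
    groups <- factor(sample(c("High", "Medium", "Low"), n, replace = TRUE,
                            prob = config$group_proportions),
                     levels = c("High", "Medium", "Low"))
    tau <- config$concentration
    df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                     stringsAsFactors = FALSE)
    clipped_vars <- character()
    for (v in registry$variables) {
      a <- alpha_levels(v)
      sol <- .solve_offset(a, config$effect_size, tau)
      if (sol$clipped) clipped_vars <- c(clipped_vars, v$id)
      m0 <- (min(a) + max(a)) / 2
      targets <- c(High = m0 + sol$s, Medium = m0, Low = m0 - sol$s)
      idx <- integer(n)
      for (g in levels(groups)) {
        sel <- which(groups == g)
        if (!length(sel)) next
        pr <- .level_probs(a, targets[[g]], tau)
        idx[sel] <- sample.int(length(a), length(sel), replace = TRUE,
                               prob = pr)
      }
      df[[v$id]] <- switch(v$kind,
        ordinal = , categorical = v$levels[idx],
        binary = c(1, 0)[idx],
        continuous = {
          lo <- v$breaks[idx]; hi <- v$breaks[idx + 1L]
          stats::runif(n, lo, hi)
        })
    }
    if (length(clipped_vars))
      warning("effect_size ", config$effect_size,
              " infeasible for variable(s) ",
              paste(clipped_vars, collapse = ", "),
              "; separation clipped to the attainable maximum")

    df$age <- sample(18:85, n, replace = TRUE)
    df$diagnosis <- if ("Diag" %in% names(df)) df$Diag
                    else sample(paste0("D", 1:5), n, replace = TRUE)
    df$entry_date <- sample.int(config$listing_window, n, replace = TRUE) - 1L
    for (nm in names(config$demographics)) {
      prev <- config$demographics[[nm]]
      p <- if (length(prev) == 3L) prev[as.integer(groups)] else rep(prev, n)
      df[[nm]] <- as.integer(stats::runif(n) < p)
    }
    if (config$missing_rate > 0) {
      ids <- registry_ids(registry)
      for (id in ids) {
        miss <- stats::runif(n) < config$missing_rate
        df[[id]][miss] <- NA
      }
    }
    list(cohort = cohort_table(df, registry), groups = groups)
  })
}
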