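# Algorithmic-fairness audit: demographic parity of priority-group
# assignment across protected binary attributes.

#' Demographic parity test for one protected attribute
#'
#' Builds the priority-group x attribute contingency table and tests
#' independence: Pearson chi-square when every expected cell count is at
#' least 5, otherwise a Monte-Carlo exact test (conditional on the margins).
#' A constant attribute trivially satisfies parity; the result is flagged and
#' `p = 1`. Per-group attribute rates are reported for interpretation.
#'
#' @param labeling A `"priority_labeling"` (any method).
#' @param attribute Binary (or categorical) attribute vector, one value per
#'   labeled patient, in the same order (or named by patient id).
#' @param attribute_name Display name for the report.
#' @param b Monte-Carlo replicates for the exact fallback (default 2000).
#' @return List of class `"parity_result"`: `table`, `statistic`, `p_value`,
#'   `test` (`"chi-square"`, `"exact"` or `"degenerate"`), `rates` (attribute
#'   rate per priority group), `flagged`.
#' @export
demographic_parity_test <- function(labeling, attribute,
                                    attribute_name = "attribute", b = 2000) {
  labels <- labeling$labels
  if (!is.null(names(attribute)) && !is.null(names(labels)))
    attribute <- attribute[names(labels)]
  if (length(attribute) != length(labels))
    stop("attribute must be defined for every labeled patient", call. = FALSE)
  if (anyNA(attribute))
    stop("attribute has missing values", call. = FALSE)

  tab <- table(priority = droplevels(labels), attribute = attribute)
  rates <- prop.table(tab, margin = 1)

  if (ncol(tab) < 2L || nrow(tab) < 2L) {
    return(structure(list(table = tab, statistic = 0, p_value = 1,
                          test = "degenerate", rates = rates,
                          attribute = attribute_name, flagged = TRUE),
                     class = "parity_result"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    fit <- stats::chisq.test(tab, correct = FALSE)
    test <- "chi-square"
  } else {
    fit <- stats::chisq.test(tab, correct = FALSE,
                             simulate.p.value = TRUE, B = b)
    test <- "exact"
  }
  structure(list(table = tab, statistic = unname(fit$statistic),
                 p_value = fit$p.value, test = test, rates = rates,
                 attribute = attribute_name, flagged = FALSE),
            class = "parity_result")
}

#' @export
print.parity_result <- function(x, ...) {
  cat(sprintf("Demographic parity, %s: %s statistic = %.3f, p = %.4g%s\n",
              x$attribute, x$test, x$statistic, x$p_value,
              if (x$flagged) " [degenerate: parity trivially holds]" else ""))
  print(round(x$rates, 3))
  invisible(x)
}

#' Audit several protected attributes jointly
#'
#' Runs [demographic_parity_test()] for each attribute column and adjusts the
#' p-values for multiplicity with Holm's method.
#'
#' @param labeling A `"priority_labeling"`.
#' @param cohort Cohort data frame holding the attribute columns.
#' @param attributes Character vector of column names (default: all columns
#'   prefixed `dem_`).
#' @return Data frame (`attribute`, `test`, `statistic`, `p_value`,
#'   `p_adjusted`) with the individual `"parity_result"` objects attached as
#'   attribute `"results"`.
#' @export
fairness_audit <- function(labeling, cohort,
                           attributes = grep("^dem_", names(cohort),
                                             value = TRUE)) {
  if (!length(attributes)) stop("no attributes to audit", call. = FALSE)
  results <- lapply(attributes, function(a) {
    vals <- stats::setNames(cohort[[a]], cohort$patient_id)
    demographic_parity_test(labeling, vals, attribute_name = a)
  })
  out <- data.frame(attribute = attributes,
                    test = vapply(results, `[[`, "", "test"),
                    statistic = vapply(results, `[[`, 0, "statistic"),
                    p_value = vapply(results, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  attr(out, "results") <- results
  out
}
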