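#' Composite priority score
#'
#' The priority score of patient `p` is the weighted sum of their normalized
#' variable values, `s_p = sum_i w_i * alpha_ip` (vector form `s = w'alpha`).
#' With weights summing to 1 and normalized values in `[0, 1]`, scores lie in
#' `[0, 1]`; higher means greater surgical need.
#'
#' @param weights A `weight_vector` (names must match `alpha` rows when both
#'   are named).
#' @param alpha An `alpha_matrix` (variables x patients) or numeric matrix.
#' @return Named numeric vector of scores, one per patient, cohort order.
#' @export
priority_score <- function(weights, alpha) {
  w <- as.numeric(weights)
  a <- unclass(alpha)
  if (length(w) != nrow(a))
    stop("dimension mismatch: ", length(w), " weights vs ", nrow(a),
         " alpha rows", call. = FALSE)
  if (!is.null(names(weights)) && !is.null(rownames(a))) {
    if (!setequal(names(weights), rownames(a)))
      stop("weight names do not match alpha row names", call. = FALSE)
    w <- as.numeric(weights)[match(rownames(a), names(weights))]
  }
  s <- drop(crossprod(w, a))
  stats::setNames(as.numeric(s), colnames(a))
}

#' Per-variable contribution of a patient's score
#'
#' The linear score decomposes exactly: each variable contributes
#' `w_i * alpha_ip`, and the contributions sum to `s_p`. The report is sorted
#' by decreasing contribution for traceability at the bedside.
#'
#' @param weights A `weight_vector`.
#' @param alpha An `alpha_matrix`.
#' @param patient_id Patient column to decompose.
#' @return Data frame (`variable_id`, `weight`, `alpha`, `contribution`),
#'   sorted descending, with attribute `score` = `s_p`.
#' @export
contribution_report <- function(weights, alpha, patient_id) {
  a <- unclass(alpha)
  col <- if (is.character(patient_id)) match(patient_id, colnames(a))
         else as.integer(patient_id)
  if (is.na(col) || col < 1L || col > ncol(a))
    stop("unknown patient: ", patient_id, call. = FALSE)
  w <- as.numeric(weights)
  contrib <- w * a[, col]
  out <- data.frame(variable_id = rownames(a), weight = w,
                    alpha = a[, col], contribution = contrib,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$contribution), ]
  rownames(out) <- NULL
  attr(out, "score") <- sum(contrib)
  out
}

#' Assign High/Medium/Low priority labels to scores
#'
#' Two labeling rules:
#' * `"tertile"` — the empirical 1/3 and 2/3 quantiles (linear interpolation)
#'   split scores into bottom/middle/top tertiles mapped to Low/Medium/High.
#'   Scores tied with a boundary go to the higher-priority group (favoring
#'   earlier care). If all scores are identical every patient is Medium and a
#'   warning is emitted.
#' * `"fixed"` — operational thresholds: `s > high_threshold` is High
#'   (scheduling within 30 days), `s < low_threshold` is Low (deferrable),
#'   otherwise Medium. Both comparisons are strict, so boundary scores are
#'   Medium.
#'
#' @param scores Named numeric score vector ([priority_score()]).
#' @param method `"tertile"` or `"fixed"`.
#' @param high_threshold Fixed-mode High cutoff (default 0.29).
#' @param low_threshold Fixed-mode Low cutoff (default 0.18).
#' @return List of class `"priority_labeling"`: `labels` (factor
#'   High/Medium/Low named by patient), `method`, `thresholds`.
#' @export
assign_priority_labels <- function(scores, method = c("tertile", "fixed"),
                                   high_threshold = 0.29, low_threshold = 0.18) {
  method <- match.arg(method)
  if (!length(scores)) stop("empty score vector", call. = FALSE)
  s <- as.numeric(scores)
  if (method == "fixed") {
    if (high_threshold <= low_threshold)
      stop("high_threshold must exceed low_threshold", call. = FALSE)
    lab <- ifelse(s > high_threshold, "High",
                  ifelse(s < low_threshold, "Low", "Medium"))
    thresholds <- c(low = low_threshold, high = high_threshold)
  } else {
    q <- stats::quantile(s, c(1 / 3, 2 / 3), type = 7, names = FALSE)
    if (q[1] == q[2] && all(s == s[1])) {
      warning("all scores identical: every patient labeled Medium")
      lab <- rep("Medium", length(s))
    } else {
      lab <- ifelse(s >= q[2], "High", ifelse(s >= q[1], "Medium", "Low"))
    }
    thresholds <- c(low = q[1], high = q[2])
  }
  structure(list(labels = stats::setNames(
                   factor(lab, levels = c("High", "Medium", "Low")),
                   names(scores)),
                 method = method, thresholds = thresholds),
            class = "priority_labeling")
}

#' @export
print.priority_labeling <- function(x, ...) {
  cat(sprintf("Priority labeling (%s): ", x$method))
  print(table(x$labels))
  invisible(x)
}

#' Write scores and labels to CSV
#' @param scores Named score vector.
#' @param labeling Optional [assign_priority_labels()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, labeling = NULL) {
  df <- data.frame(patient_id = names(scores), score = as.numeric(scores),
                   stringsAsFactors = FALSE)
  if (!is.null(labeling)) df$label <- as.character(labeling$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read scores (and labels) from CSV
#' @param path CSV with `patient_id`, `score`, optional `label`.
#' @return Named numeric vector; labels, if present, as attribute `"labels"`.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  s <- stats::setNames(as.numeric(df$score), df$patient_id)
  if (!is.null(df$label))
    attr(s, "labels") <- stats::setNames(
      factor(df$label, levels = c("High", "Medium", "Low")), df$patient_id)
  s
}
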