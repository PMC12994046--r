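#' Normalize one raw value to its expert-impact share
#'
#' Maps a raw patient value into `[0, 1]` as the share of the variable's total
#' expert impact attributable to the observed level:
#' * ordinal/categorical — `score(level) / sum(all level scores)`;
#' * continuous — locate the interval containing the value (half-open
#'   `[lo, hi)`, last interval closed) and take that interval's score share;
#' * binary — `score_present / (score_present + score_absent)` when the
#'   indicator is set, else the absent share.
#'
#' Normalized values over a variable's levels therefore sum to exactly 1: they
#' are shares of total clinical impact, not data-driven rescalings.
#'
#' @param spec A [variable_spec()].
#' @param raw A raw value valid for `spec` (vectorized).
#' @return Numeric in `[0, 1]`, same length as `raw`.
#' @examples
#' v <- variable_spec("Sever", "ordinal", levels = c("low", "medium", "high"),
#'                    impact_scores = c(2, 5, 9))
#' normalize_value(v, "high")  # 9/16 = 0.5625
#' @export
normalize_value <- function(spec, raw) {
  switch(spec$kind,
    ordinal = , categorical = {
      idx <- match(as.character(raw), spec$levels)
      if (anyNA(idx))
        stop("variable '", spec$id, "': unknown level '",
             raw[which(is.na(idx))[1]], "'", call. = FALSE)
      spec$impact_scores[idx] / sum(spec$impact_scores)
    },
    continuous = {
      x <- as.numeric(raw)
      idx <- findInterval(x, spec$breaks, rightmost.closed = TRUE)
      bad <- is.na(idx) | idx < 1L | idx > length(spec$impact_scores)
      if (any(bad))
        stop("variable '", spec$id, "': value ", x[which(bad)[1]],
             " outside declared domain [", spec$breaks[1], ", ",
             spec$breaks[length(spec$breaks)], "]", call. = FALSE)
      spec$impact_scores[idx] / sum(spec$impact_scores)
    },
    binary = {
      x <- as.numeric(raw)
      if (anyNA(x) || !all(x %in% c(0, 1)))
        stop("variable '", spec$id, "': binary values must be 0/1", call. = FALSE)
      ifelse(x == 1, spec$binary_scores[1], spec$binary_scores[2]) /
        sum(spec$binary_scores)
    })
}

#' Attainable normalized values of a variable
#' @param spec A [variable_spec()].
#' @return Numeric vector of the per-level impact shares (they sum to 1).
#' @export
alpha_levels <- function(spec) {
  s <- if (spec$kind == "binary") spec$binary_scores else spec$impact_scores
  s / sum(s)
}

#' Build the normalized decision matrix
#'
#' Applies [normalize_value()] element-wise over a complete (preprocessed)
#' cohort, producing the matrix `alpha` with one row per registry variable and
#' one column per patient, every entry in `[0, 1]`.
#'
#' @param cohort A complete [cohort_table()] (no missing values; run
#'   [preprocess_cohort()] first).
#' @param registry A [variable_registry()].
#' @return Matrix of class `"alpha_matrix"` (variables x patients), dimnames
#'   set to variable and patient ids.
#' @export
build_alpha_matrix <- function(cohort, registry) {
  ids <- registry_ids(registry)
  vals <- as.data.frame(cohort)[ids]
  if (anyNA(vals))
    stop("cohort contains missing values; run preprocess_cohort() first",
         call. = FALSE)
  rows <- lapply(registry$variables, function(v) {
    tryCatch(normalize_value(v, cohort[[v$id]]),
             error = function(e) stop("while normalizing variable '", v$id,
                                      "': ", conditionMessage(e), call. = FALSE))
  })
  alpha <- do.call(rbind, rows)
  dimnames(alpha) <- list(ids, cohort$patient_id)
  class(alpha) <- c("alpha_matrix", class(alpha))
  alpha
}

#' Write / read the normalized decision matrix
#'
#' CSV layout: `variable_id` column then one column per patient, values at
#' full precision (round-trips losslessly well beyond 12 decimal places).
#'
#' @param alpha An `alpha_matrix`.
#' @param path File path.
#' @return `path` (write) or an `alpha_matrix` (read).
#' @export
write_alpha <- function(alpha, path) {
  df <- data.frame(variable_id = rownames(alpha),
                   format(unclass(alpha), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_alpha
#' @export
read_alpha <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$variable_id
  class(m) <- c("alpha_matrix", class(m))
  m
}
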