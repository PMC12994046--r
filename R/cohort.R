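#' Construct a patient cohort table
#'
#' A cohort table is a data frame with one row per patient: a `patient_id`
#' column, one raw-value column per registry variable (possibly `NA`), and
#' optional `age`, `diagnosis`, `entry_date` columns plus demographic columns
#' prefixed `dem_` (used by the fairness audit). `age` and `diagnosis` define
#' the clinically homogeneous subgroups used for imputation; `entry_date`
#' (integer day or ISO date) is the time-on-list origin used by the scheduler
#' simulation.
#'
#' @param df Data frame of raw patient records.
#' @param registry A [variable_registry()]; every registry variable must have
#'   a column, and non-missing values must be valid for their spec.
#' @return `df` with class `"cohort_table"` prepended.
#' @export
cohort_table <- function(df, registry) {
  if (!is.data.frame(df)) stop("cohort must be a data frame", call. = FALSE)
  if (is.null(df$patient_id)) stop("cohort needs a `patient_id` column", call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicated patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "),
         call. = FALSE)
  missing_cols <- setdiff(registry_ids(registry), names(df))
  if (length(missing_cols))
    stop("cohort lacks columns for variables: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  out <- df
  class(out) <- c("cohort_table", class(df))
  validate_cohort(out, registry)
  out
}

#' Validate cohort raw values against a registry
#'
#' Checks every non-missing raw value: a declared level token
#' (ordinal/categorical), a number inside the declared interval domain
#' (continuous), or a 0/1 indicator (binary). Fails with the (variable,
#' patient) coordinates of the first offending cells.
#'
#' @param cohort A cohort data frame.
#' @param registry A [variable_registry()].
#' @return `TRUE`, invisibly.
#' @export
validate_cohort <- function(cohort, registry) {
  for (v in registry$variables) {
    x <- cohort[[v$id]]
    ok <- switch(v$kind,
      ordinal = , categorical = is.na(x) | as.character(x) %in% v$levels,
      continuous = {
        xn <- suppressWarnings(as.numeric(x))
        is.na(x) | (!is.na(xn) & xn >= v$breaks[1] & xn <= v$breaks[length(v$breaks)])
      },
      binary = {
        xn <- suppressWarnings(as.numeric(x))
        is.na(x) | (!is.na(xn) & xn %in% c(0, 1))
      })
    if (!all(ok)) {
      bad <- which(!ok)
      stop("invalid value(s) for variable '", v$id, "', patient(s) ",
           paste(utils::head(cohort$patient_id[bad], 5L), collapse = ", "),
           " (e.g. '", x[bad[1]], "')", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a cohort CSV
#'
#' Expected layout: `patient_id`, one column per variable id, optional `age`,
#' `diagnosis`, `entry_date` and `dem_*` columns. Missing values are empty
#' fields or `NA`.
#'
#' @param path CSV file path.
#' @param registry A [variable_registry()] used for validation.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, registry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  cohort_table(df, registry)
}

#' Write a cohort CSV
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

.age_band <- function(age, width = 10) {
  ifelse(is.na(age), NA_character_,
         sprintf("%d-%d", (age %/% width) * width, (age %/% width) * width + width - 1))
}

.subgroup_key <- function(cohort, age_band_width) {
  key <- rep("", nrow(cohort))
  if (!is.null(cohort$age))
    key <- paste0(key, .age_band(as.numeric(cohort$age), age_band_width))
  if (!is.null(cohort$diagnosis))
    key <- paste0(key, "|", as.character(cohort$diagnosis))
  key
}

# Mode with ties broken by position in `ordered_values` (declared level order).
.mode_by_order <- function(x, ordered_values) {
  counts <- vapply(ordered_values, function(v) sum(x == v, na.rm = TRUE), 0L)
  if (all(counts == 0L)) return(NULL)
  ordered_values[which.max(counts)]
}

#' Preprocess a cohort: exclusion and subgroup imputation
#'
#' Applies the missing-data rules used before any scoring: patients missing
#' strictly more than `missing_threshold` of the registry variables are
#' excluded (and listed in the report with their missing fraction); remaining
#' missing values are imputed within clinically homogeneous subgroups defined
#' by decade age band and diagnosis — subgroup mean for continuous variables,
#' subgroup mode for ordinal/categorical/binary (ties broken by declared level
#' order) — falling back to the whole-cohort mean/mode when a subgroup has no
#' donor values. The result contains no missing values and the operation is
#' idempotent.
#'
#' @param cohort A [cohort_table()] (validated against `registry`).
#' @param registry A [variable_registry()].
#' @param missing_threshold Maximum tolerated missing fraction per patient
#'   (strict comparison; default 0.10).
#' @param age_band_width Width in years of imputation age bands (default 10).
#' @return A list with `cohort` (complete [cohort_table()]) and `exclusions`
#'   (data frame `patient_id`, `missing_fraction` of removed patients).
#' @export
preprocess_cohort <- function(cohort, registry, missing_threshold = 0.10,
                              age_band_width = 10) {
  ids <- registry_ids(registry)
  vals <- as.data.frame(cohort)[ids]
  n_var <- length(ids)

  all_missing <- vapply(vals, function(x) all(is.na(x)), TRUE)
  if (any(all_missing))
    stop("variable(s) missing for all patients: ",
         paste(ids[all_missing], collapse = ", "), call. = FALSE)

  frac <- rowMeans(is.na(vals))
  drop <- frac > missing_threshold   # strict: exactly at threshold is retained
  exclusions <- data.frame(patient_id = cohort$patient_id[drop],
                           missing_fraction = frac[drop],
                           stringsAsFactors = FALSE)
  kept <- as.data.frame(cohort)[!drop, , drop = FALSE]
  rownames(kept) <- NULL

  if (nrow(kept) == 0L)
    stop("all patients exceed the missing-data threshold", call. = FALSE)

  key <- .subgroup_key(kept, age_band_width)
  for (v in registry$variables) {
    x <- kept[[v$id]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (v$kind == "continuous") {
      x <- as.numeric(x)
      global <- mean(x, na.rm = TRUE)
      for (i in which(miss)) {
        donors <- x[!is.na(x) & key == key[i]]
        x[i] <- if (length(donors)) mean(donors) else global
      }
    } else {
      ordered_values <- if (v$kind == "binary") c("1", "0") else v$levels
      x <- as.character(x)
      global <- .mode_by_order(x[!is.na(x)], ordered_values)
      for (i in which(miss)) {
        m <- .mode_by_order(x[!is.na(x) & key == key[i]], ordered_values)
        x[i] <- if (!is.null(m)) m else global
      }
      if (v$kind == "binary") x <- as.numeric(x)
    }
    kept[[v$id]] <- x
  }

  out <- cohort_table(kept, registry)
  list(cohort = out, exclusions = exclusions)
}
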