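#' Define a decision variable
#'
#' A decision variable is one biopsychosocial criterion used for surgical
#' prioritization: an ordinal scale (e.g. severity low..severe), a categorical
#' code (e.g. affected anatomical area), a continuous quantity discretized into
#' clinically meaningful intervals (e.g. months on the waiting list), or a
#' binary indicator (e.g. presence of other pathologies). Each level or
#' interval carries an expert-assigned clinical impact score on a 1-10 scale;
#' normalized values are shares of the variable's total impact.
#'
#' @param id Short unique token identifying the variable (e.g. `"Sever"`).
#' @param kind One of `"ordinal"`, `"categorical"`, `"continuous"`, `"binary"`.
#' @param label Free-text description; defaults to `id`.
#' @param levels Ordered character vector of level tokens (ordinal/categorical).
#' @param breaks Strictly increasing numeric vector of interval breakpoints
#'   (continuous): intervals are `[b1, b2), [b2, b3), ...`, the last closed.
#'   Representing intervals by shared breakpoints makes them non-overlapping,
#'   contiguous and domain-covering by construction.
#' @param impact_scores Positive numeric vector, one expert impact score per
#'   level (ordinal/categorical) or per interval (continuous).
#' @param binary_scores Length-2 positive numeric `c(score_present,
#'   score_absent)` for binary variables.
#' @return An object of class `"variable_spec"`.
#' @examples
#' variable_spec("Sever", "ordinal",
#'   levels = c("low", "moderate", "high", "severe"),
#'   impact_scores = c(1, 3, 6, 9))
#' @export
variable_spec <- function(id, kind, label = id, levels = NULL, breaks = NULL,
                          impact_scores = NULL, binary_scores = NULL) {
  kind <- match.arg(kind, c("ordinal", "categorical", "continuous", "binary"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("variable id must be a non-empty string", call. = FALSE)
  spec <- structure(
    list(id = id, label = label, kind = kind, levels = levels,
         breaks = breaks, impact_scores = impact_scores,
         binary_scores = binary_scores),
    class = "variable_spec")
  validate_variable_spec(spec)
  spec
}

validate_variable_spec <- function(spec) {
  id <- spec$id
  fail <- function(msg) stop("variable '", id, "': ", msg, call. = FALSE)
  populated <- c(levels = !is.null(spec$levels),
                 breaks = !is.null(spec$breaks),
                 binary = !is.null(spec$binary_scores))
  if (spec$kind %in% c("ordinal", "categorical")) {
    if (!populated[["levels"]] || any(populated[c("breaks", "binary")]))
      fail("ordinal/categorical variables declare `levels` only")
    if (anyDuplicated(spec$levels)) fail("duplicated level tokens")
    if (is.null(spec$impact_scores) ||
        length(spec$impact_scores) != length(spec$levels))
      fail(sprintf("needs %d impact scores, got %d",
                   length(spec$levels), length(spec$impact_scores)))
    if (any(spec$impact_scores <= 0)) fail("impact scores must be > 0")
  } else if (spec$kind == "continuous") {
    if (!populated[["breaks"]] || any(populated[c("levels", "binary")]))
      fail("continuous variables declare `breaks` only")
    if (length(spec$breaks) < 2L || is.unsorted(spec$breaks, strictly = TRUE))
      fail("breaks must be strictly increasing (>= 2 values)")
    k <- length(spec$breaks) - 1L
    if (is.null(spec$impact_scores) || length(spec$impact_scores) != k)
      fail(sprintf("needs %d interval scores, got %d",
                   k, length(spec$impact_scores)))
    if (any(spec$impact_scores <= 0)) fail("impact scores must be > 0")
  } else { # binary
    if (!populated[["binary"]] || any(populated[c("levels", "breaks")]))
      fail("binary variables declare `binary_scores` only")
    if (length(spec$binary_scores) != 2L || any(spec$binary_scores <= 0))
      fail("binary_scores must be two positive numbers (present, absent)")
  }
  invisible(spec)
}

#' Number of levels/intervals of a variable
#' @param spec A `variable_spec`.
#' @return Integer count (2 for binary).
#' @export
n_levels <- function(spec) {
  switch(spec$kind,
         ordinal = , categorical = length(spec$levels),
         continuous = length(spec$breaks) - 1L,
         binary = 2L)
}

#' Build a variable registry
#'
#' The registry is the ordered list of decision variables; its order fixes the
#' row order of every downstream matrix (normalized decision matrix, weight
#' vector, rating matrix).
#'
#' @param variables List of [variable_spec()] objects.
#' @return Object of class `"variable_registry"`.
#' @export
variable_registry <- function(variables) {
  if (!length(variables)) stop("registry needs at least one variable", call. = FALSE)
  ids <- vapply(variables, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicated variable ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (v in variables) validate_variable_spec(v)
  names(variables) <- ids
  structure(list(variables = variables), class = "variable_registry")
}

#' @export
print.variable_registry <- function(x, ...) {
  cat("Variable registry:", length(x$variables), "decision variables\n")
  for (v in x$variables)
    cat(sprintf("  %-6s %-11s %2d levels  %s\n",
                v$id, v$kind, n_levels(v), v$label))
  invisible(x)
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s (%s): %s\n", x$id, x$kind, x$label))
  invisible(x)
}

#' Variable ids of a registry, in canonical order
#' @param registry A [variable_registry()].
#' @return Character vector of variable ids.
#' @export
registry_ids <- function(registry) names(registry$variables)

#' Read a variable registry from YAML
#'
#' The file holds a top-level `variables:` list; each entry declares `id`,
#' `kind`, an optional `label`, and the score block matching its kind
#' (`levels` + `scores`, `breaks` + `scores`, or `binary: [present, absent]`).
#'
#' @param path Path to the YAML registry file.
#' @return A [variable_registry()].
#' @export
load_registry <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse registry file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  entries <- if (!is.null(doc$variables)) doc$variables else doc
  if (!is.list(entries) || !length(entries))
    stop("registry file '", path, "' declares no variables", call. = FALSE)
  specs <- lapply(entries, function(e) {
    if (is.null(e$id) || is.null(e$kind))
      stop("registry entry missing `id` or `kind`: ",
           paste(deparse(e), collapse = " "), call. = FALSE)
    variable_spec(id = e$id, kind = e$kind,
                  label = if (is.null(e$label)) e$id else e$label,
                  levels = if (!is.null(e$levels)) as.character(e$levels),
                  breaks = if (!is.null(e$breaks)) as.numeric(e$breaks),
                  impact_scores = if (!is.null(e$scores)) as.numeric(e$scores),
                  binary_scores = if (!is.null(e$binary)) as.numeric(e$binary))
  })
  variable_registry(specs)
}

#' Write a variable registry to YAML
#' @param registry A [variable_registry()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  entries <- lapply(registry$variables, function(v) {
    e <- list(id = v$id, label = v$label, kind = v$kind)
    if (v$kind %in% c("ordinal", "categorical")) {
      e$levels <- as.list(v$levels); e$scores <- as.list(v$impact_scores)
    } else if (v$kind == "continuous") {
      e$breaks <- as.list(v$breaks); e$scores <- as.list(v$impact_scores)
    } else e$binary <- as.list(v$binary_scores)
    e
  })
  yaml::write_yaml(list(variables = unname(entries)), path)
  invisible(path)
}

#' Default 20-variable ENT registry
#'
#' The shipped registry covers the 20 biopsychosocial criteria of the ENT
#' waiting-list framework (clinical severity and urgency, sleep disorder,
#' waiting times, expected surgical benefit, functional and psychosocial
#' limitations, pain, resource demand), in the canonical order. Which
#' variables are ordinal, categorical, continuous or binary is not fully
#' pinned down by their published definitions; this registry encodes the most
#' natural reading and every choice — kinds, levels, interval breakpoints and
#' the per-level impact scores — is user-overridable via [load_registry()].
#'
#' @return A [variable_registry()] of 20 variables.
#' @export
default_registry <- function() {
  load_registry(system.file("extdata", "default_registry.yaml",
                            package = "biopriority", mustWork = TRUE))
}

#' Published expert weight vector for the default registry
#'
#' The consensus weights of the seven-physician panel for the 20 default
#' variables (Sever 0.081 down to Ccrit 0.023). As printed they sum to 1.001
#' from rounding to three decimals; set `renormalize = TRUE` to rescale to an
#' exact unit sum.
#'
#' @param renormalize Rescale to sum exactly 1 (default `FALSE`, printed values).
#' @return A `weight_vector` (named numeric, registry order).
#' @export
published_weights <- function(renormalize = FALSE) {
  tab <- utils::read.csv(system.file("extdata", "table1_weights.csv",
                                     package = "biopriority", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  w <- stats::setNames(tab$weight, tab$variable_id)
  if (renormalize) w <- w / sum(w)
  structure(w, total_mass = NA_real_, class = "weight_vector")
}
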