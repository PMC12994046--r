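#' Construct an expert rating matrix
#'
#' One row per decision variable, one column per rater; entries are direct
#' importance ratings on the 0-10 scale elicited independently from each
#' expert.
#'
#' @param ratings Numeric matrix (variables x raters), entries in `[0, 10]`,
#'   at least one strictly positive. Row names should be variable ids.
#' @param registry Optional [variable_registry()]; if given, rows are checked
#'   (and reordered) against the registry order.
#' @return Matrix of class `"rating_matrix"`.
#' @export
rating_matrix <- function(ratings, registry = NULL) {
  ratings <- as.matrix(ratings)
  storage.mode(ratings) <- "double"
  if (anyNA(ratings) || any(ratings < 0) || any(ratings > 10))
    stop("ratings must lie in [0, 10] with no missing entries", call. = FALSE)
  if (!any(ratings > 0))
    stop("degenerate ratings: all entries are zero", call. = FALSE)
  if (!is.null(registry)) {
    ids <- registry_ids(registry)
    if (nrow(ratings) != length(ids))
      stop("rating matrix has ", nrow(ratings), " rows but registry has ",
           length(ids), " variables", call. = FALSE)
    if (!is.null(rownames(ratings))) {
      if (!setequal(rownames(ratings), ids))
        stop("rating matrix rows do not match registry variable ids", call. = FALSE)
      ratings <- ratings[ids, , drop = FALSE]
    } else rownames(ratings) <- ids
  }
  class(ratings) <- c("rating_matrix", class(ratings))
  ratings
}

#' Read expert ratings from long CSV
#'
#' Expected columns: `variable_id`, `rater_id`, `score`.
#'
#' @param path CSV path.
#' @param registry Optional [variable_registry()] for row order/validation.
#' @return A [rating_matrix()].
#' @export
read_ratings <- function(path, registry = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable_id", "rater_id", "score")
  if (!all(need %in% names(df)))
    stop("ratings file needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  vars <- if (is.null(registry)) unique(df$variable_id) else registry_ids(registry)
  raters <- unique(df$rater_id)
  m <- matrix(NA_real_, length(vars), length(raters),
              dimnames = list(vars, raters))
  m[cbind(match(df$variable_id, vars), match(df$rater_id, raters))] <- df$score
  rating_matrix(m, registry)
}

#' Aggregate expert ratings into normalized weights
#'
#' Each variable's weight is its total rating mass divided by the grand total
#' over all variables and raters: `w_i = sum_m mu_im / W`,
#' `W = sum_i sum_m mu_im`. This linear normalization preserves the ordinal
#' meaning of the direct ratings and scales the weights to sum to 1.
#'
#' @param ratings A [rating_matrix()] (or coercible matrix).
#' @return A `weight_vector`: named nonnegative numeric summing to 1, with the
#'   grand rating total attached as attribute `total_mass`.
#' @examples
#' aggregate_weights(rbind(a = c(8, 6), b = c(2, 4)))  # w = (0.7, 0.3)
#' @export
aggregate_weights <- function(ratings) {
  if (!inherits(ratings, "rating_matrix")) ratings <- rating_matrix(ratings)
  W <- sum(ratings)
  w <- rowSums(ratings) / W
  structure(w, total_mass = W, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("Criterion weights (sum =", format(sum(x), digits = 10), ")\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Write weights to CSV (`variable_id`, `weight`, 6 decimal places)
#' @param weights A `weight_vector`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  df <- data.frame(variable_id = names(weights),
                   weight = sprintf("%.6f", as.numeric(weights)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a weight vector from CSV (`variable_id`, `weight`)
#' @param path CSV path.
#' @return A `weight_vector`.
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(stats::setNames(as.numeric(df$weight), df$variable_id),
            total_mass = NA_real_, class = "weight_vector")
}

.bin_scores <- function(x, n_bins) {
  # equal-width bins over the 0-10 rating scale
  breaks <- seq(0, 10, length.out = n_bins + 1)
  cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
}

.kappa2 <- function(b1, b2, n_bins) {
  po <- mean(b1 == b2)
  m1 <- tabulate(b1, n_bins) / length(b1)
  m2 <- tabulate(b2, n_bins) / length(b2)
  pe <- sum(m1 * m2)
  if (pe >= 1) return(list(kappa = 1, degenerate = TRUE))
  list(kappa = (po - pe) / (1 - pe), degenerate = FALSE)
}

#' Pairwise Cohen's kappa between raters
#'
#' Discretizes each rater's 0-10 scores into `n_bins` equal-width bins and
#' computes Cohen's kappa for every rater pair over the variables as items,
#' plus the mean over all pairs. A pair in which both raters are constant in
#' the same bin has chance agreement 1; kappa is defined as 1 by convention
#' and the pair is flagged.
#'
#' @param ratings A [rating_matrix()].
#' @param n_bins Number of equal-width bins (default 5).
#' @return List of class `"kappa_result"`: `kappa` (raters x raters matrix,
#'   `NA` diagonal), `mean_kappa`, `degenerate_pairs` (character vector).
#' @export
pairwise_kappa <- function(ratings, n_bins = 5) {
  if (!inherits(ratings, "rating_matrix")) ratings <- rating_matrix(ratings)
  if (ncol(ratings) < 2L) stop("need at least two raters", call. = FALSE)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  binned <- apply(ratings, 2, .bin_scores, n_bins = n_bins)
  m <- ncol(ratings)
  raters <- colnames(ratings)
  if (is.null(raters)) raters <- paste0("R", seq_len(m))
  K <- matrix(NA_real_, m, m, dimnames = list(raters, raters))
  degenerate <- character()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    res <- .kappa2(binned[, i], binned[, j], n_bins)
    K[i, j] <- K[j, i] <- res$kappa
    if (res$degenerate)
      degenerate <- c(degenerate, paste(raters[i], raters[j], sep = ":"))
  }
  structure(list(kappa = K, mean_kappa = mean(K[upper.tri(K)]),
                 n_bins = n_bins, degenerate_pairs = degenerate),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Inter-rater agreement: mean Cohen's kappa = %.3f (%d bins)\n",
              x$mean_kappa, x$n_bins))
  if (length(x$degenerate_pairs))
    cat("  flagged constant-bin pairs:",
        paste(x$degenerate_pairs, collapse = ", "), "\n")
  invisible(x)
}

#' Weight-stability sensitivity analysis
#'
#' Perturbs each criterion weight individually by +/- `perturbation` (the full
#' vector is then renormalized to sum 1, keeping the unit-sum contract; only
#' relative weights matter for ranking), recomputes scores, priority-group
#' labels and cluster assignments with the same seed and initialization as the
#' baseline, and records the fraction of patients whose priority group and
#' cluster assignment are unchanged.
#'
#' @param weights Baseline `weight_vector`.
#' @param alpha A normalized decision matrix ([build_alpha_matrix()]).
#' @param perturbation Relative perturbation (default 0.10); must be `< 1`.
#' @param k Number of clusters (default 3).
#' @param label_method `"tertile"` or `"fixed"` priority labeling of scores.
#' @param weighted Cluster on weight-scaled profiles (default `TRUE`; matches
#'   the pipeline default so that clusters respond to weight changes).
#' @param seed RNG seed shared by baseline and all perturbed runs.
#' @param ... Passed to [kmeans_cluster()] (e.g. `mode`, `n_restarts`).
#' @return List of class `"stability_report"`: `per_perturbation` data frame
#'   (`variable_id`, `direction`, `fraction_rank_stable`,
#'   `fraction_cluster_stable`), plus aggregate means over all
#'   `2 * n_vars` perturbations.
#' @export
weight_sensitivity <- function(weights, alpha, perturbation = 0.10, k = 3,
                               label_method = c("tertile", "fixed"),
                               weighted = TRUE, seed = 1L, ...) {
  if (perturbation >= 1) stop("perturbation must be < 1", call. = FALSE)
  if (perturbation < 0) stop("perturbation must be >= 0", call. = FALSE)
  label_method <- match.arg(label_method)

  run <- function(w) {
    s <- priority_score(w, alpha)
    lab <- assign_priority_labels(s, method = label_method)
    X <- t(unclass(alpha))
    if (weighted) X <- sweep(X, 2, as.numeric(w), `*`)
    cl <- kmeans_cluster(X, k = k, seed = seed, ...)
    list(labels = lab$labels, clusters = cl$assignments)
  }
  base <- run(weights)
  w0 <- as.numeric(weights)
  nv <- length(w0)
  ids <- names(weights)
  if (is.null(ids)) ids <- rownames(alpha)
  if (is.null(ids)) ids <- paste0("V", seq_len(nv))
  rows <- vector("list", 2L * nv)
  r <- 0L
  for (i in seq_len(nv)) for (dir in c(1, -1)) {
    w <- w0
    w[i] <- w[i] * (1 + dir * perturbation)
    w <- w / sum(w)
    pert <- run(structure(stats::setNames(w, ids),
                          class = "weight_vector"))
    # compare cluster partitions up to index permutation: a patient is stable
    # if it stays with the same co-membership pattern under the best matching
    stable_cl <- .partition_agreement(base$clusters, pert$clusters)
    r <- r + 1L
    rows[[r]] <- data.frame(
      variable_id = ids[i],
      direction = ifelse(dir > 0, "+", "-"),
      fraction_rank_stable = mean(base$labels == pert$labels),
      fraction_cluster_stable = stable_cl,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  structure(list(per_perturbation = per,
                 perturbation = perturbation,
                 fraction_rank_stable = mean(per$fraction_rank_stable),
                 fraction_cluster_stable = mean(per$fraction_cluster_stable)),
            class = "stability_report")
}

# Fraction of patients keeping their cluster under the label permutation that
# maximizes agreement (cluster indices are arbitrary).
.partition_agreement <- function(a, b) {
  ka <- sort(unique(a)); kb <- sort(unique(b))
  if (length(kb) > 8L) { # greedy fallback, not hit at K = 3
    tab <- table(a, b)
    return(sum(apply(tab, 1, max)) / length(a))
  }
  perms <- .permutations(kb)
  best <- 0
  for (p in perms) {
    relab <- p[match(b, kb)]
    best <- max(best, mean(a == relab))
  }
  best
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("Weight-stability analysis (+/-%.0f%%, %d perturbations)\n",
                     "  priority-group label stable: %.1f%%\n",
                     "  cluster assignment stable:   %.1f%%\n"),
              100 * x$perturbation, nrow(x$per_perturbation),
              100 * x$fraction_rank_stable, 100 * x$fraction_cluster_stable))
  invisible(x)
}
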