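# Patient stratification: Gower dissimilarity, k-means / k-medoids, K
# selection, cluster labeling by mean score, PCA projection and a permutation
# MANOVA separation test.

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG stream, so
#' seeded computations do not perturb surrounding randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Gower dissimilarity matrix for mixed-type records
#'
#' Entry `(p, q)` is the mean over variables of per-variable dissimilarities:
#' numeric (continuous) — absolute difference divided by the observed range;
#' ordinal — absolute difference of `(rank - 1)/(L - 1)` level positions;
#' categorical/binary — simple mismatch (0/1). A numeric variable with zero
#' observed range contributes 0 and is flagged in attribute
#' `"zero_range_variables"`. Entries lie in `[0, 1]`, the matrix is symmetric
#' with zero diagonal; the triangle inequality is not guaranteed (Gower is a
#' dissimilarity, not a metric).
#'
#' For cohort input, continuous variables are scaled by their declared domain
#' range (the interval breakpoints), not the observed sample range, so
#' dissimilarities are comparable across cohorts; for plain numeric input the
#' observed range is used unless `ranges` is given.
#'
#' @param x A [cohort_table()] (with `registry` given) or a numeric matrix
#'   with rows = patients (all columns treated as numeric).
#' @param registry [variable_registry()] describing `x`'s columns (required
#'   for a cohort).
#' @param ranges Optional numeric vector of per-column ranges for numeric
#'   matrix input (default: observed ranges).
#' @return N x N dissimilarity matrix (class `"gower_matrix"`).
#' @export
gower_matrix <- function(x, registry = NULL, ranges = NULL) {
  if (is.matrix(x) && is.numeric(x)) {
    cols <- lapply(seq_len(ncol(x)), function(j) list(
      kind = "numeric", values = x[, j],
      range = if (!is.null(ranges)) ranges[j]))
    ids <- colnames(x)
    n <- nrow(x)
    labels <- rownames(x)
  } else {
    if (is.null(registry))
      stop("a registry is required for cohort input", call. = FALSE)
    df <- as.data.frame(x)
    cols <- lapply(registry$variables, function(v) {
      raw <- df[[v$id]]
      switch(v$kind,
        continuous = list(kind = "numeric", values = as.numeric(raw),
                          range = diff(range(v$breaks))),
        ordinal = list(kind = "numeric",
                       values = {
                         r <- match(as.character(raw), v$levels)
                         if (length(v$levels) > 1L)
                           (r - 1) / (length(v$levels) - 1) else r * 0
                       },
                       range = if (length(v$levels) > 1L) 1 else 0),
        categorical = list(kind = "factor", values = as.character(raw)),
        binary = list(kind = "factor", values = as.character(as.numeric(raw))))
    })
    ids <- registry_ids(registry)
    n <- nrow(df)
    labels <- df$patient_id
  }
  D <- matrix(0, n, n)
  zero_range <- character()
  for (j in seq_along(cols)) {
    cj <- cols[[j]]
    if (cj$kind == "numeric") {
      rng <- if (!is.null(cj$range)) cj$range else diff(range(cj$values))
      if (rng == 0) {
        zero_range <- c(zero_range, if (!is.null(ids)) ids[j] else as.character(j))
        next  # contributes 0 but still counts in the average
      }
      D <- D + abs(outer(cj$values, cj$values, `-`)) / rng
    } else {
      D <- D + outer(cj$values, cj$values, `!=`) * 1
    }
  }
  D <- D / length(cols)
  dimnames(D) <- list(labels, labels)
  structure(D, zero_range_variables = zero_range,
            class = c("gower_matrix", "matrix", "array"))
}

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

.assign_nearest <- function(X, centers) {
  # squared distances via ||x||^2 - 2 x.c + ||c||^2
  cross <- X %*% t(centers)
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) - 2 * cross +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  d2[d2 < 0] <- 0
  list(cluster = max.col(-d2, ties.method = "first"),
       d2 = d2)
}

.lloyd <- function(X, centers, max_iter, tol) {
  trace <- numeric()
  assign <- NULL
  for (it in seq_len(max_iter)) {
    a <- .assign_nearest(X, centers)
    assign <- a$cluster
    # empty cluster: re-seed its centroid at the point farthest from its center
    for (j in seq_len(nrow(centers))) {
      if (!any(assign == j)) {
        far <- which.max(a$d2[cbind(seq_len(nrow(X)), assign)])
        centers[j, ] <- X[far, ]
        assign[far] <- j
      }
    }
    obj <- sum(vapply(seq_len(nrow(X)), function(i)
      sum((X[i, ] - centers[assign[i], ])^2), 0))
    trace <- c(trace, obj)
    new_centers <- centers
    for (j in seq_len(nrow(centers)))
      new_centers[j, ] <- colMeans(X[assign == j, , drop = FALSE])
    if (it > 1L && trace[it - 1L] - obj < tol &&
        all(abs(new_centers - centers) < tol)) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  a <- .assign_nearest(X, centers)
  obj <- sum(a$d2[cbind(seq_len(nrow(X)), a$cluster)])
  trace <- c(trace, obj)
  list(cluster = a$cluster, centers = centers, objective = obj,
       objective_trace = trace)
}

#' Cluster patients by k-means or Gower k-medoids
#'
#' Default mode runs Lloyd's algorithm with k-means++ seeding on the numeric
#' profile matrix (normalized values all share the `[0, 1]` scale, so
#' Euclidean geometry is well defined), minimizing the within-cluster sum of
#' squared distances to centroids; the best of `n_restarts` runs is kept and
#' the per-iteration objective trace of the winning run is returned (it is
#' non-increasing). An empty cluster arising during iteration is re-seeded at
#' the point farthest from its current centroid. `mode = "gower"` instead
#' runs PAM k-medoids (via \pkg{cluster}) on a Gower dissimilarity, for users
#' who prefer clustering raw mixed-type records.
#'
#' @param x Profile matrix with rows = patients (an `alpha_matrix` is
#'   transposed automatically), or for `mode = "gower"` a [gower_matrix()] /
#'   `dist` / cohort (with `registry`).
#' @param k Number of clusters (default 3, the clinical High/Medium/Low
#'   target).
#' @param mode `"euclidean"` (Lloyd k-means) or `"gower"` (PAM k-medoids).
#' @param seed RNG seed for initialization.
#' @param n_restarts k-means++ restarts (default 10).
#' @param max_iter,tol Lloyd iteration controls.
#' @param registry Needed when `x` is a cohort in gower mode.
#' @return List of class `"cluster_model"`: `assignments` (named integer),
#'   `centroids` (k x n_vars, euclidean mode; medoid profiles in gower mode),
#'   `objective`, `objective_trace`, `k`, `mode`, `seed`.
#' @export
kmeans_cluster <- function(x, k = 3, mode = c("euclidean", "gower"),
                           seed = 1L, n_restarts = 10, max_iter = 300,
                           tol = 1e-6, registry = NULL) {
  mode <- match.arg(mode)
  if (mode == "euclidean") {
    X <- if (inherits(x, "alpha_matrix")) t(unclass(x)) else as.matrix(x)
    storage.mode(X) <- "double"
    if (k > nrow(unique(X)))
      stop("infeasible K: ", k, " clusters but only ", nrow(unique(X)),
           " distinct profiles", call. = FALSE)
    best <- NULL
    with_seed(seed, {
      for (r in seq_len(n_restarts)) {
        init <- .kmeanspp_init(X, k)
        fit <- .lloyd(X, init, max_iter, tol)
        if (is.null(best) || fit$objective < best$objective) best <- fit
      }
    })
    out <- list(assignments = stats::setNames(best$cluster, rownames(X)),
                centroids = best$centers, objective = best$objective,
                objective_trace = best$objective_trace,
                k = k, mode = "euclidean_kmeans", seed = seed)
  } else {
    D <- if (inherits(x, "gower_matrix")) unclass(x)
         else if (inherits(x, "dist")) as.matrix(x)
         else if (is.matrix(x) && isSymmetric(unname(x)) &&
                  all(diag(x) == 0)) x
         else unclass(gower_matrix(x, registry))
    if (k > nrow(D)) stop("infeasible K", call. = FALSE)
    fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
    out <- list(assignments = stats::setNames(as.integer(fit$clustering),
                                              rownames(D)),
                centroids = NULL, medoids = fit$id.med,
                objective = fit$objective[["swap"]] * nrow(D),
                objective_trace = NULL,
                k = k, mode = "gower_kmedoids", seed = seed)
  }
  class(out) <- "cluster_model"
  out
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %s, K = %d, objective = %.5g\n  sizes: %s\n",
              x$mode, x$k, x$objective,
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}

#' Choose the number of clusters
#'
#' Fits the clustering for each `K` in `k_range`, reporting the objective
#' (elbow curve) and the mean silhouette width computed on the same geometry
#' used for clustering (Euclidean distances of the profile matrix, or the
#' Gower dissimilarity). The recommended `K` maximizes the mean silhouette;
#' the elbow curve is returned for visual confirmation. Silhouette widths of
#' singleton clusters are 0 and flagged.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Candidate cluster counts (default `2:8`).
#' @return List of class `"k_selection"`: `table` (data frame `k`,
#'   `objective`, `mean_silhouette`, `n_singletons`), `recommended_k`.
#' @export
select_k <- function(x, k_range = 2:8, mode = c("euclidean", "gower"),
                     seed = 1L, n_restarts = 10, registry = NULL) {
  mode <- match.arg(mode)
  X <- if (inherits(x, "alpha_matrix")) t(unclass(x)) else x
  D <- if (mode == "euclidean") as.matrix(stats::dist(X))
       else if (inherits(x, "gower_matrix")) unclass(x)
       else unclass(gower_matrix(X, registry))
  if (all(D[upper.tri(D)] == 0))
    stop("all profiles identical: silhouette undefined", call. = FALSE)
  rows <- lapply(k_range, function(k) {
    fit <- kmeans_cluster(X, k = k, mode = mode, seed = seed,
                          n_restarts = n_restarts, registry = registry)
    sil <- cluster::silhouette(as.integer(fit$assignments),
                               dmatrix = D)
    widths <- if (is.matrix(sil)) sil[, "sil_width"] else 0
    data.frame(k = k, objective = fit$objective,
               mean_silhouette = mean(widths),
               n_singletons = sum(tabulate(fit$assignments, k) == 1L))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 recommended_k = tab$k[which.max(tab$mean_silhouette)],
                 mode = mode),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Cluster-number selection (", x$mode, " geometry)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("recommended K =", x$recommended_k, "(silhouette argmax)\n")
  invisible(x)
}

#' Label clusters by mean priority score
#'
#' Clusters are ranked by the mean composite score of their members; with
#' `K = 3` the top/middle/bottom clusters become High/Medium/Low, otherwise
#' ordinal labels `P1` (highest mean) .. `PK`. Ties between cluster means are
#' broken by the higher maximum member score (with a warning).
#'
#' @param model A [kmeans_cluster()] result.
#' @param scores Score vector aligned with the clustered patients.
#' @return A `"priority_labeling"` (method `"cluster"`) with the per-cluster
#'   mean scores attached as `cluster_means`.
#' @export
label_clusters <- function(model, scores) {
  cl <- model$assignments
  s <- as.numeric(scores)
  if (length(s) != length(cl))
    stop("scores and assignments differ in length", call. = FALSE)
  means <- vapply(seq_len(model$k), function(k) mean(s[cl == k]), 0)
  maxs  <- vapply(seq_len(model$k), function(k) max(s[cl == k]), 0)
  if (anyDuplicated(means))
    warning("tied cluster mean scores: ties broken by maximum member score")
  rank_order <- order(-means, -maxs)  # rank_order[1] = top-priority cluster
  lab_names <- if (model$k == 3L) c("High", "Medium", "Low")
               else paste0("P", seq_len(model$k))
  if (model$k == 1L) lab_names <- "Medium"
  cluster_label <- character(model$k)
  cluster_label[rank_order] <- lab_names
  labels <- factor(cluster_label[cl],
                   levels = if (model$k == 3L) c("High", "Medium", "Low")
                            else unique(lab_names))
  structure(list(labels = stats::setNames(labels, names(cl)),
                 method = "cluster",
                 thresholds = NULL,
                 cluster_means = stats::setNames(means, cluster_label)),
            class = "priority_labeling")
}

#' Two-component PCA projection of patient profiles
#'
#' Centers the columns of the patients-by-variables matrix and projects onto
#' the top two eigenvectors of the covariance (no rescaling: normalized
#' values already share the `[0, 1]` scale). Sign convention: each loading's
#' largest-magnitude entry is positive. If the data have rank < 2 the second
#' component is reported with zero explained variance and flagged.
#'
#' @param x Patients x variables matrix (an `alpha_matrix` is transposed).
#' @return List of class `"projection_result"`: `coordinates` (N x 2),
#'   `explained_variance` (fractions for PC1, PC2), `loadings`
#'   (n_vars x 2, orthonormal), `rank_deficient` flag.
#' @export
pca_project <- function(x) {
  X <- if (inherits(x, "alpha_matrix")) t(unclass(x)) else as.matrix(x)
  if (nrow(X) < 3L) stop("need at least 3 patients for PCA", call. = FALSE)
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  frac <- ev / sum(ev)
  k2 <- min(2L, ncol(fit$rotation))
  L <- fit$rotation[, seq_len(k2), drop = FALSE]
  Z <- fit$x[, seq_len(k2), drop = FALSE]
  for (j in seq_len(k2)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; Z[, j] <- -Z[, j] }
  }
  rank_deficient <- k2 < 2L || frac[2] < .Machine$double.eps
  if (k2 < 2L) {  # pad a zero second component
    L <- cbind(L, 0); Z <- cbind(Z, 0); frac <- c(frac, 0)
  }
  colnames(L) <- colnames(Z) <- c("PC1", "PC2")
  structure(list(coordinates = Z,
                 explained_variance = stats::setNames(frac[1:2], c("PC1", "PC2")),
                 loadings = L, rank_deficient = rank_deficient),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("PCA projection: PC1 %.1f%%, PC2 %.1f%% of total variance%s\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2],
              if (x$rank_deficient) " (rank deficient)" else ""))
  invisible(x)
}

.scatter <- function(X, groups) {
  mu <- colMeans(X)
  W <- matrix(0, ncol(X), ncol(X))
  B <- matrix(0, ncol(X), ncol(X))
  for (g in unique(groups)) {
    Xi <- X[groups == g, , drop = FALSE]
    mi <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mi)
    W <- W + crossprod(Xc)
    B <- B + nrow(Xi) * tcrossprod(mi - mu)
  }
  list(W = W, B = B)
}

.wilks <- function(X, groups, ridge = 1e-8) {
  s <- .scatter(X, groups)
  T <- s$W + s$B
  r <- ridge * mean(diag(T))
  d <- diag(ncol(X))
  detW <- det(s$W + r * d)
  detT <- det(T + r * d)
  if (detT <= 0) return(1)
  detW / detT
}

#' Permutation MANOVA test of cluster separation
#'
#' Tests whether cluster centroids are separated beyond chance using a
#' Wilks'-lambda-style statistic `det(W) / det(W + B)` (within / total
#' scatter; smaller = more separation), with significance from a label
#' permutation null: `p = (1 + #\{perm lambda <= observed\}) /
#' (1 + n_permutations)`. Avoiding the classical F approximation keeps the
#' test exact-by-construction at small N. Pairwise Mahalanobis distances
#' between centroids use the pooled within-cluster covariance,
#' ridge-regularized when singular.
#'
#' @param x Patients x variables matrix (an `alpha_matrix` is transposed).
#' @param assignments Integer cluster labels (or a `cluster_model`).
#' @param n_permutations Number of label shuffles (default 999).
#' @param seed RNG seed for the permutations.
#' @return List of class `"separation_test"`: `statistic` (observed lambda),
#'   `p_value`, `mahalanobis` (K x K centroid distance matrix),
#'   `n_permutations`, `seed`.
#' @export
separation_test <- function(x, assignments, n_permutations = 999, seed = 1L) {
  X <- if (inherits(x, "alpha_matrix")) t(unclass(x)) else as.matrix(x)
  if (inherits(assignments, "cluster_model"))
    assignments <- assignments$assignments
  groups <- as.integer(assignments)
  ks <- sort(unique(groups))
  if (length(ks) < 2L) stop("need at least two clusters", call. = FALSE)
  if (any(tabulate(groups) == 1L))
    stop("each cluster needs at least 2 members", call. = FALSE)

  obs <- .wilks(X, groups)
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i)
    .wilks(X, sample(groups)), 0))
  p <- (1 + sum(perm <= obs)) / (1 + n_permutations)

  # pooled within covariance for Mahalanobis centroid distances
  s <- .scatter(X, groups)
  S <- s$W / (nrow(X) - length(ks))
  Sinv <- tryCatch(solve(S), error = function(e) {
    Sr <- S + diag(1e-6 * mean(diag(S)) + 1e-12, ncol(S))
    tryCatch(solve(Sr), error = function(e2)
      stop("singular pooled covariance even after regularization; ",
           "deficient variables: ",
           paste(colnames(X)[diag(S) < 1e-12], collapse = ", "), call. = FALSE))
  })
  centroids <- do.call(rbind, lapply(ks, function(g)
    colMeans(X[groups == g, , drop = FALSE])))
  K <- length(ks)
  Dm <- matrix(0, K, K, dimnames = list(ks, ks))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    d <- centroids[i, ] - centroids[j, ]
    Dm[i, j] <- Dm[j, i] <- sqrt(max(0, drop(t(d) %*% Sinv %*% d)))
  }
  structure(list(statistic = obs, p_value = p, mahalanobis = Dm,
                 n_permutations = n_permutations, seed = seed),
            class = "separation_test")
}

#' @export
print.separation_test <- function(x, ...) {
  cat(sprintf("Permutation MANOVA: Wilks lambda = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}
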