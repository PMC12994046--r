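#' Run the full prioritization pipeline
#'
#' Convenience wrapper chaining the standard analysis: preprocess the cohort
#' (exclusion + subgroup imputation), aggregate expert ratings into weights,
#' build the normalized decision matrix, compute composite scores, cluster
#' patients on their normalized profiles, label clusters by mean score, and
#' produce the PCA projection and centroid-separation diagnostics.
#' Deterministic given `seed`.
#'
#' @param cohort A [cohort_table()] (raw; preprocessing is applied).
#' @param ratings A [rating_matrix()] or a precomputed `weight_vector`.
#' @param registry A [variable_registry()].
#' @param k Number of clusters (default 3).
#' @param mode Clustering mode, `"euclidean"` or `"gower"`.
#' @param weighted Cluster/project the weight-scaled profiles `w_i alpha_ip`
#'   instead of the raw normalized profiles (default `FALSE`: uneven weight
#'   scaling distorts the cluster geometry; see the methods vignette).
#' @param label_method Score labeling to also compute: `"tertile"` or
#'   `"fixed"`.
#' @param seed RNG seed for clustering and diagnostics.
#' @param n_permutations Permutations for the separation test (default 199
#'   in the pipeline; increase for reporting).
#' @return List of class `"priority_pipeline"`: `cohort`, `exclusions`,
#'   `weights`, `alpha`, `scores`, `score_labels`, `clusters`,
#'   `cluster_labels`, `projection`, `separation`, `seed`.
#' @export
run_pipeline <- function(cohort, ratings, registry, k = 3,
                         mode = c("euclidean", "gower"), weighted = FALSE,
                         label_method = c("tertile", "fixed"), seed = 1L,
                         n_permutations = 199) {
  mode <- match.arg(mode)
  label_method <- match.arg(label_method)
  pre <- preprocess_cohort(cohort, registry)
  weights <- if (inherits(ratings, "weight_vector")) ratings
             else aggregate_weights(ratings)
  alpha <- build_alpha_matrix(pre$cohort, registry)
  scores <- priority_score(weights, alpha)
  score_labels <- assign_priority_labels(scores, method = label_method)
  X <- t(unclass(alpha))
  if (weighted) X <- sweep(X, 2, as.numeric(weights), `*`)
  clusters <- if (mode == "gower" && !weighted)
    kmeans_cluster(pre$cohort, k = k, mode = "gower", seed = seed,
                   registry = registry)
  else kmeans_cluster(X, k = k, mode = mode, seed = seed)
  cluster_labels <- label_clusters(clusters, scores)
  projection <- pca_project(X)
  separation <- separation_test(X, clusters,
                                n_permutations = n_permutations, seed = seed)
  structure(list(cohort = pre$cohort, exclusions = pre$exclusions,
                 weights = weights, alpha = alpha, scores = scores,
                 score_labels = score_labels, clusters = clusters,
                 cluster_labels = cluster_labels, projection = projection,
                 separation = separation, seed = seed),
            class = "priority_pipeline")
}

#' @export
print.priority_pipeline <- function(x, ...) {
  cat("Prioritization pipeline:", ncol(x$alpha), "patients,",
      nrow(x$alpha), "variables\n")
  cat(sprintf("  excluded: %d | score range: %.3f-%.3f\n",
              nrow(x$exclusions), min(x$scores), max(x$scores)))
  cat("  cluster sizes:",
      paste(tabulate(x$clusters$assignments, x$clusters$k), collapse = ", "),
      sprintf("| separation p = %.4g\n", x$separation$p_value))
  invisible(x)
}
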