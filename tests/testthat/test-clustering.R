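# exhaustive-enumeration oracle: best k-partition objective on tiny instances
enumerate_kmeans <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  assign_next <- function(assign, i) {
    if (i > n) {
      if (length(unique(assign)) < k) return()
      obj <- 0
      for (g in unique(assign)) {
        Xi <- X[assign == g, , drop = FALSE]
        mu <- colMeans(Xi)
        obj <- obj + sum(sweep(Xi, 2, mu)^2)
      }
      if (obj < best) best <<- obj
      return()
    }
    for (g in seq_len(min(k, max(assign[seq_len(i - 1)], 0) + 1)))
      assign_next(c(assign[seq_len(i - 1)], g), i + 1)
  }
  assign_next(integer(0), 1)
  best
}

test_that("Gower dissimilarity matches the hand oracle on toy records", {
  # two numeric variables with unit ranges: (|0.2-0.6| + |0.4-0.8|)/2 = 0.4
  X <- rbind(c(0.2, 0.4), c(0.6, 0.8))
  D <- gower_matrix(X, ranges = c(1, 1))
  expect_equal(D[1, 2], 0.4)
  expect_equal(diag(D), c(0, 0), ignore_attr = TRUE)

  # identical records are at distance zero
  reg <- toy_registry()
  coh <- toy_cohort(reg)
  df <- as.data.frame(coh)
  df2 <- rbind(df, transform(df[1, ], patient_id = "p5"))
  D2 <- gower_matrix(cohort_table(df2, reg), reg)
  expect_equal(D2["p1", "p5"], 0)

  # a lone categorical variable: differing levels are maximally dissimilar
  reg1 <- variable_registry(list(
    variable_spec("c", "categorical", levels = c("x", "y"),
                  impact_scores = c(1, 2))))
  coh1 <- cohort_table(data.frame(patient_id = c("a", "b"),
                                  c = c("x", "y")), reg1)
  expect_equal(gower_matrix(coh1, reg1)["a", "b"], 1)

  # mixed-type oracle: sev ordinal ranks (2,0)/2 -> 1; wait |2-14|/24 = 0.5;
  # comorb mismatch 1; area mismatch 1 -> mean = 0.875
  D3 <- gower_matrix(coh, reg)
  expect_equal(D3["p1", "p2"], (1 + 0.5 + 1 + 1) / 4)

  # zero-range variable contributes 0 and is flagged
  Z <- cbind(c(1, 2, 3), c(5, 5, 5))
  Dz <- gower_matrix(Z)
  expect_equal(attr(Dz, "zero_range_variables"), "2")
  expect_equal(Dz[1, 3], 0.5)  # (1 + 0)/2
})

test_that("Gower is symmetric, bounded and agrees with daisy on numeric data", {
  set.seed(5)
  X <- matrix(runif(30), 10, 3)
  D <- gower_matrix(X)
  expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)
  expect_true(all(D >= 0 & D <= 1))
  ref <- as.matrix(cluster::daisy(as.data.frame(X), metric = "gower"))
  expect_equal(unclass(D), unclass(ref), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("k-means finds the enumeration optimum on tiny instances", {
  set.seed(11)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- centers[rep(1:3, each = 2), ] + matrix(rnorm(12, sd = 0.4), 6, 2)
  fit <- kmeans_cluster(X, k = 3, seed = 2, n_restarts = 10)
  expect_equal(fit$objective, enumerate_kmeans(X, 3), tolerance = 1e-9)
  # each tight pair forms its own cluster
  expect_equal(fit$assignments[1], fit$assignments[2])
  expect_equal(fit$assignments[3], fit$assignments[4])
  expect_equal(fit$assignments[5], fit$assignments[6])
  expect_length(unique(fit$assignments), 3L)

  # independent oracle on a random instance
  Y <- matrix(runif(14), 7, 2)
  fy <- kmeans_cluster(Y, k = 2, seed = 3, n_restarts = 20)
  expect_equal(fy$objective, enumerate_kmeans(Y, 2), tolerance = 1e-9)
})

test_that("K = 1 reduces to the global mean and total scatter", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)
  fit <- kmeans_cluster(X, k = 1, seed = 1, n_restarts = 2)
  expect_equal(fit$centroids[1, ], colMeans(X), ignore_attr = TRUE)
  expect_equal(fit$objective, sum(sweep(X, 2, colMeans(X))^2))
})

test_that("k-means objective is non-increasing per Lloyd iteration and
           matches stats::kmeans at the optimum", {
  set.seed(6)
  X <- matrix(runif(60), 30, 2)
  fit <- kmeans_cluster(X, k = 3, seed = 9, n_restarts = 10)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
  # centroids equal their members' means (the fixed-point condition)
  for (g in 1:3)
    expect_equal(fit$centroids[g, ],
                 colMeans(X[fit$assignments == g, , drop = FALSE]),
                 ignore_attr = TRUE)
  # independent route: stats::kmeans agrees at the global optimum of a
  # well-separated instance
  b <- make_blobs(n_per = 10, sep = 12, sd = 0.5, seed = 61)
  fitb <- kmeans_cluster(b$X, k = 3, seed = 9, n_restarts = 10)
  kmb <- stats::kmeans(b$X, centers = 3, nstart = 50, iter.max = 100)
  expect_equal(fitb$objective, kmb$tot.withinss, tolerance = 1e-9)
})

test_that("duplicating every point leaves the optimal centroids unchanged", {
  set.seed(13)
  b <- make_blobs(n_per = 5, sep = 8, sd = 0.3, seed = 13)
  fit1 <- kmeans_cluster(b$X, k = 3, seed = 1)
  fit2 <- kmeans_cluster(rbind(b$X, b$X), k = 3, seed = 1)
  ord1 <- order(fit1$centroids[, 1], fit1$centroids[, 2])
  ord2 <- order(fit2$centroids[, 1], fit2$centroids[, 2])
  expect_equal(fit1$centroids[ord1, ], fit2$centroids[ord2, ],
               tolerance = 1e-9)
  expect_equal(fit2$objective, 2 * fit1$objective, tolerance = 1e-9)
})

test_that("assignments are deterministic given the seed and K is validated", {
  X <- matrix(runif(40), 20, 2)
  f1 <- kmeans_cluster(X, k = 3, seed = 42)
  f2 <- kmeans_cluster(X, k = 3, seed = 42)
  expect_identical(f1$assignments, f2$assignments)
  expect_error(kmeans_cluster(matrix(1, 5, 2), k = 3), "infeasible K")
})

test_that("gower k-medoids recovers well-separated mixed blobs", {
  b <- make_blobs(n_per = 8, sep = 12, sd = 0.4, seed = 21)
  fit <- kmeans_cluster(gower_matrix(b$X), k = 3, mode = "gower", seed = 1)
  expect_equal(fit$mode, "gower_kmedoids")
  tab <- table(fit$assignments, b$truth)
  expect_equal(sum(apply(tab, 2, max)), length(b$truth))  # pure clusters
})

test_that("silhouette-based K selection finds three separated blobs", {
  b <- make_blobs(n_per = 10, sep = 10, sd = 0.4, seed = 17)
  sel <- select_k(b$X, k_range = 2:5, seed = 3)
  expect_equal(sel$recommended_k, 3)
  expect_gt(sel$table$mean_silhouette[sel$table$k == 3], 0.5)
  # the elbow curve is strictly decreasing in K on non-degenerate data
  expect_true(all(diff(sel$table$objective) < 0))

  # two blobs: silhouette maximal at K = 2
  set.seed(19)
  X2 <- rbind(matrix(rnorm(40, sd = 0.3), 20, 2),
              matrix(rnorm(40, mean = 8, sd = 0.3), 20, 2))
  sel2 <- select_k(X2, k_range = 2:4, seed = 3)
  expect_equal(sel2$recommended_k, 2)
  expect_true(all(diff(sel2$table$objective) < 0))

  # identical points: silhouette undefined
  expect_error(select_k(matrix(1, 6, 2), k_range = 2:3), "identical")
})

test_that("clusters are labeled by descending mean score", {
  cl <- structure(list(assignments = stats::setNames(rep(1:3, each = 4),
                                                     paste0("p", 1:12)),
                       k = 3L), class = "cluster_model")
  s <- c(rep(0.22, 4), rep(0.30, 4), rep(0.16, 4))
  lab <- label_clusters(cl, s)
  expect_equal(as.character(lab$labels[1:4]), rep("Medium", 4))
  expect_equal(as.character(lab$labels[5:8]), rep("High", 4))
  expect_equal(as.character(lab$labels[9:12]), rep("Low", 4))
  expect_equal(unname(lab$cluster_means[c("High", "Medium", "Low")]),
               c(0.30, 0.22, 0.16))

  # permuting cluster indices leaves patient labels unchanged
  cl2 <- cl; cl2$assignments <- stats::setNames(c(3, 1, 2)[cl$assignments],
                                                names(cl$assignments))
  s2 <- s
  lab2 <- label_clusters(cl2, s2)
  expect_identical(as.character(lab2$labels), as.character(lab$labels))

  # K = 1 degenerates to a single Medium group
  cl1 <- structure(list(assignments = stats::setNames(rep(1L, 3), letters[1:3]),
                        k = 1L), class = "cluster_model")
  expect_true(all(label_clusters(cl1, c(0.1, 0.2, 0.3))$labels == "Medium"))

  # tied means warn and break by maximum member score
  clt <- structure(list(assignments = stats::setNames(rep(1:2, each = 2), NULL),
                        k = 2L), class = "cluster_model")
  expect_warning(labt <- label_clusters(clt, c(0.1, 0.3, 0.2, 0.2)), "tied")
  expect_equal(as.character(labt$labels), c("P1", "P1", "P2", "P2"))
})

test_that("PCA projection is variance-ordered with a fixed sign convention", {
  # collinear data: PC1 explains everything
  t <- seq(-1, 1, length.out = 20)
  X <- cbind(2 * t, -t)
  pr <- pca_project(X)
  expect_equal(unname(pr$explained_variance), c(1, 0), tolerance = 1e-12)
  expect_true(pr$rank_deficient)
  # sign convention: dominant loading entry positive
  expect_gt(pr$loadings[which.max(abs(pr$loadings[, 1])), 1], 0)

  # rank-2 data reconstruct exactly from two components
  set.seed(23)
  B <- matrix(rnorm(10 * 2), 10, 2)
  L <- matrix(rnorm(2 * 5), 2, 5)
  X2 <- B %*% L
  pr2 <- pca_project(X2)
  recon <- pr2$coordinates %*% t(pr2$loadings)
  centered <- sweep(X2, 2, colMeans(X2))
  expect_equal(recon, centered, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(pr2$explained_variance), 1, tolerance = 1e-12)
  expect_gte(pr2$explained_variance[1], pr2$explained_variance[2])
  # loadings orthonormal
  expect_equal(crossprod(pr2$loadings), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)

  # isotropic data: explained fractions roughly equal
  set.seed(29)
  X3 <- matrix(rnorm(4000), 2000, 2)
  pr3 <- pca_project(X3)
  expect_lt(abs(pr3$explained_variance[1] - 0.5), 0.05)
  expect_error(pca_project(matrix(1, 2, 3)), "at least 3")
})

test_that("the permutation MANOVA separates blobs and is calibrated on noise", {
  b <- make_blobs(n_per = 8, sep = 15, sd = 0.3, seed = 31)
  st <- separation_test(b$X, b$truth, n_permutations = 199, seed = 5)
  expect_equal(st$p_value, 1 / 200)  # observed below every permutation
  expect_true(all(st$mahalanobis[upper.tri(st$mahalanobis)] > 0))
  expect_equal(st$mahalanobis, t(st$mahalanobis))

  # null calibration: random labels on homogeneous data rarely reject
  set.seed(37)
  ps <- replicate(20, {
    X <- matrix(rnorm(50 * 3), 50, 3)
    g <- sample(rep(1:2, 25))
    separation_test(X, g, n_permutations = 99,
                    seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(mean(ps > 0.05), 0.9)

  # coincident centroids: Mahalanobis distances vanish
  set.seed(41)
  base <- matrix(rnorm(20), 10, 2)
  X <- rbind(base, base)          # same points in both groups
  g <- rep(1:2, each = 10)
  st0 <- separation_test(X, g, n_permutations = 99, seed = 1)
  expect_equal(max(st0$mahalanobis), 0, tolerance = 1e-9)

  expect_error(separation_test(matrix(rnorm(20), 10, 2), rep(1, 10)),
               "two clusters")
  expect_error(separation_test(matrix(rnorm(20), 10, 2), c(1, rep(2, 9))),
               "2 members")
})
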