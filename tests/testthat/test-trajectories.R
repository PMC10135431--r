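test_that("temporal profiles are group means z-scored with population sd", {
  ages <- rep(c(3, 6, 12, 20), each = 2)
  x <- rbind(
    lin = rep(c(1, 2, 3, 4), each = 2),
    const = rep(5, 8)
  )
  colnames(x) <- paste0("s", 1:8)
  tp <- temporal_profiles(x, ages)
  expect_equal(unname(tp$z["lin", ]),
               c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
  expect_true(tp$constant["const"])
  expect_false("const" %in% rownames(tp$z))
  # brute-force oracle on random data
  withr::with_seed(81, {
    y <- matrix(rnorm(20 * 8), 20, dimnames = list(sprintf("g%d", 1:20),
                                                   paste0("s", 1:8)))
  })
  tp2 <- temporal_profiles(y, ages)
  for (g in rownames(y)) {
    mns <- as.numeric(tapply(y[g, ], ages, mean)[c("3", "6", "12", "20")])
    zz <- (mns - mean(mns)) / sqrt(mean((mns - mean(mns))^2))
    expect_equal(unname(tp2$z[g, ]), zz, tolerance = 1e-9)
  }
})

test_that("co-expression similarity has correlation semantics", {
  p <- c(-1.2, -0.2, 0.4, 1.0)
  expect_equal(coexpression_similarity(p, p), 1)
  expect_equal(coexpression_similarity(p, -p), -1)
  # refinement oracle: a dense grid changes the value by < 1e-3
  withr::with_seed(82, {
    for (i in 1:5) {
      a <- rnorm(4); b <- rnorm(4)
      coarse <- coexpression_similarity(a, b, grid_points = 101)
      dense <- coexpression_similarity(a, b, grid_points = 10001)
      expect_lt(abs(coarse - dense), 1e-3)
    }
  })
  expect_error(coexpression_similarity(rep(1, 4), p), "constant")
})

test_that("the circular SOM recovers planted shapes deterministically", {
  tp <- simulate_trajectory_profiles(n_per_shape = 20, noise_sd = 0.2, seed = 83)
  m1 <- som_cluster(tp$z, 3, seed = 84)
  m2 <- som_cluster(tp$z, 3, seed = 84)
  expect_identical(m1$assignment, m2$assignment)
  expect_equal(m1$nodes, m2$nodes)
  expect_gte(ari(m1$assignment, tp$truth), 0.9)
  expect_error(som_cluster(tp$z, 1, seed = 1), "k must be >= 2")
  expect_error(som_cluster(tp$z[1:3, ], 5, seed = 1), "exceeds")
})

test_that("assignments are invariant under gene reordering", {
  tp <- simulate_trajectory_profiles(n_per_shape = 15, noise_sd = 0.2, seed = 85)
  m <- som_cluster(tp$z, 3, seed = 86)
  perm <- rev(seq_len(nrow(tp$z)))
  mp <- som_cluster(tp$z[perm, ], 3, seed = 86)
  # same partition (cluster labels may rotate around the ring)
  expect_equal(ari(m$assignment, mp$assignment[rownames(tp$z)]), 1)
})

test_that("BIC selects the planted cluster count", {
  tp <- simulate_trajectory_profiles(n_per_shape = 20, noise_sd = 0.2, seed = 87)
  sel <- select_k_bic(tp$z, k_range = 2:6, seed = 88)
  expect_equal(sel$k_star, 3)
  expect_true(all(is.finite(sel$bic$bic)))
  expect_gte(ari(sel$model$assignment, tp$truth), 0.9)
  # cross-check the local ARI implementation against mclust
  skip_if_not_installed("mclust")
  expect_equal(ari(sel$model$assignment, tp$truth),
               mclust::adjustedRandIndex(sel$model$assignment, tp$truth))
})

test_that("a single tight cloud selects the smallest k", {
  withr::with_seed(89, {
    center <- c(-1.2, -0.4, 0.4, 1.2)
    center <- (center - mean(center)) / sqrt(mean((center - mean(center))^2))
    z <- matrix(rep(center, each = 120), 120) +
      matrix(rnorm(480, sd = 0.15), 120)
    rownames(z) <- sprintf("g%d", 1:120)
    colnames(z) <- c("3", "6", "12", "20")
  })
  sel <- select_k_bic(z, k_range = 2:5, seed = 90)
  expect_equal(sel$k_star, 2)
  expect_true(all(diff(sel$bic$bic) > 0))  # monotone increasing in k
})

test_that("cluster mean profiles equal the mean of member z-profiles", {
  tp <- simulate_trajectory_profiles(n_per_shape = 12, noise_sd = 0.2, seed = 91)
  m <- som_cluster(tp$z, 3, seed = 92)
  cm <- cluster_mean_profiles(m, tp$z)
  for (j in 1:3) {
    idx <- names(m$assignment)[m$assignment == j]
    expect_equal(cm[j, ], colMeans(tp$z[idx, , drop = FALSE]))
  }
})
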