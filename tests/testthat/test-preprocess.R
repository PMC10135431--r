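test_that("CPM matches its definition", {
  # gene with count 10 in a library of 1e6 reads -> 10 CPM; zero count -> 0
  m <- matrix(c(10, 0, 1e6 - 10), 3, 1,
              dimnames = list(c("a", "b", "filler"), "s1"))
  expect_equal(compute_cpm(m)["a", "s1"], 10)
  expect_equal(compute_cpm(m)["b", "s1"], 0)

  # brute-force oracle on a random matrix with TMM factors
  cc <- toy_counts(50, 6)
  f <- runif(6, 0.8, 1.2)
  got <- compute_cpm(cc, f)
  want <- cc
  for (s in 1:6) want[, s] <- cc[, s] / (sum(cc[, s]) * f[s]) * 1e6
  expect_equal(got, want)
  expect_error(compute_cpm(cbind(cc, zero = 0)), "all-zero")
})

test_that("column CPM sums to 1e6 with unit factors", {
  cc <- toy_counts(80, 5, seed = 7)
  expect_equal(unname(colSums(compute_cpm(cc))), rep(1e6, 5), tolerance = 1e-12)
})

test_that("low-abundance filter applies the library-size-derived threshold", {
  # all library sizes 8e6 -> N = 1 exactly
  tot <- matrix(1, 4, 5, dimnames = list(paste0("g", 1:4), paste0("t", 1:5)))
  pol <- matrix(1, 4, 5, dimnames = list(paste0("g", 1:4), paste0("p", 1:5)))
  tot[4, ] <- 8e6 - 3
  pol[4, ] <- 8e6 - 3
  # genes 1..3 have CPM 1/8 = 0.125; gene 4 huge
  flt <- filter_low_abundance(tot, pol)
  expect_equal(flt$threshold, 1)
  expect_equal(flt$kept, "g4")
})

test_that("a gene at CPM exactly N in exactly 4 samples is kept (inclusive)", {
  # library size 1e6 everywhere -> N = 8 CPM; count 8 -> CPM exactly 8
  mk <- function(gA) {
    m <- rbind(gA = gA, filler = 1e6 - gA)
    colnames(m) <- paste0("s", seq_along(gA))
    m
  }
  tot <- mk(c(8, 8, 8, 8, 0))
  pol <- mk(c(0, 0, 0, 0, 0))
  expect_true("gA" %in% filter_low_abundance(tot, pol)$kept)
  tot3 <- mk(c(8, 8, 8, 0, 0))  # only 3 samples at threshold
  expect_false("gA" %in% filter_low_abundance(tot3, pol)$kept)
})

test_that("filter equals the exhaustive per-gene rule and is monotone", {
  withr::with_seed(11, {
    tot <- matrix(rnbinom(300 * 8, mu = 30, size = 1), 300,
                  dimnames = list(sprintf("g%03d", 1:300), paste0("t", 1:8)))
    pol <- matrix(rnbinom(300 * 8, mu = 30, size = 1), 300,
                  dimnames = list(sprintf("g%03d", 1:300), paste0("p", 1:8)))
  })
  flt <- filter_low_abundance(tot, pol, min_samples = 4)
  N <- median(8e6 / c(colSums(tot), colSums(pol)))
  expect_equal(flt$threshold, N)
  cpm_t <- compute_cpm(tot); cpm_p <- compute_cpm(pol)
  for (g in rownames(tot)) {
    keep <- sum(cpm_t[g, ] >= N) >= 4 || sum(cpm_p[g, ] >= N) >= 4
    expect_identical(g %in% flt$kept, keep)
  }
  # monotone: adding counts to a kept gene never removes it
  g_kept <- flt$kept[1]
  tot2 <- tot; tot2[g_kept, ] <- tot2[g_kept, ] + 50
  expect_true(g_kept %in% filter_low_abundance(tot2, pol)$kept)
})

test_that("TMM factors behave as the trimmed M-value definition requires", {
  cc <- toy_counts(200, 2, lambda = 200, seed = 3)
  same <- cbind(a = cc[, 1], b = cc[, 1])
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  # pure depth change is absorbed by library size
  depth <- cbind(a = cc[, 1], b = 2L * cc[, 1])
  expect_equal(unname(tmm_factors(depth)), c(1, 1))
  # composition shift: oracle = brute-force trimmed weighted mean
  shift <- cc[, 1:2]
  shift[1:20, 2] <- shift[1:20, 2] * 8
  f <- tmm_factors(shift, reference = 1)
  raw <- brute_tmm_pair(shift[, 2], shift[, 1])
  want <- c(1 / sqrt(raw), raw / sqrt(raw))  # geometric-mean-1 rescaling
  expect_equal(unname(f), unname(want), tolerance = 1e-10)
  # geometric mean of factors is 1
  many <- toy_counts(300, 6, lambda = 150, seed = 8)
  expect_equal(exp(mean(log(tmm_factors(many)))), 1, tolerance = 1e-9)
})

test_that("TMM factors are invariant to global depth rescaling of a sample", {
  cc <- toy_counts(250, 5, lambda = 120, seed = 13)
  f1 <- tmm_factors(cc, reference = 2)
  cc2 <- cc; cc2[, 3] <- cc2[, 3] * 4L
  f2 <- tmm_factors(cc2, reference = 2)
  # invariant up to the depth-dependent precision weights
  expect_equal(f1, f2, tolerance = 1e-3)
})

test_that("correlation-IQR outlier rule flags a planted outlier only", {
  withr::with_seed(5, {
    base <- rnorm(400, 8, 2)
    x <- sapply(1:8, function(i) base + rnorm(400, sd = 0.05))
    x[, 8] <- rnorm(400, 8, 2)  # independent noise sample
    colnames(x) <- paste0("s", 1:8)
  })
  res <- detect_outliers(x, rep("total", 8))
  expect_identical(res$sample_id[res$flagged], "s8")
  # scale-free: adding a constant leaves flags unchanged
  res2 <- detect_outliers(x + 5, rep("total", 8))
  expect_identical(res$flagged, res2$flagged)
})

test_that("identical samples yield no outlier flags and small sets error", {
  withr::with_seed(6, {
    base <- rnorm(100)
    x <- sapply(1:4, function(i) base + rnorm(100, sd = 1e-6))
    colnames(x) <- paste0("s", 1:4)
  })
  expect_false(any(detect_outliers(x, rep("total", 4))$flagged))
  expect_error(detect_outliers(x[, 1:3], rep("total", 3)), ">= 4")
  xc <- x; xc[, 2] <- 3
  expect_error(detect_outliers(xc, rep("total", 4)), "constant")
})

test_that("batch adjustment removes planted batch structure, preserves nulls", {
  withr::with_seed(21, {
    n <- 2000; ns <- 12
    group <- rep(c(3, 6, 12, 20), each = 3)
    batch <- rep(c("B1", "B2"), 6)
    x <- matrix(rnorm(n * ns, 6, 1), n, dimnames = list(sprintf("g%d", 1:n),
                                                        sprintf("s%d", 1:ns)))
    # null: no batch effect -> near-identity
    x0 <- batch_adjust(x, batch, group)
    expect_lt(max(abs(x0 - x)), 0.1)
    # planted additive offset delta = 2 on batch B2
    delta <- 2
    xb <- x + delta * matrix(rep(batch == "B2", each = n), n)
    xadj <- batch_adjust(xb, batch, group)
    diff_means <- rowMeans(xadj[, batch == "B2"]) - rowMeans(xadj[, batch == "B1"])
    expect_lt(abs(mean(diff_means)), 0.05)
  })
})

test_that("batch adjustment identity and confounding guards", {
  withr::with_seed(22, {
    x <- matrix(rnorm(50 * 8), 50, dimnames = list(NULL, paste0("s", 1:8)))
  })
  group <- rep(c(3, 20), each = 4)
  expect_identical(batch_adjust(x, rep("B1", 8), group), x)
  expect_error(batch_adjust(x, rep(c("B1", "B2"), each = 4), group),
               "confounded")
})

test_that("PCA separates planted sample clusters and normalizes variance", {
  withr::with_seed(30, {
    x <- matrix(rnorm(500 * 10), 500)
    x[, 6:10] <- x[, 6:10] + 2
    colnames(x) <- paste0("s", 1:10)
  })
  pc <- pca_samples(x)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
  side <- pc$scores[, 1] > median(pc$scores[, 1])
  expect_true(all(side[1:5] == side[1]) && all(side[6:10] == !side[1]))
  # duplicated sample -> identical scores
  xd <- cbind(x, s11 = x[, 1])
  pcd <- pca_samples(xd)
  expect_equal(pcd$scores["s11", ], pcd$scores["s1", ], tolerance = 1e-9)
})
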