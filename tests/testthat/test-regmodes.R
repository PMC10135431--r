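test_that("APV slope is exactly 1 on coupled noiseless data", {
  d <- study_design()
  smp <- d$samples
  withr::with_seed(51, {
    n <- 20
    tot <- matrix(rnorm(n * sum(smp$fraction == "total"), 6, 1), n)
    colnames(tot) <- smp$sample_id[smp$fraction == "total"]
    rownames(tot) <- sprintf("g%02d", 1:n)
  })
  pol <- tot
  colnames(pol) <- sub("_T$", "_P", colnames(tot))
  res <- apv_fit(tot, pol, smp, "20v3", "translation")
  expect_equal(res$beta, rep(1, n), tolerance = 1e-9)
  expect_equal(res$effect, rep(0, n), tolerance = 1e-9)
})

test_that("planted translational effects are recovered by APV", {
  sim <- simulate_paired_profiles(
    n_genes = 600, mode_config = list(translation = c(40, 1)),
    noise_sd = 0.25, seed = 52
  )
  res <- apv_fit(sim$total, sim$polysome, sim$samples, "20v3", "translation")
  planted <- sim$truth$mode == "translation"
  err <- res$effect[planted] - sim$truth$effect[planted]
  expect_lt(max(abs(err)), 0.45)
  expect_lt(mean(abs(err)), 0.2)
})

test_that("swapping the fraction matrices swaps translation and buffering", {
  sim <- simulate_paired_profiles(
    n_genes = 500,
    mode_config = list(translation = c(30, 1), buffering = c(30, 1)),
    seed = 53
  )
  smp <- sim$samples
  fwd <- regmode_analysis(sim$total, sim$polysome, smp, contrasts = "20v3")
  # swap matrices, relabelling columns so the sheet still matches
  tot2 <- sim$polysome; colnames(tot2) <- colnames(sim$total)
  pol2 <- sim$total; colnames(pol2) <- colnames(sim$polysome)
  rev <- regmode_analysis(tot2, pol2, smp, contrasts = "20v3")
  map <- c(translation = "buffering", buffering = "translation",
           abundance = "abundance", none = "none")
  expect_identical(unname(map[fwd$mode]), rev$mode)
  expect_equal(fwd$gamma, rev$gamma_b)
})

test_that("identical fraction matrices yield no translation or buffering", {
  sim <- simulate_paired_profiles(n_genes = 300,
                                  mode_config = list(abundance = c(30, 1.5)),
                                  seed = 54)
  pol <- sim$total
  colnames(pol) <- colnames(sim$polysome)
  calls <- regmode_analysis(sim$total, pol, sim$samples, contrasts = "20v3")
  expect_false(any(calls$mode %in% c("translation", "buffering")))
})

test_that("planted modes classify with high sensitivity and low confusion", {
  sim <- simulate_paired_profiles(
    n_genes = 1000,
    mode_config = list(abundance = c(50, 1), translation = c(50, 1),
                       buffering = c(50, 1)),
    noise_sd = 0.25, seed = 55
  )
  calls <- regmode_analysis(sim$total, sim$polysome, sim$samples,
                            contrasts = "20v3")
  truth <- truth_modes(sim$truth, "20v3")
  nz <- truth != "none"
  sens <- mean(calls$mode[nz] == truth[nz])
  called <- calls$mode != "none"
  prec <- mean(truth[called] == calls$mode[called])
  expect_gte(sens, 0.9)
  expect_gte(prec, 0.9)
  # translation <-> buffering confusion <= 5%
  tb <- truth == "translation" & calls$mode == "buffering"
  bt <- truth == "buffering" & calls$mode == "translation"
  expect_lte(mean(tb[truth == "translation"]), 0.05)
  expect_lte(mean(bt[truth == "buffering"]), 0.05)
})

test_that("all-zero effects give mode none everywhere", {
  sim <- simulate_paired_profiles(n_genes = 200, mode_config = list(),
                                  seed = 56)
  calls <- regmode_analysis(sim$total, sim$polysome, sim$samples,
                            contrasts = "20v3", alpha = 0.001)
  expect_true(mean(calls$mode == "none") > 0.99)
})

test_that("mode summaries tally calls and flag multi-mode genes", {
  calls <- data.frame(
    gene = c("g1", "g1", "g2", "g3"),
    contrast = c("6v3", "20v12", "6v3", "6v3"),
    mode = c("translation", "buffering", "abundance", "none")
  )
  sm <- summarize_modes(calls)
  expect_identical(sm$multi_mode_genes, "g1")
  expect_equal(sm$overall[["abundance"]], 1)
  got <- sm$counts$n_genes[sm$counts$contrast == "6v3" &
                             sm$counts$mode == "translation"]
  expect_equal(got, 1)
  empty <- summarize_modes(calls[0, ])
  expect_length(empty$multi_mode_genes, 0)
})
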