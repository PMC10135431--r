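test_that("count simulation is seeded-deterministic with recorded truth", {
  d <- study_design(c("3" = 2, "20" = 2))
  s1 <- simulate_experiment(d, n_genes = 100,
                            mode_config = list(translation = c(10, 1)),
                            seed = 7)
  s2 <- simulate_experiment(d, n_genes = 100,
                            mode_config = list(translation = c(10, 1)),
                            seed = 7)
  expect_identical(s1$experiment$counts, s2$experiment$counts)
  tr <- s1$truth[s1$truth$mode == "translation", ]
  # translation genes: no planted change except at the oldest age
  expect_true(all(tr$offset_3 == 0))
  expect_true(all(abs(tr$offset_20) == 1))
  expect_true(all(s1$truth$offset_20[s1$truth$mode == "none"] == 0))
  expect_error(simulate_experiment(study_design(), n_genes = 5,
                                   mode_config = list(abundance = c(10, 1))),
               "exceed")
})

test_that("simulated counts follow the negative-binomial moment relation", {
  # one gene, many samples at fixed mean: var ~ mu + phi mu^2
  d <- study_design(c("3" = 2, "6" = 2))
  withr::with_seed(31, {
    mu <- 500; phi <- 0.1
    draws <- rnbinom(2e4, mu = mu, size = 1 / phi)
  })
  expect_equal(mean(draws), mu, tolerance = 0.02)
  expect_equal(var(draws), mu + phi * mu^2, tolerance = 0.05)
  # and the generator's per-gene dispersions scatter around the target
  sim <- simulate_experiment(d, n_genes = 2000, seed = 32, dispersion = 0.1)
  cpm <- compute_cpm(sim$experiment$counts)
  expect_true(all(sim$experiment$counts >= 0))
})

test_that("planted outlier samples are flagged by the correlation rule", {
  d <- study_design()
  out_id <- d$samples$sample_id[d$samples$fraction == "polysome"][3]
  sim <- simulate_experiment(d, n_genes = 800, outlier_samples = out_id,
                             seed = 33)
  norm <- normalize_experiment(sim$experiment)
  qc <- detect_outliers(
    cbind(norm$log2cpm$total, norm$log2cpm$polysome),
    c(rep("total", ncol(norm$log2cpm$total)),
      rep("polysome", ncol(norm$log2cpm$polysome)))
  )
  expect_true(qc$flagged[qc$sample_id == out_id])
  expect_lte(sum(qc$flagged), 2)
})

test_that("a clean simulation rarely triggers the outlier rule", {
  # under the 1.5 IQR rule false flags are possible but must stay rare
  flags <- vapply(1:5, function(i) {
    sim <- simulate_experiment(study_design(), n_genes = 400,
                               batch_effect_sd = 0, seed = 100 + i)
    norm <- normalize_experiment(sim$experiment)
    qc <- detect_outliers(
      cbind(norm$log2cpm$total, norm$log2cpm$polysome),
      c(rep("total", ncol(norm$log2cpm$total)),
        rep("polysome", ncol(norm$log2cpm$polysome)))
    )
    sum(qc$flagged)
  }, numeric(1))
  expect_lte(mean(flags), 1)
})

test_that("noiseless TPM simulation round-trips planted PSI exactly", {
  d <- study_design(c("3" = 2, "20" = 2))
  ann <- build_toy_annotation(1, 1, seed = 1)
  ev <- enumerate_events(ann)
  psi_truth <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    data.frame(event_id = ev$event_id[i], age_months = c(3, 20), psi = 0.75)
  }))
  tq <- simulate_transcript_tpm(ann, d, psi_truth, NULL, noise_sd = 0, seed = 2)
  psi <- compute_psi(tq$events, tq$tpm)
  expect_true(all(abs(psi - 0.75) < 1e-12))
  # per-sample TPM totals are constant at 1e6
  expect_equal(unname(colSums(tq$tpm)), rep(1e6, ncol(tq$tpm)),
               tolerance = 1e-6)
  # planted PSI 0 silences inclusion transcripts entirely
  psi0 <- psi_truth; psi0$psi <- 0
  tq0 <- simulate_transcript_tpm(ann, d, psi0, NULL, noise_sd = 0, seed = 2)
  se <- ev[ev$gene_id == "gSE1", ]
  expect_true(all(tq0$tpm[strsplit(se$inclusion, ",")[[1]], ] == 0))
  # invalid planted values are rejected
  bad <- psi_truth; bad$psi[1] <- 1.2
  expect_error(simulate_transcript_tpm(ann, d, bad, NULL), "outside")
})

test_that("recovered PSI under noise satisfies the CLT bound", {
  d <- study_design(c("3" = 6, "20" = 6))
  ann <- build_toy_annotation(1, 1, seed = 1)
  ev <- enumerate_events(ann)
  psi_truth <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    data.frame(event_id = ev$event_id[i], age_months = c(3, 20), psi = 0.5)
  }))
  tq <- simulate_transcript_tpm(ann, d, psi_truth, NULL, noise_sd = 0.05,
                                seed = 3)
  smp <- d$samples
  tot <- smp$sample_id[smp$fraction == "total"]
  psi <- compute_psi(tq$events, tq$tpm[, tot])
  grp3 <- tot[smp$age_months[match(tot, smp$sample_id)] == 3]
  # mean recovered PSI within 3 * (noise_sd / sqrt(6)) of truth
  dev <- abs(rowMeans(psi[, grp3]) - 0.5)
  expect_true(all(dev <= 3 * 0.05 / sqrt(6)))
})

test_that("paired-profile generator plants fraction-specific offsets", {
  sim <- simulate_paired_profiles(
    n_genes = 300,
    mode_config = list(translation = c(20, 1), buffering = c(20, 1)),
    noise_sd = 0.01, coupling = 0.5, seed = 41
  )
  smp <- sim$samples
  old_t <- smp$sample_id[smp$fraction == "total" & smp$age_months == 20]
  young_t <- smp$sample_id[smp$fraction == "total" & smp$age_months == 3]
  dt <- rowMeans(sim$total[, old_t]) - rowMeans(sim$total[, young_t])
  tr <- sim$truth$mode == "translation"
  bf <- sim$truth$mode == "buffering"
  # translation genes move only in the polysome fraction
  expect_lt(max(abs(dt[tr])), 0.5)
  expect_gt(min(abs(dt[bf])), 0.5)
})
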