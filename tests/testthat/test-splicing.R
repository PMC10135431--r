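test_that("each template gene yields exactly its planted event type", {
  ann <- build_toy_annotation(2, 1, seed = 1)
  ev <- enumerate_events(ann)
  types <- attr(ann, "event_type")
  for (g in unique(ev$gene_id)) {
    expect_identical(unique(ev$type[ev$gene_id == g]), unname(types[g]))
    expect_equal(sum(ev$gene_id == g), 1)
  }
  # APA genes carry no splicing event
  expect_false(any(grepl("^gAPA", ev$gene_id)))
  # canonical SE event: inclusion is the three-exon form
  se <- ev[ev$gene_id == "gSE1", ]
  expect_identical(se$inclusion, "gSE1.t1")
  expect_identical(se$exclusion, "gSE1.t2")
})

test_that("single-transcript genes produce no events", {
  ann <- build_toy_annotation(1, 1, seed = 1)
  solo <- ann[ann$transcript_id == "gSE1.t1", ]
  class(solo) <- c("toy_annotation", "data.frame")
  expect_equal(nrow(enumerate_events(solo)), 0)
})

test_that("event typing is strand-consistent under reflection", {
  ann <- build_toy_annotation(3, 1, seed = 4)
  ev <- enumerate_events(ann)
  # reflect + flip = the same molecule: types preserved
  same <- enumerate_events(reflect_annotation(ann, flip_strand = TRUE))
  expect_identical(sort(paste(same$gene_id, same$type)),
                   sort(paste(ev$gene_id, ev$type)))
  # reflect only: donor/acceptor and first/last sides swap
  swap <- enumerate_events(reflect_annotation(ann, flip_strand = FALSE))
  map <- c(SE = "SE", RI = "RI", MX = "MX", A5 = "A3", A3 = "A5",
           AF = "AL", AL = "AF")
  expect_identical(sort(paste(swap$gene_id, swap$type)),
                   sort(paste(ev$gene_id, unname(map[ev$type]))))
})

test_that("a minus-strand A5 construction is typed A5, not A3", {
  ann <- build_toy_annotation(2, 1, seed = 1)
  ev <- enumerate_events(ann)
  # strands alternate across genes; pick the minus-strand A5 gene
  a5_genes <- unique(ev$gene_id[ev$type == "A5"])
  minus <- ev[ev$gene_id %in% a5_genes & ev$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_identical(minus$type, "A5")
})

test_that("PSI equals the inclusion share with a floor for missingness", {
  ann <- build_toy_annotation(1, 1, seed = 1)
  ev <- enumerate_events(ann)
  se <- ev[ev$gene_id == "gSE1", , drop = FALSE]
  tpm <- matrix(0, 2, 3, dimnames = list(c("gSE1.t1", "gSE1.t2"),
                                         c("s1", "s2", "s3")))
  tpm[, 1] <- c(3, 1)     # 3 TPM inclusion vs 1 exclusion -> 0.75
  tpm[, 2] <- c(0, 0)     # below floor -> missing
  tpm[, 3] <- c(0.2, 0.2) # denominator 0.4 < 1 -> missing
  psi <- compute_psi(se, tpm)
  expect_equal(unname(psi[1, ]), c(0.75, NA, NA))
  # complement symmetry: swapping inclusion and exclusion gives 1 - PSI
  swapped <- se
  swapped$inclusion <- se$exclusion
  swapped$exclusion <- se$inclusion
  withr::with_seed(7, tpm2 <- matrix(runif(2 * 5, 1, 10), 2,
                                     dimnames = list(rownames(tpm), paste0("r", 1:5))))
  expect_equal(compute_psi(swapped, tpm2), 1 - compute_psi(se, tpm2))
  # brute-force ratio oracle
  expect_equal(unname(compute_psi(se, tpm2)[1, ]),
               unname(tpm2[1, ] / colSums(tpm2)))
})

test_that("planted dPSI shifts are detected and identical PSI gives p = 1", {
  d <- study_design()
  ann <- build_toy_annotation(6, 1, seed = 2)
  ev <- enumerate_events(ann)
  ages <- d$ages
  shift <- seq_len(nrow(ev)) %% 2 == 0
  psi_truth <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    data.frame(event_id = ev$event_id[i], age_months = ages,
               psi = if (shift[i]) c(0.3, 0.3, 0.3, 0.7) else rep(0.5, 4))
  }))
  tq <- simulate_transcript_tpm(ann, d, psi_truth, NULL, noise_sd = 0.08,
                                seed = 3)
  smp <- d$samples
  tot <- smp$sample_id[smp$fraction == "total"]
  psi <- compute_psi(tq$events, tq$tpm[, tot])
  groups <- smp$age_months[match(tot, smp$sample_id)]
  res <- test_dpsi(psi, tq$tpm[, tot], tq$events, groups, contrasts = "20v3")
  shifted_ids <- ev$event_id[shift]
  expect_true(all(res$significant[res$event_id %in% shifted_ids]))
  expect_true(all(abs(res$dpsi[res$event_id %in% shifted_ids] - 0.4) < 0.1))
  # identical PSI across samples -> dPSI 0, p 1
  flat <- matrix(0.6, nrow(ev), length(tot),
                 dimnames = list(ev$event_id, tot))
  res0 <- test_dpsi(flat, tq$tpm[, tot], ev, groups, contrasts = "20v3")
  expect_true(all(res0$dpsi == 0))
  expect_true(all(res0$p == 1))
})

test_that("hypergeometric overlap matches enumeration and the printed margins", {
  # exhaustive oracle on a small universe: fix set A, enumerate all B subsets
  n_a <- 5; n_b <- 4; universe <- 20
  all_b <- combn(universe, n_b)
  overlap_counts <- colSums(all_b <= n_a)  # A = items 1..5
  for (k in 1:4) {
    want <- mean(overlap_counts >= k)
    got <- overlap_test(n_a, n_b, k, universe)$p
    expect_equal(got, want, tolerance = 1e-12)
  }
  # forced total overlap is certain
  expect_equal(overlap_test(10, 10, 10, 10)$p, 1)
  # the study-scale AS overlap: order of magnitude 1e-256
  big <- overlap_test(883, 835, 244, 65311)
  expect_lt(big$log10_p, -250)
  expect_gt(big$log10_p, -265)
  expect_error(overlap_test(5, 4, 5, 20), ".")
})

test_that("the chi-square trend statistic matches its closed form", {
  eq <- trend_test(c(25, 25, 25, 25))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  tt <- trend_test(c(10, 30))
  expect_equal(tt$statistic, 10)
  expect_equal(tt$p, 0.001565402, tolerance = 1e-6)
  withr::with_seed(9, counts <- rpois(6, 40))
  got <- trend_test(counts)
  expect_equal(got$statistic, sum((counts - mean(counts))^2 / mean(counts)))
  expect_error(trend_test(c(0, 0)), "all-zero")
})
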