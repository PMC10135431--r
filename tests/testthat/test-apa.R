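plus_tx <- function(exons, tid = "t1", gid = "g1", strand = "+") {
  ann <- data.frame(gene_id = gid, transcript_id = tid, seqnames = "chr1",
                    start = exons[, 1], end = exons[, 2], strand = strand)
  class(ann) <- c("toy_annotation", "data.frame")
  ann
}

test_that("terminal fragments are the strand-aware final two exons", {
  ex <- rbind(c(100, 200), c(300, 400), c(500, 600))
  plus <- terminal_fragments(plus_tx(ex))
  expect_equal(plus$frag_start, 300)
  expect_equal(plus$frag_end, 600)
  expect_equal(plus$end3, 600)
  minus <- terminal_fragments(plus_tx(ex, strand = "-"))
  expect_equal(minus$frag_start, 100)
  expect_equal(minus$frag_end, 400)
  expect_equal(minus$end3, 100)
  mono <- terminal_fragments(plus_tx(rbind(c(100, 200))))
  expect_equal(mono$frag_start, 100)
  expect_equal(mono$end3, 200)
  mono_m <- terminal_fragments(plus_tx(rbind(c(100, 200)), strand = "-"))
  expect_equal(mono_m$end3, 100)
})

mk_frags <- function(ends, strand = "+", gid = "g1") {
  data.frame(transcript_id = paste0("t", seq_along(ends)), gene_id = gid,
             strand = strand, frag_start = ends - 50, frag_end = ends,
             end3 = ends)
}

test_that("3' ends group by inclusive single-linkage within 25 nt", {
  one <- group_apa_sites(mk_frags(c(1000, 1020)))
  expect_equal(nrow(one), 1)
  two <- group_apa_sites(mk_frags(c(1000, 1030)))
  expect_equal(two$weight, c(0, 1))
  chain <- group_apa_sites(mk_frags(c(1000, 1020, 1040)))
  expect_equal(nrow(chain), 1)  # chained through the middle end
  boundary <- group_apa_sites(mk_frags(c(1000, 1025)))
  expect_equal(nrow(boundary), 1)  # delta = 25 counts as within
  # idempotent: regrouping the site 3' ends changes nothing
  regroup <- group_apa_sites(mk_frags(two$end3))
  expect_equal(regroup$end3, two$end3)
  expect_equal(regroup$weight, two$weight)
})

test_that("site order follows transcription direction", {
  plus <- group_apa_sites(mk_frags(c(1000, 1100)))
  expect_equal(plus$end3[plus$weight == 0], 1000)  # proximal = low coord on +
  minus <- group_apa_sites(mk_frags(c(1000, 1100), strand = "-"))
  expect_equal(minus$end3[minus$weight == 0], 1100) # proximal = high coord on -
})

test_that("gene psi spans 0 (proximal) to 1 (distal) and scales invariantly", {
  sites <- group_apa_sites(mk_frags(c(1000, 1100)))
  tpm <- matrix(c(10, 0, 0, 10, 5, 5), 2,
                dimnames = list(c("t1", "t2"), c("prox", "dist", "even")))
  psi <- compute_gene_psi(sites, tpm)
  expect_equal(unname(psi["g1", ]), c(0, 1, 0.5))
  expect_equal(compute_gene_psi(sites, tpm * 7), psi)
  # reversed strand maps psi -> 1 - psi for a two-site gene
  sites_m <- group_apa_sites(mk_frags(c(1000, 1100), strand = "-"))
  psi_m <- compute_gene_psi(sites_m, tpm)
  expect_equal(unname(psi_m["g1", ]), 1 - unname(psi["g1", ]))
  # expression floor: totals below 1 TPM are missing
  expect_true(is.na(compute_gene_psi(sites, tpm / 100)["g1", 3]))
  # single-site genes are excluded from testing
  single <- group_apa_sites(mk_frags(c(1000, 1010)))
  expect_equal(nrow(compute_gene_psi(single, tpm)), 0)
})

test_that("Welch test flags a planted psi shift and handles degeneracy", {
  withr::with_seed(61, {
    psi <- rbind(
      shift = c(rnorm(5, 0.25, 0.05), rnorm(5, 0.75, 0.05)),
      null = rnorm(10, 0.5, 0.05)
    )
    colnames(psi) <- paste0("s", 1:10)
  })
  groups <- rep(c(3, 20), each = 5)
  res <- test_apa(psi, groups, contrasts = "20v3")
  expect_true(res$significant[res$gene_id == "shift"])
  expect_gt(res$dpsi[res$gene_id == "shift"], 0.3)
  # identical vectors: dpsi 0; zero variance limits
  flat <- rbind(a = rep(0.5, 10), b = rep(c(0.2, 0.8), each = 5))
  res2 <- test_apa(flat, groups, contrasts = "20v3")
  expect_equal(res2$dpsi[res2$gene_id == "a"], 0)
  expect_equal(res2$p[res2$gene_id == "a"], 1)
  expect_equal(res2$p[res2$gene_id == "b"], 0)
  expect_equal(res2$dpsi[res2$gene_id == "b"], 0.6)
})

test_that("Welch test type-I error is near nominal on null psi", {
  withr::with_seed(62, {
    psi <- matrix(rnorm(2000 * 10, 0.5, 0.05), 2000,
                  dimnames = list(sprintf("g%d", 1:2000), paste0("s", 1:10)))
  })
  res <- test_apa(psi, rep(c(3, 20), each = 5), contrasts = "20v3")
  rate <- mean(res$p < 0.05)
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / 2000)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})
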