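# Enumerate splicing events from the GTF, quantify PSI per fraction, test
# dPSI across the age contrasts, and compute the transcriptome/translatome
# overlap (Fisher) and the age trend (chi-square) of event counts.

source("analysis/00_common.R")

ann <- read_gtf(file.path(RESULTS, "data/annotation.gtf"))
tpm <- read_matrix(file.path(RESULTS, "data/tpm.tsv"), "transcript_id")
samples <- read_tsv_meta(file.path(RESULTS, "data/samples.tsv"))

events <- enumerate_events(ann)
write_tsv_meta(events, file.path(RESULTS, "splicing/events.tsv"))
message(sprintf("%d events: %s", nrow(events),
                paste(names(table(events$type)), table(events$type),
                      sep = "=", collapse = " ")))

sig_sets <- list()
for (fr in c("total", "polysome")) {
  cols <- samples$sample_id[samples$fraction == fr]
  psi <- compute_psi(events, tpm[, cols], floor = 1.0)
  groups <- samples$age_months[match(cols, samples$sample_id)]
  res <- test_dpsi(psi, tpm[, cols], events, groups)
  write_tsv_meta(polysomics:::matrix_to_df(psi, "event_id"),
                 file.path(RESULTS, sprintf("splicing/psi_%s.tsv", fr)))
  write_tsv_meta(res, file.path(RESULTS, sprintf("splicing/dpsi_%s.tsv", fr)),
                 list(alpha = 0.05))
  sig_sets[[fr]] <- unique(res$event_id[res$significant])
  message(sprintf("%s: %d significant event/contrast pairs (%d events)",
                  fr, sum(res$significant, na.rm = TRUE),
                  length(sig_sets[[fr]])))
  # age trend of significant events across ordered "neighbour" comparisons
  ordered_cts <- c("6v3", "12v6", "20v12")
  counts <- vapply(ordered_cts, function(ct)
    sum(res$significant[res$contrast == ct], na.rm = TRUE), numeric(1))
  if (sum(counts) > 0) {
    tr <- trend_test(counts)
    message(sprintf("  trend across %s: counts %s, chi2 = %.2f, p = %.3g",
                    paste(ordered_cts, collapse = "/"),
                    paste(counts, collapse = "/"), tr$statistic, tr$p))
  }
}

both <- length(intersect(sig_sets$total, sig_sets$polysome))
ot <- overlap_test(length(sig_sets$total), length(sig_sets$polysome),
                   both, nrow(events))
message(sprintf(
  "overlap: %d total-RNA vs %d polysome events share %d (expected %.2f), p = %.3g",
  length(sig_sets$total), length(sig_sets$polysome), both, ot$expected, ot$p))
write_tsv_meta(
  data.frame(n_total = length(sig_sets$total),
             n_polysome = length(sig_sets$polysome),
             n_both = both, universe = nrow(events),
             expected = ot$expected, p = ot$p, log10_p = ot$log10_p),
  file.path(RESULTS, "splicing/overlap_test.tsv")
)
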