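# Filter, normalize and QC the simulated experiment: library-size-derived
# CPM filter, TMM + log2 CPM per fraction, correlation-IQR outlier
# detection, batch adjustment, PCA.

source("analysis/00_common.R")

counts <- read_matrix(file.path(RESULTS, "data/counts.tsv"))
samples <- read_tsv_meta(file.path(RESULTS, "data/samples.tsv"))
exp <- count_experiment(counts, samples)

norm <- normalize_experiment(exp, min_samples = 4)
message(sprintf("filter threshold N = %.3f CPM; %d of %d genes kept",
                norm$threshold, length(norm$genes), nrow(counts)))

qc <- detect_outliers(
  cbind(norm$log2cpm$total, norm$log2cpm$polysome),
  c(rep("total", ncol(norm$log2cpm$total)),
    rep("polysome", ncol(norm$log2cpm$polysome)))
)
message(sprintf("outlier flags: %d (%s)", sum(qc$flagged),
                paste(qc$sample_id[qc$flagged], collapse = ", ")))

for (fr in c("total", "polysome")) {
  cols <- samples[match(colnames(norm$log2cpm[[fr]]), samples$sample_id), ]
  adj <- batch_adjust(norm$log2cpm[[fr]], cols$batch, cols$age_months)
  write_tsv_meta(polysomics:::matrix_to_df(adj),
                 file.path(RESULTS, sprintf("preprocess/log2cpm_%s.tsv", fr)),
                 list(filter_threshold = norm$threshold, batch_adjusted = TRUE))
}
write_tsv_meta(qc, file.path(RESULTS, "preprocess/qc_samples.tsv"))

adj_t <- read_matrix(file.path(RESULTS, "preprocess/log2cpm_total.tsv"))
adj_p <- read_matrix(file.path(RESULTS, "preprocess/log2cpm_polysome.tsv"))
pc <- pca_samples(cbind(adj_t, adj_p))
write_tsv_meta(polysomics:::matrix_to_df(pc$scores[, 1:4], "sample_id"),
               file.path(RESULTS, "preprocess/pca_scores.tsv"),
               list(var_explained = paste(round(pc$var_explained[1:4], 3),
                                          collapse = ",")))
message(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * pc$var_explained[1], 100 * pc$var_explained[2]))
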