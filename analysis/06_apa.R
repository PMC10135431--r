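# Alternative polyadenylation: terminal fragments, grouped 3' end sites,
# positional psi per gene, Welch tests across age contrasts.

source("analysis/00_common.R")

ann <- read_gtf(file.path(RESULTS, "data/annotation.gtf"))
tpm <- read_matrix(file.path(RESULTS, "data/tpm.tsv"), "transcript_id")
samples <- read_tsv_meta(file.path(RESULTS, "data/samples.tsv"))
truth <- read_tsv_meta(file.path(RESULTS, "data/truth_apa.tsv"))

sites <- group_apa_sites(terminal_fragments(ann), window = 25)
write_tsv_meta(sites, file.path(RESULTS, "apa/sites.tsv"), list(window = 25))
message(sprintf("%d genes with >= 2 APA sites (of %d genes with fragments)",
                length(unique(sites$gene_id[sites$n_sites >= 2])),
                length(unique(sites$gene_id))))

for (fr in c("total", "polysome")) {
  cols <- samples$sample_id[samples$fraction == fr]
  psi <- compute_gene_psi(sites, tpm[, cols], floor = 1.0)
  res <- test_apa(psi, samples$age_months[match(cols, samples$sample_id)])
  write_tsv_meta(polysomics:::matrix_to_df(psi, "gene_id"),
                 file.path(RESULTS, sprintf("apa/psi_%s.tsv", fr)))
  write_tsv_meta(res, file.path(RESULTS, sprintf("apa/tests_%s.tsv", fr)),
                 list(alpha = 0.05))
  sig <- unique(res$gene_id[res$significant])
  planted <- unique(truth$gene_id[truth$psi != 0.5])
  message(sprintf("%s: %d significant APA genes; planted shifted genes recovered: %d/%d",
                  fr, length(sig), length(intersect(sig, planted)),
                  length(planted)))
}
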