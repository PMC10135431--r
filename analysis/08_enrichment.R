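# Enrichment: hypergeometric ORA of the union DEGs and permutation GSEA on
# the four regulatory axes, against gene sets built from the planted truth
# (written to and read back from a standard GMT file).

source("analysis/00_common.R")

truth <- read_tsv_meta(file.path(RESULTS, "data/truth_modes.tsv"))
degs <- read_tsv_meta(file.path(RESULTS, "de/degs_union.tsv"))$gene
calls <- read_tsv_meta(file.path(RESULTS, "modes/regmode_calls.tsv"))
universe <- unique(calls$gene)

# truth-derived gene sets as a GMT (exercises the standard format);
# directional sets, since a mixed up/down set has no net running-sum signal
gmt_path <- file.path(RESULTS, "enrichment/planted_sets.gmt")
lab <- ifelse(truth$mode == "none", "none",
              paste0(truth$mode, ifelse(truth$effect > 0, "_up", "_down")))
sets <- split(truth$gene, lab)
sets <- sets[setdiff(names(sets), "none")]
writeLines(vapply(names(sets), function(nm) {
  paste(c(paste0("planted_", nm), "planted truth set", sets[[nm]]),
        collapse = "\t")
}, character(1)), gmt_path)
gene_sets <- read_gmt(gmt_path)

ora_res <- ora(intersect(degs, universe), gene_sets, universe)
write_tsv_meta(ora_res, file.path(RESULTS, "enrichment/ora_degs.tsv"))
message(sprintf("ORA of %d DEGs: top set %s (overlap %d, FDR %.2g)",
                length(degs), ora_res$set[1], ora_res$overlap[1],
                ora_res$fdr[1]))

nes_rows <- list()
for (axis in c("totalRNA", "translated", "translation", "buffering")) {
  ranked <- rank_genes(calls, axis, "20v3")
  g <- gsea(ranked, gene_sets, n_perm = 1000,
            seed = polysomics:::child_seed(MASTER_SEED, 8))
  g$axis <- axis
  nes_rows[[axis]] <- g
  message(sprintf("GSEA %s: %s", axis,
                  paste(sprintf("%s NES %.2f (FDR %.2g)", g$set, g$nes, g$fdr),
                        collapse = "; ")))
}
gsea_all <- do.call(rbind, nes_rows)
write_tsv_meta(gsea_all, file.path(RESULTS, "enrichment/gsea_axes_20v3.tsv"),
               list(n_perm = 1000, contrast = "20v3"))
# NES matrix for a dot-plot (sets x axes)
nes_mat <- tapply(gsea_all$nes, list(gsea_all$set, gsea_all$axis), identity)
write_tsv_meta(polysomics:::matrix_to_df(nes_mat, "set"),
               file.path(RESULTS, "enrichment/nes_matrix.tsv"))
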