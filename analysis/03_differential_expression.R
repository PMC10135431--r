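# Moderated differential expression over the six pairwise age contrasts,
# per fraction, with batch in the design; BH q < 0.05 and |FC| > log2(1.2).

source("analysis/00_common.R")

samples <- read_tsv_meta(file.path(RESULTS, "data/samples.tsv"))
union_degs <- character(0)
for (fr in c("total", "polysome")) {
  m <- read_matrix(file.path(RESULTS, sprintf("preprocess/log2cpm_%s.tsv", fr)))
  cols <- samples[match(colnames(m), samples$sample_id), ]
  fit <- fit_gene_models(m, cols$age_months, cols$batch)
  tab <- test_all_contrasts(fit)
  tab$selected <- tab$q < 0.05 & abs(tab$fc) > log2(1.2)
  write_tsv_meta(tab, file.path(RESULTS, sprintf("de/de_%s.tsv", fr)),
                 list(alpha = 0.05, min_abs_fc = log2(1.2)))
  sel <- unique(tab$gene[tab$selected])
  union_degs <- union(union_degs, sel)
  per_ct <- tapply(tab$selected, tab$contrast, sum)
  message(sprintf("%s: %d DEGs in >= 1 contrast (per contrast: %s)",
                  fr, length(sel),
                  paste(names(per_ct), per_ct, sep = "=", collapse = " ")))
}
write_tsv_meta(data.frame(gene = sort(union_degs)),
               file.path(RESULTS, "de/degs_union.tsv"))
message(sprintf("union over fractions: %d DEGs", length(union_degs)))
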