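# Shared settings for the analysis drivers: one master seed, one results
# tree. Each numbered script reads the outputs of the previous ones from
# results/, so the sequence 01 -> 08 reproduces the full analysis.

suppressMessages(library(polysomics))

MASTER_SEED <- 20260101
RESULTS <- "results"
dirs <- file.path(RESULTS, c("data", "preprocess", "de", "modes", "splicing",
                             "apa", "trajectories", "enrichment"))
for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)

read_matrix <- function(path, id = "gene_id") {
  df <- read_tsv_meta(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
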