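# Temporal trajectories of the union DEGs: z-scored 4-point profiles,
# circular-SOM clustering with the cluster count chosen by BIC.

source("analysis/00_common.R")

samples <- read_tsv_meta(file.path(RESULTS, "data/samples.tsv"))
adj_t <- read_matrix(file.path(RESULTS, "preprocess/log2cpm_total.tsv"))
adj_p <- read_matrix(file.path(RESULTS, "preprocess/log2cpm_polysome.tsv"))
degs <- read_tsv_meta(file.path(RESULTS, "de/degs_union.tsv"))$gene
degs <- intersect(degs, rownames(adj_t))
message(sprintf("clustering %d union DEGs (total-RNA profiles)", length(degs)))

ages_of <- function(m) samples$age_months[match(colnames(m), samples$sample_id)]
prof_t <- temporal_profiles(adj_t[degs, , drop = FALSE], ages_of(adj_t))
sel <- select_k_bic(prof_t$z, k_range = 2:8,
                    seed = polysomics:::child_seed(MASTER_SEED, 7))
message(sprintf("BIC selects k* = %d (BIC by k: %s)", sel$k_star,
                paste(sel$bic$k, round(sel$bic$bic), sep = ":", collapse = " ")))

write_tsv_meta(
  data.frame(gene = names(sel$model$assignment),
             cluster = sel$model$assignment,
             similarity_to_node = sel$model$similarity),
  file.path(RESULTS, "trajectories/clusters.tsv"), list(k_star = sel$k_star)
)
write_tsv_meta(sel$bic, file.path(RESULTS, "trajectories/bic.tsv"))
write_tsv_meta(polysomics:::matrix_to_df(
  cluster_mean_profiles(sel$model, prof_t$z), "cluster"),
  file.path(RESULTS, "trajectories/cluster_mean_profiles_total.tsv"))

# project the same genes onto translatome profiles (paired heatmap layout)
prof_p <- temporal_profiles(adj_p[rownames(prof_t$z), , drop = FALSE],
                            ages_of(adj_p))
proj <- prof_p$z[intersect(rownames(prof_t$z), rownames(prof_p$z)), ,
                 drop = FALSE]
write_tsv_meta(polysomics:::matrix_to_df(proj, "gene"),
               file.path(RESULTS, "trajectories/profiles_polysome.tsv"))
# ring order for heatmap display: genes sorted by node, then similarity
ord <- order(sel$model$assignment, -sel$model$similarity)
write_tsv_meta(data.frame(gene = names(sel$model$assignment)[ord]),
               file.path(RESULTS, "trajectories/heatmap_order.tsv"))
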