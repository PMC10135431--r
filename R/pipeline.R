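## End-to-end pipeline driver.
##
## Orchestrates simulate -> preprocess -> differential expression (both
## fractions) -> regulatory modes -> splicing -> APA -> trajectories ->
## enrichment on a synthetic experiment, writing every stage output as TSV
## with parameter-echo headers plus a checksum manifest. Deterministic
## given `seed`: reruns are byte-identical.

pipeline_defaults <- function() {
  list(
    n_genes = 600,
    mode_counts = c(abundance = 40, translation = 40, buffering = 40),
    effect = 1,
    dispersion = 0.05,
    batch_effect_sd = 0.3,
    n_event_genes_per_type = 2,
    n_apa_genes = 3,
    dpsi_effect = 0.3,
    apa_effect = 0.3,
    tpm_noise_sd = 0.05,
    alpha = 0.05,
    min_abs_fc = log2(1.2),
    min_samples = 4,
    apa_window = 25,
    tpm_floor = 1.0,
    k_range = 2:6,
    n_perm = 200
  )
}

#' Run the full synthetic-data analysis pipeline
#'
#' @param outdir output directory (created if missing).
#' @param seed master seed; every stage derives a child seed from it.
#' @param config named list overriding entries of the default configuration
#'   (gene counts, planted effect sizes, thresholds; see
#'   `polysomics:::pipeline_defaults()`).
#' @return invisibly, a list with `manifest` (stage, file, md5 checksum) and
#'   the per-stage result objects.
#' @export
run_pipeline <- function(outdir, seed = 1, config = list()) {
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- character(0)
  stage_of <- character(0)
  emit <- function(stage, name, df, meta = list()) {
    path <- file.path(outdir, name)
    write_tsv_meta(df, path, c(list(stage = stage, seed = seed), meta))
    files <<- c(files, path)
    stage_of <<- c(stage_of, stage)
    path
  }
  log_stage <- function(stage, what) {
    message(sprintf("[%s] %s (%.1fs elapsed)", stage, what,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }

  ## stage 1: simulate ------------------------------------------------------
  design <- study_design()
  sim <- simulate_experiment(
    design, n_genes = cfg$n_genes,
    mode_config = lapply(cfg$mode_counts, function(n) c(n, cfg$effect)),
    dispersion = cfg$dispersion, batch_effect_sd = cfg$batch_effect_sd,
    seed = child_seed(seed, 1)
  )
  ann <- build_toy_annotation(cfg$n_event_genes_per_type, cfg$n_apa_genes,
                              seed = child_seed(seed, 2))
  events <- enumerate_events(ann)
  ages <- design$ages
  psi_truth <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    lo <- 0.5 - cfg$dpsi_effect / 2
    hi <- 0.5 + cfg$dpsi_effect / 2
    shift <- i %% 2 == 0  # half the events shift at the oldest age
    data.frame(event_id = events$event_id[i], age_months = ages,
               psi = if (shift) c(lo, lo, lo, hi) else rep(0.5, length(ages)))
  }))
  sites <- group_apa_sites(terminal_fragments(ann), window = cfg$apa_window)
  apa_genes <- unique(sites$gene_id[sites$n_sites >= 2])
  apa_truth <- do.call(rbind, lapply(seq_along(apa_genes), function(i) {
    lo <- 0.5 - cfg$apa_effect / 2
    hi <- 0.5 + cfg$apa_effect / 2
    shift <- i %% 2 == 1
    data.frame(gene_id = apa_genes[i], age_months = ages,
               psi = if (shift) c(lo, lo, lo, hi) else rep(0.5, length(ages)))
  }))
  tq <- simulate_transcript_tpm(ann, design, psi_truth, apa_truth,
                                noise_sd = cfg$tpm_noise_sd,
                                seed = child_seed(seed, 3))
  emit("simulate", "counts.tsv", matrix_to_df(sim$experiment$counts))
  emit("simulate", "samples.tsv", sim$experiment$samples)
  emit("simulate", "truth_modes.tsv", sim$truth)
  emit("simulate", "tpm.tsv", matrix_to_df(tq$tpm, "transcript_id"))
  emit("simulate", "truth_psi.tsv", psi_truth)
  emit("simulate", "truth_apa.tsv", apa_truth)
  gtf_path <- file.path(outdir, "annotation.gtf")
  write_gtf(ann, gtf_path)
  files <- c(files, gtf_path); stage_of <- c(stage_of, "simulate")
  log_stage("simulate", sprintf("%d genes, %d events, %d APA genes",
                                cfg$n_genes, nrow(events), length(apa_genes)))

  ## stage 2: preprocess ----------------------------------------------------
  norm <- normalize_experiment(sim$experiment, min_samples = cfg$min_samples)
  smp <- sim$experiment$samples
  qc <- detect_outliers(
    cbind(norm$log2cpm$total, norm$log2cpm$polysome),
    c(rep("total", ncol(norm$log2cpm$total)),
      rep("polysome", ncol(norm$log2cpm$polysome)))
  )
  adj <- lapply(c("total", "polysome"), function(fr) {
    cols <- smp[match(colnames(norm$log2cpm[[fr]]), smp$sample_id), ]
    batch_adjust(norm$log2cpm[[fr]], cols$batch, cols$age_months)
  })
  names(adj) <- c("total", "polysome")
  pc <- pca_samples(cbind(adj$total, adj$polysome))
  emit("preprocess", "log2cpm_total.tsv", matrix_to_df(adj$total),
       list(filter_threshold = norm$threshold))
  emit("preprocess", "log2cpm_polysome.tsv", matrix_to_df(adj$polysome),
       list(filter_threshold = norm$threshold))
  emit("preprocess", "qc_samples.tsv", qc)
  emit("preprocess", "pca_scores.tsv",
       matrix_to_df(pc$scores[, 1:4, drop = FALSE], "sample_id"))
  log_stage("preprocess", sprintf("%d genes kept (N = %.3f CPM), %d outlier flags",
                                  length(norm$genes), norm$threshold,
                                  sum(qc$flagged)))

  ## stage 3: differential expression ---------------------------------------
  de <- lapply(c("total", "polysome"), function(fr) {
    cols <- smp[match(colnames(adj[[fr]]), smp$sample_id), ]
    fit <- fit_gene_models(adj[[fr]], cols$age_months, cols$batch)
    test_all_contrasts(fit)
  })
  names(de) <- c("total", "polysome")
  for (fr in names(de)) {
    tab <- de[[fr]]
    tab$selected <- tab$q < cfg$alpha & abs(tab$fc) > cfg$min_abs_fc
    emit("de", sprintf("de_%s.tsv", fr), tab,
         list(alpha = cfg$alpha, min_abs_fc = cfg$min_abs_fc))
  }
  union_degs <- sort(unique(unlist(lapply(de, function(tab) {
    select_degs(tab, cfg$alpha, cfg$min_abs_fc)$gene
  }))))
  emit("de", "degs_union.tsv", data.frame(gene = union_degs))
  log_stage("de", sprintf("%d union DEGs over %d contrasts",
                          length(union_degs), length(unique(de$total$contrast))))

  ## stage 4: regulatory modes ----------------------------------------------
  calls <- regmode_analysis(adj$total, adj$polysome, smp,
                            alpha = cfg$alpha, min_eff = cfg$min_abs_fc)
  modes_summary <- summarize_modes(calls)
  emit("modes", "regmode_calls.tsv", calls,
       list(alpha = cfg$alpha, min_eff = cfg$min_abs_fc))
  emit("modes", "regmode_counts.tsv", modes_summary$counts)
  log_stage("modes", sprintf("%d non-none calls, %d multi-mode genes",
                             sum(calls$mode != "none"),
                             length(modes_summary$multi_mode_genes)))

  ## stage 5: splicing ------------------------------------------------------
  psi <- compute_psi(events, tq$tpm, floor = cfg$tpm_floor)
  groups <- smp$age_months[match(colnames(psi), smp$sample_id)]
  dpsi <- test_dpsi(psi, tq$tpm, events, groups, alpha = cfg$alpha)
  emit("splice", "events.tsv", events)
  emit("splice", "psi.tsv", matrix_to_df(psi, "event_id"))
  emit("splice", "dpsi.tsv", dpsi, list(alpha = cfg$alpha))
  log_stage("splice", sprintf("%d events, %d significant event/contrast pairs",
                              nrow(events), sum(dpsi$significant, na.rm = TRUE)))

  ## stage 6: APA -----------------------------------------------------------
  gpsi <- compute_gene_psi(sites, tq$tpm, floor = cfg$tpm_floor)
  apa_res <- test_apa(gpsi, smp$age_months[match(colnames(gpsi), smp$sample_id)],
                      alpha = cfg$alpha)
  emit("apa", "apa_sites.tsv", sites, list(window = cfg$apa_window))
  emit("apa", "apa_psi.tsv", matrix_to_df(gpsi, "gene_id"))
  emit("apa", "apa_tests.tsv", apa_res, list(alpha = cfg$alpha))
  log_stage("apa", sprintf("%d testable genes, %d significant pairs",
                           nrow(gpsi), sum(apa_res$significant, na.rm = TRUE)))

  ## stage 7: trajectories --------------------------------------------------
  traj_genes <- if (length(union_degs) >= 12) union_degs else rownames(adj$total)
  prof <- temporal_profiles(adj$total[traj_genes, , drop = FALSE],
                            smp$age_months[match(colnames(adj$total),
                                                 smp$sample_id)])
  sel <- select_k_bic(prof$z, k_range = cfg$k_range,
                      seed = child_seed(seed, 7), ages = ages)
  emit("trajectories", "clusters.tsv",
       data.frame(gene = names(sel$model$assignment),
                  cluster = sel$model$assignment,
                  similarity = sel$model$similarity),
       list(k_star = sel$k_star))
  emit("trajectories", "cluster_bic.tsv", sel$bic)
  emit("trajectories", "node_profiles.tsv",
       matrix_to_df(sel$model$nodes, "node"))
  log_stage("trajectories", sprintf("k* = %d over %d profiles",
                                    sel$k_star, nrow(prof$z)))

  ## stage 8: enrichment ----------------------------------------------------
  truth_sets <- lapply(split(sim$truth$gene, sim$truth$mode), unique)
  truth_sets <- truth_sets[setdiff(names(truth_sets), "none")]
  names(truth_sets) <- paste0("planted_", names(truth_sets))
  universe <- rownames(adj$total)
  enr <- NULL
  if (length(union_degs) >= 1 && length(truth_sets)) {
    ora_res <- ora(intersect(union_degs, universe), truth_sets, universe)
    emit("enrichment", "ora.tsv", ora_res)
    ranked <- rank_genes(calls, "translation",
                         sprintf("%gv%g", max(ages), min(ages)))
    gsea_res <- gsea(ranked, truth_sets, n_perm = cfg$n_perm,
                     seed = child_seed(seed, 8))
    emit("enrichment", "gsea_translation.tsv", gsea_res,
         list(n_perm = cfg$n_perm))
    enr <- list(ora = ora_res, gsea = gsea_res)
    log_stage("enrichment", sprintf("%d ORA sets, %d GSEA sets",
                                    nrow(ora_res), nrow(gsea_res)))
  }

  manifest <- data.frame(
    stage = stage_of, file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("done", sprintf("%d output files", nrow(manifest)))
  invisible(list(manifest = manifest, design = design, truth = sim$truth,
                 norm = norm, de = de, calls = calls, dpsi = dpsi,
                 apa = apa_res, trajectories = sel, enrichment = enr))
}
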