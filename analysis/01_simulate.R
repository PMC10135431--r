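# Simulate the synthetic study: paired total/polysome counts over the
# four-age design with planted regulatory modes, plus a toy annotation with
# planted splicing and APA shifts and matching transcript TPMs.

source("analysis/00_common.R")

design <- study_design()  # 5/6/4/5 subjects at 3/6/12/20 months, paired

# subject_sd 0.4 >> sampling noise: a subject's total and polysome library
# share the extract, so most biological variance is common to them
sim <- simulate_experiment(
  design, n_genes = 2000,
  mode_config = list(abundance = c(80, 1), translation = c(80, 1),
                     buffering = c(80, 1)),
  dispersion = 0.02, batch_effect_sd = 0.3, subject_sd = 0.4,
  seed = polysomics:::child_seed(MASTER_SEED, 1)
)

ann <- build_toy_annotation(8, 6, seed = polysomics:::child_seed(MASTER_SEED, 2))
events <- enumerate_events(ann)
ages <- design$ages

# plant a dPSI = 0.3 shift at the oldest age in half the events
shift <- seq_len(nrow(events)) %% 2 == 0
psi_truth <- data.frame(
  event_id = rep(events$event_id, each = length(ages)),
  age_months = rep(ages, nrow(events)),
  psi = as.vector(t(ifelse(outer(shift, ages == 20, "&"), 0.65,
                           ifelse(outer(shift, rep(TRUE, 4), "&"), 0.35, 0.5))))
)
sites <- group_apa_sites(terminal_fragments(ann))
apa_genes <- unique(sites$gene_id[sites$n_sites >= 2])
apa_shift <- seq_along(apa_genes) %% 2 == 1
apa_truth <- data.frame(
  gene_id = rep(apa_genes, each = length(ages)),
  age_months = rep(ages, length(apa_genes)),
  psi = as.vector(t(ifelse(outer(apa_shift, ages == 20, "&"), 0.65,
                           ifelse(outer(apa_shift, rep(TRUE, 4), "&"), 0.35, 0.5))))
)
tq <- simulate_transcript_tpm(ann, design, psi_truth, apa_truth,
                              noise_sd = 0.05,
                              seed = polysomics:::child_seed(MASTER_SEED, 3))

write_tsv_meta(polysomics:::matrix_to_df(sim$experiment$counts),
               file.path(RESULTS, "data/counts.tsv"),
               list(seed = MASTER_SEED, n_genes = 2000))
write_tsv_meta(sim$experiment$samples, file.path(RESULTS, "data/samples.tsv"))
write_tsv_meta(sim$truth, file.path(RESULTS, "data/truth_modes.tsv"))
write_tsv_meta(polysomics:::matrix_to_df(tq$tpm, "transcript_id"),
               file.path(RESULTS, "data/tpm.tsv"))
write_tsv_meta(psi_truth, file.path(RESULTS, "data/truth_psi.tsv"))
write_tsv_meta(apa_truth, file.path(RESULTS, "data/truth_apa.tsv"))
write_gtf(ann, file.path(RESULTS, "data/annotation.gtf"))

message(sprintf(
  "simulated %d genes x %d libraries; %d splicing events (%d shifted), %d APA genes (%d shifted)",
  nrow(sim$experiment$counts), ncol(sim$experiment$counts),
  nrow(events), sum(shift), length(apa_genes), sum(apa_shift)
))
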