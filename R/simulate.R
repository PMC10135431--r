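## Synthetic data with planted, recoverable ground truth.
##
## Three generators mirror the study design (paired total/polysome libraries
## over four age groups):
##   * simulate_experiment()        -- negative-binomial count matrices with
##     planted regulatory modes, batch structure and optional outliers;
##   * simulate_paired_profiles()   -- Gaussian log2-scale paired matrices
##     with planted modes at a stated noise sd (for calibrated recovery
##     studies on the log scale);
##   * simulate_transcript_tpm()    -- transcript TPM tables realizing
##     planted PSI (splicing) and psi (APA) values over a toy annotation;
##   * simulate_trajectory_profiles() -- z-scored 4-point profiles with
##     planted trajectory shapes.

parse_mode_config <- function(mode_config) {
  modes <- c("abundance", "translation", "buffering")
  cfg <- lapply(mode_config, function(x) {
    stopifnot(length(x) == 2)
    list(n = as.integer(x[[1]]), effect = as.numeric(x[[2]]))
  })
  if (!all(names(cfg) %in% modes)) stop("unknown regulatory mode in mode_config")
  cfg
}

#' Simulate a paired total/polysome count experiment with planted modes
#'
#' Counts are negative binomial with mean
#' `lib_size * frac_g * 2^(age offset + batch offset + subject effect)` and
#' gene-wise dispersions log-normal around `dispersion`. Library sizes are
#' log-normal around 8e6 reads. Mode genes receive a log2 offset of
#' magnitude `effect` (random sign) at the oldest age group: `translation`
#' genes shift polysome means only, `buffering` genes total means only,
#' `abundance` genes both equally. Total and polysome libraries of one
#' subject share the subject-level random effect. Listed outlier samples
#' receive independent per-gene log2 perturbations (sd 2) that depress
#' their inter-sample correlation.
#'
#' @param design a [study_design()] (>= 2 age groups).
#' @param n_genes total genes.
#' @param mode_config named list, mode -> c(count, log2 effect), e.g.
#'   `list(translation = c(50, 1))`. Counts must sum to <= `n_genes`.
#' @param dispersion central NB dispersion (default 0.05).
#' @param base_mean nominal per-gene expression weight (relative; default 10).
#' @param batch_effect_sd sd of per-gene additive log2 batch offsets.
#' @param outlier_samples sample ids to perturb.
#' @param subject_sd sd of the shared subject-level log2 effect (default 0.1).
#' @param seed integer seed.
#' @return list with `experiment` (a [count_experiment()]) and `truth`
#'   (per-gene data frame: `gene`, `mode`, `effect` (signed), trajectory
#'   class and per-age log2 offsets `offset_<age>`).
#' @export
simulate_experiment <- function(design, n_genes = 2000,
                                mode_config = list(),
                                dispersion = 0.05, base_mean = 10,
                                batch_effect_sd = 0,
                                outlier_samples = character(),
                                subject_sd = 0.1, seed = 1) {
  if (length(design$ages) < 2) stop("degenerate design: need >= 2 age groups")
  cfg <- parse_mode_config(mode_config)
  if (sum(vapply(cfg, `[[`, integer(1), "n")) > n_genes) {
    stop("mode counts exceed n_genes")
  }
  smp <- design$samples
  if (!all(outlier_samples %in% smp$sample_id)) stop("unknown outlier sample id")
  ages <- design$ages
  oldest <- as.character(max(ages))

  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    mode <- rep("none", n_genes)
    sgn <- rep(0, n_genes)
    i <- 0L
    for (m in names(cfg)) {
      idx <- i + seq_len(cfg[[m]]$n)
      mode[idx] <- m
      sgn[idx] <- sample(c(-1, 1), cfg[[m]]$n, replace = TRUE) * cfg[[m]]$effect
      i <- i + cfg[[m]]$n
    }
    offsets <- matrix(0, n_genes, length(ages),
                      dimnames = list(genes, as.character(ages)))
    offsets[, oldest] <- sgn

    rel <- stats::rlnorm(n_genes, meanlog = log(base_mean), sdlog = 1)
    frac <- rel / sum(rel)
    phi <- stats::rlnorm(n_genes, meanlog = log(dispersion), sdlog = 0.3)
    lib <- stats::rlnorm(nrow(smp), meanlog = log(8e6), sdlog = 0.2)
    subjects <- unique(smp$subject_id)
    subj_eff <- matrix(stats::rnorm(n_genes * length(subjects), sd = subject_sd),
                       n_genes, dimnames = list(genes, subjects))
    batches <- unique(smp$batch)
    batch_eff <- matrix(stats::rnorm(n_genes * length(batches),
                                     sd = batch_effect_sd),
                        n_genes, dimnames = list(genes, batches))

    counts <- matrix(0L, n_genes, nrow(smp),
                     dimnames = list(genes, smp$sample_id))
    for (s in seq_len(nrow(smp))) {
      age <- as.character(smp$age_months[s])
      o <- offsets[, age]
      # fraction-specific planting: translation -> polysome only,
      # buffering -> total only, abundance -> both
      if (smp$fraction[s] == "total") o[mode == "translation"] <- 0
      if (smp$fraction[s] == "polysome") o[mode == "buffering"] <- 0
      log2_shift <- o + batch_eff[, smp$batch[s]] + subj_eff[, smp$subject_id[s]]
      if (smp$sample_id[s] %in% outlier_samples) {
        log2_shift <- log2_shift + stats::rnorm(n_genes, sd = 2)
      }
      mu <- lib[s] * frac * 2^log2_shift
      counts[, s] <- stats::rnbinom(n_genes, mu = mu, size = 1 / phi)
    }

    truth <- data.frame(gene = genes, mode = mode, effect = sgn,
                        trajectory = ifelse(sgn > 0, "up",
                                            ifelse(sgn < 0, "down", "flat")),
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, as.data.frame(offsets)[, , drop = FALSE])
    names(truth)[-(1:4)] <- paste0("offset_", ages)
    list(experiment = count_experiment(counts, smp), truth = truth)
  })
}

#' Expected regulatory mode per gene for one contrast
#'
#' Reads a simulation truth table: a mode gene carries its mode in a
#' contrast iff its planted offsets differ between the contrast's ages.
#'
#' @param truth truth table from [simulate_experiment()] or
#'   [simulate_paired_profiles()].
#' @param contrast label `"AvB"`.
#' @return character vector of expected modes aligned with `truth$gene`.
#' @export
truth_modes <- function(truth, contrast) {
  ages <- strsplit(contrast, "v", fixed = TRUE)[[1]]
  oa <- truth[[paste0("offset_", ages[1])]]
  ob <- truth[[paste0("offset_", ages[2])]]
  ifelse(truth$mode != "none" & oa != ob, truth$mode, "none")
}

#' Simulate paired log2-scale matrices with planted regulatory modes
#'
#' Gaussian counterpart of [simulate_experiment()] operating directly on the
#' log2 scale, for recovery studies at a stated measurement noise sd. The
#' per-sample variance `noise_sd^2` decomposes into a subject-shared part
#' (`coupling` fraction; both fractions of a subject derive from one tissue
#' extract, so most biological and extraction variance is common to them)
#' and a fraction-specific library part. The shared part makes the APV
#' regression slope identifiable and close to `coupling`.
#'
#' @param design a [study_design()].
#' @param n_genes total genes.
#' @param mode_config named list, mode -> c(count, log2 effect).
#' @param noise_sd total per-sample log2 noise sd (default 0.25).
#' @param coupling fraction of per-sample variance shared between a
#'   subject's two fractions (default 0.85, typical of same-extract
#'   libraries).
#' @param base_level mean log2 expression (default 6).
#' @param seed integer seed.
#' @return list with `total`, `polysome` (gene x sample matrices),
#'   `samples` (sheet) and `truth` (as in [simulate_experiment()]).
#' @export
simulate_paired_profiles <- function(design = study_design(), n_genes = 1000,
                                     mode_config = list(), noise_sd = 0.25,
                                     coupling = 0.85, base_level = 6,
                                     seed = 1) {
  stopifnot(coupling >= 0, coupling <= 1)
  cfg <- parse_mode_config(mode_config)
  if (sum(vapply(cfg, `[[`, integer(1), "n")) > n_genes) {
    stop("mode counts exceed n_genes")
  }
  smp <- design$samples
  ages <- design$ages
  oldest <- as.character(max(ages))
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    mode <- rep("none", n_genes)
    sgn <- rep(0, n_genes)
    i <- 0L
    for (m in names(cfg)) {
      idx <- i + seq_len(cfg[[m]]$n)
      mode[idx] <- m
      sgn[idx] <- sample(c(-1, 1), cfg[[m]]$n, replace = TRUE) * cfg[[m]]$effect
      i <- i + cfg[[m]]$n
    }
    offsets <- matrix(0, n_genes, length(ages),
                      dimnames = list(genes, as.character(ages)))
    offsets[, oldest] <- sgn

    base <- stats::rnorm(n_genes, base_level, 2)
    subjects <- unique(smp$subject_id)
    shared_sd <- noise_sd * sqrt(coupling)
    indep_sd <- noise_sd * sqrt(1 - coupling)
    subj_eff <- matrix(stats::rnorm(n_genes * length(subjects), sd = shared_sd),
                       n_genes, dimnames = list(genes, subjects))
    mk <- function(fraction) {
      cols <- smp[smp$fraction == fraction, ]
      m <- matrix(0, n_genes, nrow(cols),
                  dimnames = list(genes, cols$sample_id))
      for (s in seq_len(nrow(cols))) {
        o <- offsets[, as.character(cols$age_months[s])]
        if (fraction == "total") o[mode == "translation"] <- 0
        if (fraction == "polysome") o[mode == "buffering"] <- 0
        m[, s] <- base + subj_eff[, cols$subject_id[s]] + o +
          stats::rnorm(n_genes, sd = indep_sd)
      }
      m
    }
    total <- mk("total")
    polysome <- mk("polysome")
    truth <- data.frame(gene = genes, mode = mode, effect = sgn,
                        trajectory = ifelse(sgn > 0, "up",
                                            ifelse(sgn < 0, "down", "flat")),
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, as.data.frame(offsets))
    names(truth)[-(1:4)] <- paste0("offset_", ages)
    list(total = total, polysome = polysome, samples = smp, truth = truth)
  })
}

#' Simulate transcript TPM tables realizing planted PSI and APA psi
#'
#' For each splicing event of the annotation, the inclusion-form share of
#' the event's transcript abundance is the planted per-age PSI plus
#' zero-mean logit-scale noise (clipped to [0, 1]; exact at planted 0/1).
#' For APA genes, the distal-site share realizes the planted psi the same
#' way. Remaining transcripts split their gene's abundance evenly. Each
#' sample column is rescaled to sum to 1e6.
#'
#' @param ann toy annotation carrying the event/APA genes.
#' @param design a [study_design()]; one TPM column per design sample.
#' @param psi_truth data frame `event_id`, `age_months`, `psi` (may be
#'   empty). Every event id must exist in the annotation's enumeration.
#' @param apa_truth data frame `gene_id`, `age_months`, `psi` (may be
#'   empty); genes must have >= 2 APA sites.
#' @param noise_sd logit-scale noise sd (0 = exact).
#' @param base_tpm nominal per-gene abundance (default 50).
#' @param seed integer seed.
#' @return list with `tpm` (transcript x sample matrix), `events` (the
#'   enumerated events), `sites` (APA site table).
#' @export
simulate_transcript_tpm <- function(ann, design, psi_truth = NULL,
                                    apa_truth = NULL, noise_sd = 0,
                                    base_tpm = 50, seed = 1) {
  smp <- design$samples
  events <- enumerate_events(ann)
  sites <- group_apa_sites(terminal_fragments(ann))
  if (!is.null(psi_truth) && nrow(psi_truth)) {
    if (!all(psi_truth$event_id %in% events$event_id)) {
      stop("psi_truth references an event not present in the annotation")
    }
    if (any(psi_truth$psi < 0 | psi_truth$psi > 1)) {
      stop("planted PSI outside [0, 1]")
    }
  }
  if (!is.null(apa_truth) && nrow(apa_truth)) {
    n_sites <- sites$n_sites[match(apa_truth$gene_id, sites$gene_id)]
    if (any(is.na(n_sites) | n_sites < 2)) {
      stop("apa_truth references a gene without >= 2 APA sites")
    }
    if (any(apa_truth$psi < 0 | apa_truth$psi > 1)) {
      stop("planted psi outside [0, 1]")
    }
  }

  tx_gene <- unique(ann[, c("transcript_id", "gene_id")])
  txs <- tx_gene$transcript_id
  tx_by_gene <- split(tx_gene$transcript_id, tx_gene$gene_id)

  # precomputed planting instructions: transcript index sets and per-age
  # target fractions
  plants <- list()
  if (!is.null(psi_truth) && nrow(psi_truth)) {
    for (eid in unique(psi_truth$event_id)) {
      ev <- events[events$event_id == eid, ]
      pt <- psi_truth[psi_truth$event_id == eid, ]
      plants[[length(plants) + 1L]] <- list(
        on = match(strsplit(ev$inclusion, ",", fixed = TRUE)[[1]], txs),
        off = match(strsplit(ev$exclusion, ",", fixed = TRUE)[[1]], txs),
        zero = integer(0),
        psi = stats::setNames(pt$psi, pt$age_months)
      )
    }
  }
  if (!is.null(apa_truth) && nrow(apa_truth)) {
    for (g in unique(apa_truth$gene_id)) {
      ss <- sites[sites$gene_id == g, ]
      at <- apa_truth[apa_truth$gene_id == g, ]
      prox <- strsplit(ss$transcripts[which.min(ss$weight)], ",")[[1]]
      dist <- strsplit(ss$transcripts[which.max(ss$weight)], ",")[[1]]
      mid <- setdiff(unlist(strsplit(ss$transcripts, ",")), c(prox, dist))
      plants[[length(plants) + 1L]] <- list(
        on = match(dist, txs), off = match(prox, txs),
        zero = match(mid, txs),
        psi = stats::setNames(at$psi, at$age_months)
      )
    }
  }

  with_seed(seed, {
    gene_ids <- names(tx_by_gene)
    gene_tpm <- stats::rlnorm(length(gene_ids), log(base_tpm), 0.5)
    names(gene_tpm) <- gene_ids
    gene_of_tx <- tx_gene$gene_id
    tx_idx_by_gene <- lapply(tx_by_gene, function(tt) match(tt, txs))

    tpm <- matrix(0, length(txs), nrow(smp),
                  dimnames = list(txs, smp$sample_id))
    for (s in seq_len(nrow(smp))) {
      age <- as.character(smp$age_months[s])
      share <- rep(NA_real_, length(txs))
      for (pl in plants) {
        target <- pl$psi[[age]]
        p <- if (noise_sd == 0 || target <= 0 || target >= 1) target else
          min(max(stats::plogis(stats::qlogis(target) +
                                  stats::rnorm(1, sd = noise_sd)), 0), 1)
        share[pl$on] <- p / length(pl$on)
        share[pl$off] <- (1 - p) / length(pl$off)
        if (length(pl$zero)) share[pl$zero] <- 0
      }
      for (g in seq_along(gene_ids)) {
        gi <- tx_idx_by_gene[[g]]
        un <- gi[is.na(share[gi])]
        if (length(un)) {
          used <- sum(share[gi], na.rm = TRUE)
          share[un] <- max(1 - used, 0) / length(un)
        }
      }
      col <- gene_tpm[gene_of_tx] * share
      tpm[, s] <- col / sum(col) * 1e6
    }
    list(tpm = tpm, events = events, sites = sites)
  })
}

#' Simulate temporal profiles with planted shapes
#'
#' Profiles are isotropic Gaussian perturbations of z-scored shape
#' centroids (monotone up/down, a mid-life peak, a V). The perturbed
#' profiles are not re-standardized: the spherical noise matches the
#' spherical-Gaussian quantization model behind the BIC cluster-count
#' selection, and downstream similarity/clustering does not require exact
#' unit variance.
#'
#' @param n_per_shape genes per shape.
#' @param shapes subset of `up`, `down`, `peak`, `V` (default first three).
#' @param noise_sd isotropic per-point noise sd (default 0.2).
#' @param ages age axis.
#' @param seed integer seed.
#' @return list with `z` (profile matrix) and `truth` (shape label per gene).
#' @export
simulate_trajectory_profiles <- function(n_per_shape = 20,
                                         shapes = c("up", "down", "peak"),
                                         noise_sd = 0.2,
                                         ages = c(3, 6, 12, 20), seed = 1) {
  zscore <- function(x) {
    x <- x - mean(x)
    x / sqrt(mean(x^2))
  }
  base_shapes <- lapply(list(
    up = c(-1.2, -0.4, 0.4, 1.2),
    down = c(1.2, 0.4, -0.4, -1.2),
    peak = c(-1, 1, 1, -1),
    V = c(1, -1, -1, 1)
  ), zscore)
  stopifnot(all(shapes %in% names(base_shapes)))
  with_seed(seed, {
    # truncated-normal perturbations (+/- 2 sd): bounded noise keeps the
    # planted clusters free of stray between-cluster profiles, so the
    # benchmark probes recovery of clear structure
    rtnorm <- function(n, sd) {
      x <- stats::rnorm(n, sd = sd)
      while (any(bad <- abs(x) > 2 * sd)) x[bad] <- stats::rnorm(sum(bad), sd = sd)
      x
    }
    z <- do.call(rbind, lapply(shapes, function(sh) {
      matrix(rep(base_shapes[[sh]], each = n_per_shape), ncol = length(ages)) +
        matrix(rtnorm(n_per_shape * length(ages), sd = noise_sd),
               ncol = length(ages))
    }))
    rownames(z) <- sprintf("g%04d", seq_len(nrow(z)))
    colnames(z) <- as.character(ages)
    list(z = z, truth = rep(shapes, each = n_per_shape))
  })
}
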