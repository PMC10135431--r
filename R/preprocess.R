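## Filtering, normalization and QC.
##
## The low-abundance filter keeps genes reaching a library-size-derived CPM
## threshold N = median_i(8e6 / library_size_i) in at least `min_samples`
## samples of either fraction. Normalization is TMM (trimmed mean of
## M-values) with log2 CPM on a 0.5 pseudocount. QC combines PCA, an
## average-pairwise-correlation outlier rule, and a simplified location-scale
## empirical-Bayes batch adjustment.

#' Counts per million
#'
#' @param counts gene x sample count matrix (library sizes = column sums).
#' @param tmm_factors optional per-sample TMM scaling factors (default 1).
#' @return matrix of CPM values: `counts[g,s] / (lib_size[s] * tmm[s]) * 1e6`.
#' @export
compute_cpm <- function(counts, tmm_factors = NULL) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("all-zero sample column: CPM undefined")
  if (is.null(tmm_factors)) tmm_factors <- rep(1, ncol(counts))
  stopifnot(length(tmm_factors) == ncol(counts), all(tmm_factors > 0))
  sweep(counts, 2, lib * tmm_factors, "/") * 1e6
}

# log2 CPM with the package-wide pseudocount of 0.5.
log2_cpm <- function(counts, tmm_factors = NULL) {
  log2(compute_cpm(counts, tmm_factors) + 0.5)
}

#' Low-abundance filter at a library-size-derived CPM threshold
#'
#' The threshold is `N = median(8e6 / lib_size)` over all samples of both
#' fractions; a gene is kept when its (unnormalized) CPM is at least N in at
#' least `min_samples` total-RNA samples or at least `min_samples` polysome
#' samples. The 8e6 constant ties N to the nominal sequencing depth: a
#' library of exactly 8 million reads yields N = 1 CPM.
#'
#' @param total_counts,polysome_counts count matrices sharing a gene index.
#' @param min_samples minimum samples at or above threshold (default 4).
#' @return list with `kept` (gene ids), `threshold` (N), and the logical
#'   `keep` vector in input gene order.
#' @export
filter_low_abundance <- function(total_counts, polysome_counts, min_samples = 4) {
  total_counts <- as.matrix(total_counts)
  polysome_counts <- as.matrix(polysome_counts)
  if (!identical(rownames(total_counts), rownames(polysome_counts))) {
    stop("matrices must share the gene index")
  }
  if (ncol(total_counts) < min_samples && ncol(polysome_counts) < min_samples) {
    stop("fewer than min_samples samples in both fractions")
  }
  lib <- c(colSums(total_counts), colSums(polysome_counts))
  threshold <- stats::median(8e6 / lib)
  keep <- rowSums(compute_cpm(total_counts) >= threshold) >= min_samples |
    rowSums(compute_cpm(polysome_counts) >= threshold) >= min_samples
  list(kept = rownames(total_counts)[keep], threshold = threshold, keep = keep)
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values (Robinson-Oshlack): pairwise log ratios against a
#' reference sample, 30%/5% two-sided trimming on M/A, inverse-variance
#' weighting, factors rescaled to geometric mean 1. The `"auto"` reference is
#' the sample whose upper-quartile count fraction is closest to the mean.
#' Computation is delegated to edgeR's TMM implementation.
#'
#' @param counts gene x sample count matrix (>= 2 samples).
#' @param reference sample id, column index, or `"auto"`.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, reference = "auto") {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs >= 2 samples")
  ref <- NULL
  if (!identical(reference, "auto")) {
    ref <- if (is.character(reference)) match(reference, colnames(counts)) else reference
    if (is.na(ref)) stop("unknown reference sample")
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref)
  names(f) <- colnames(counts)
  f
}

#' Correlation-IQR outlier detection
#'
#' Within each fraction set, computes every sample's average Pearson
#' correlation to the other samples of its set and flags samples falling
#' more than 1.5 interquartile ranges below the first quartile of those
#' averages. Quartiles use linear interpolation between order statistics
#' (quantile type 7). Flagging is a single pass (no re-flagging).
#'
#' @param log2cpm gene x sample matrix of log2 CPM values.
#' @param set_label per-sample set membership (e.g. `"total"`/`"polysome"`).
#' @return data frame per sample: `sample_id`, `set`, `avg_correlation`,
#'   `flagged`.
#' @export
detect_outliers <- function(log2cpm, set_label) {
  stopifnot(length(set_label) == ncol(log2cpm))
  if (any(apply(log2cpm, 2, stats::sd) == 0)) {
    stop("constant sample vector: correlation undefined")
  }
  out <- lapply(split(seq_len(ncol(log2cpm)), set_label), function(idx) {
    if (length(idx) < 4) stop("each set needs >= 4 samples")
    cc <- stats::cor(log2cpm[, idx, drop = FALSE])
    rbar <- (rowSums(cc) - 1) / (length(idx) - 1)
    q <- stats::quantile(rbar, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(
      sample_id = colnames(log2cpm)[idx],
      set = set_label[idx][1],
      avg_correlation = rbar,
      flagged = rbar < q[1] - 1.5 * (q[2] - q[1]),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simplified empirical-Bayes batch adjustment
#'
#' Location-scale batch correction on log2 CPM: per gene, batch mean offsets
#' and scale ratios are estimated from residuals after removing age-group
#' means, shrunk toward their across-gene average with precision weights,
#' and removed. Group-mean structure is preserved. This is a deliberately
#' simplified location-scale model in the empirical-Bayes spirit of ComBat,
#' not a reimplementation of it.
#'
#' @param log2cpm gene x sample matrix.
#' @param batch per-sample batch labels (each batch >= 2 samples).
#' @param group per-sample biological group (age group) whose mean structure
#'   must be preserved.
#' @return adjusted matrix of the same dimensions.
#' @export
batch_adjust <- function(log2cpm, batch, group) {
  log2cpm <- as.matrix(log2cpm)
  batch <- factor(batch)
  group <- factor(group)
  stopifnot(length(batch) == ncol(log2cpm), length(group) == ncol(log2cpm))
  if (nlevels(batch) == 1) return(log2cpm)
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples")
  X <- stats::model.matrix(~ group + batch)
  if (qr(X)$rank < ncol(X)) {
    stop("batch is confounded with the age-group design; cannot adjust")
  }

  ## location: batch coefficients estimated jointly with group means (OLS on
  ## the full design handles unbalanced batch/group layouts), then shrunk
  ## toward their across-gene mean with precision weights.
  qrX <- qr(X)
  beta <- t(qr.coef(qrX, t(log2cpm)))
  resid <- t(qr.resid(qrX, t(log2cpm)))
  df_resid <- ncol(log2cpm) - qrX$rank
  s2 <- pmax(rowSums(resid^2) / max(df_resid, 1), 1e-8)
  covX <- chol2inv(qr.R(qrX))
  batch_cols <- grep("^batch", colnames(X))
  adjusted <- log2cpm
  for (j in batch_cols) {
    gamma <- beta[, j]
    se2 <- s2 * covX[j, j]
    tau2 <- max(stats::var(gamma) - mean(se2), 0)
    w <- tau2 / (tau2 + se2)
    gamma_star <- w * gamma + (1 - w) * mean(gamma)
    adjusted <- adjusted - outer(gamma_star, X[, j])
  }

  ## scale: per-batch residual sd ratios, log-centered across batches per
  ## gene (sample-weighted, so overall scale is untouched), shrunk toward
  ## their across-gene mean, then divided out of the residuals.
  G <- stats::model.matrix(~ 0 + group)
  coef_g <- solve(crossprod(G), crossprod(G, t(adjusted)))
  fitted <- t(G %*% coef_g)
  dimnames(fitted) <- dimnames(adjusted)
  res2 <- adjusted - fitted
  nb <- as.vector(table(batch))
  log_r <- sapply(levels(batch), function(b) {
    idx <- which(batch == b)
    s2_b <- pmax(rowMeans(res2[, idx, drop = FALSE]^2), 1e-10)
    0.5 * log(s2_b)
  })
  log_r <- log_r - as.vector(log_r %*% (nb / sum(nb)))  # weighted centering
  for (bi in seq_along(levels(batch))) {
    idx <- which(batch == levels(batch)[bi])
    v_logr <- 1 / (2 * max(nb[bi] - 1, 1))
    tau2_r <- max(stats::var(log_r[, bi]) - v_logr, 0)
    w_r <- tau2_r / (tau2_r + v_logr)
    r_star <- exp(w_r * log_r[, bi] + (1 - w_r) * mean(log_r[, bi]))
    res2[, idx] <- res2[, idx, drop = FALSE] / r_star
  }
  fitted + res2
}

#' Principal component analysis of samples
#'
#' Samples are centered per gene; scores come from the singular value
#' decomposition (via `prcomp` on the transposed matrix).
#'
#' @param log2cpm gene x sample matrix (>= 2 samples).
#' @return list with `scores` (sample x component) and `var_explained`
#'   (fractions summing to 1).
#' @export
pca_samples <- function(log2cpm) {
  if (ncol(log2cpm) < 2) stop("PCA needs >= 2 samples")
  pc <- stats::prcomp(t(log2cpm), center = TRUE, scale. = FALSE)
  list(scores = pc$x, var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Filter and normalize a paired experiment
#'
#' Applies [filter_low_abundance()] across the two fractions, then computes
#' TMM factors and log2 CPM per fraction (each fraction normalized
#' independently, as the two RNA pools have distinct composition).
#'
#' @param experiment a [count_experiment()] holding both fractions.
#' @param min_samples passed to the filter.
#' @return list with per-fraction `log2cpm` matrices, `tmm` factors,
#'   `lib_size`, the filter `threshold` and the kept `genes`.
#' @export
normalize_experiment <- function(experiment, min_samples = 4) {
  tot <- fraction_counts(experiment, "total")
  pol <- fraction_counts(experiment, "polysome")
  flt <- filter_low_abundance(tot, pol, min_samples = min_samples)
  tot <- tot[flt$keep, , drop = FALSE]
  pol <- pol[flt$keep, , drop = FALSE]
  tmm_t <- tmm_factors(tot)
  tmm_p <- tmm_factors(pol)
  list(
    log2cpm = list(total = log2_cpm(tot, tmm_t), polysome = log2_cpm(pol, tmm_p)),
    tmm = list(total = tmm_t, polysome = tmm_p),
    lib_size = list(total = colSums(tot), polysome = colSums(pol)),
    threshold = flt$threshold,
    genes = flt$kept,
    samples = experiment$samples
  )
}
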