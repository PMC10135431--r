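## Regulatory-mode classification from paired total/polysome data.
##
## Per gene and pairwise age contrast, analysis of partial variance (APV):
## regress one RNA pool on the other plus a group indicator. The group
## coefficient gamma is the adjusted effect -- the change in polysomal RNA
## not explained by total RNA ("translation" direction), or the change in
## total RNA not explained by polysomal RNA ("buffering" direction).
## Significance uses the same moderated-variance engine as differential
## expression. Classification per (gene, contrast):
##   translation: q(gamma)  < alpha, |gamma|  > min_eff, |deltaP| > min_eff,
##                |deltaP| > |deltaT|
##   buffering:   q(gammaB) < alpha, |gammaB| > min_eff, |deltaT| > min_eff,
##                |deltaT| > |deltaP|
##   abundance:   deltaT and deltaP each significant, same sign
## with exclusive priority translation > buffering > abundance. The
## dominance conditions keep the two directional calls mutually exclusive.

#' Per-gene analysis of partial variance for one contrast
#'
#' Fits `response = alpha + beta * covariate + gamma * I(later group)` per
#' gene over the subjects of a pairwise age contrast, pairing fractions by
#' subject. Direction `"translation"` regresses polysome on total (gamma is
#' the translational effect); `"buffering"` swaps response and covariate.
#'
#' @param total_log2cpm,polysome_log2cpm gene x sample matrices (same genes).
#' @param samples sample sheet rows describing the columns of both matrices
#'   (`sample_id`, `subject_id`, `age_months`, `fraction`).
#' @param contrast label `"AvB"` (later age A vs earlier age B).
#' @param direction `"translation"` or `"buffering"`.
#' @return data frame per gene: `gene`, `contrast`, `direction`, `effect`
#'   (gamma), `beta`, `p`, `q` (BH across genes).
#' @export
apv_fit <- function(total_log2cpm, polysome_log2cpm, samples, contrast,
                    direction = c("translation", "buffering")) {
  direction <- match.arg(direction)
  stopifnot(identical(rownames(total_log2cpm), rownames(polysome_log2cpm)))
  ages <- as.numeric(strsplit(contrast, "v", fixed = TRUE)[[1]])

  st <- samples[samples$fraction == "total", ]
  sp <- samples[samples$fraction == "polysome", ]
  subj <- intersect(st$subject_id, sp$subject_id)
  st <- st[match(subj, st$subject_id), ]
  sp <- sp[match(subj, sp$subject_id), ]
  keep <- st$age_months %in% ages
  if (!any(st$age_months == ages[1]) || !any(st$age_months == ages[2])) {
    stop("contrast references an absent age group")
  }
  st <- st[keep, ]; sp <- sp[keep, ]
  if (!all(st$sample_id %in% colnames(total_log2cpm)) ||
      !all(sp$sample_id %in% colnames(polysome_log2cpm))) {
    stop("unpaired subject: a fraction sample is missing from its matrix")
  }
  tmat <- total_log2cpm[, st$sample_id, drop = FALSE]
  pmat <- polysome_log2cpm[, sp$sample_id, drop = FALSE]
  z <- as.numeric(st$age_months == ages[1]) # 1 = later group
  n <- length(z)
  if (n < 4) stop("too few paired subjects for APV")

  if (direction == "translation") {
    Y <- pmat; Cv <- tmat
  } else {
    Y <- tmat; Cv <- pmat
  }

  ng <- nrow(Y)
  gamma <- beta <- s2 <- vu <- rep(NA_real_, ng)
  df_resid <- n - 3
  for (g in seq_len(ng)) {
    X <- cbind(1, Cv[g, ], z)
    xtx <- crossprod(X)
    ok <- TRUE
    inv <- tryCatch(solve(xtx), error = function(e) {ok <<- FALSE; NULL})
    if (!ok) next
    bh <- inv %*% crossprod(X, Y[g, ])
    res <- Y[g, ] - X %*% bh
    beta[g] <- bh[2]
    gamma[g] <- bh[3]
    s2[g] <- sum(res^2) / df_resid
    vu[g] <- inv[3, 3]
  }
  sq <- squeeze_var(s2[!is.na(s2)], df_resid)
  s2_post <- rep(NA_real_, ng)
  s2_post[!is.na(s2)] <- sq$s2_post
  df_total <- sq$df_prior + df_resid
  if (!is.finite(df_total)) df_total <- 1e6
  tstat <- gamma / sqrt(s2_post * vu)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  data.frame(
    gene = rownames(Y), contrast = contrast, direction = direction,
    effect = gamma, beta = beta, p = p, q = bh_adjust(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Classify genes into regulatory modes for one contrast
#'
#' @param apv_translation,apv_buffering [apv_fit()] tables for the contrast.
#' @param de_total,de_polysome [test_contrast()] tables for the contrast
#'   (total and polysome fractions).
#' @param alpha BH-adjusted p threshold (maxPAdj).
#' @param min_eff minimum absolute effect (minEff), default log2(1.2).
#' @return data frame per gene: `gene`, `contrast`, `mode` (one of
#'   `translation`, `buffering`, `abundance`, `none`), `delta_t`, `delta_p`,
#'   `gamma`, `gamma_b`, and the q-values behind each rule.
#' @export
classify_modes <- function(apv_translation, apv_buffering, de_total,
                           de_polysome, alpha = 0.05, min_eff = log2(1.2)) {
  genes <- apv_translation$gene
  stopifnot(
    identical(genes, apv_buffering$gene),
    identical(genes, de_total$gene),
    identical(genes, de_polysome$gene)
  )
  gamma <- apv_translation$effect
  gamma_b <- apv_buffering$effect
  q_tr <- apv_translation$q
  q_bf <- apv_buffering$q
  dt <- de_total$fc; qt <- de_total$q
  dp <- de_polysome$fc; qp <- de_polysome$q

  # the dominance conditions |dP| > |dT| (translation) and |dT| > |dP|
  # (buffering) make the two directional calls mutually exclusive: a
  # buffering gene whose polysome fold change drifts past min_eff by noise
  # cannot be misrouted to translation, and swapping the fraction matrices
  # swaps the two calls exactly
  is_tr <- !is.na(q_tr) & q_tr < alpha & abs(gamma) > min_eff &
    abs(dp) > min_eff & abs(dp) > abs(dt)
  is_bf <- !is.na(q_bf) & q_bf < alpha & abs(gamma_b) > min_eff &
    abs(dt) > min_eff & abs(dt) > abs(dp)
  sig_t <- qt < alpha & abs(dt) > min_eff
  sig_p <- qp < alpha & abs(dp) > min_eff
  is_ab <- sig_t & sig_p & sign(dt) == sign(dp)

  mode <- rep("none", length(genes))
  mode[is_ab] <- "abundance"
  mode[is_bf] <- "buffering"
  mode[is_tr] <- "translation"   # priority translation > buffering > abundance

  data.frame(
    gene = genes, contrast = apv_translation$contrast[1], mode = mode,
    delta_t = dt, delta_p = dp, gamma = gamma, gamma_b = gamma_b,
    q_translation = q_tr, q_buffering = q_bf, q_total = qt, q_polysome = qp,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Run the full regulatory-mode analysis across contrasts
#'
#' Convenience wrapper: fits the differential-expression models per fraction
#' once, then runs both APV directions and [classify_modes()] for every
#' contrast.
#'
#' @param total_log2cpm,polysome_log2cpm gene x sample matrices.
#' @param samples sample sheet covering both matrices.
#' @param contrasts contrast labels; default all pairwise age comparisons.
#' @param alpha,min_eff classification thresholds.
#' @return row-bound [classify_modes()] tables.
#' @export
regmode_analysis <- function(total_log2cpm, polysome_log2cpm, samples,
                             contrasts = NULL, alpha = 0.05,
                             min_eff = log2(1.2)) {
  st <- samples[match(colnames(total_log2cpm), samples$sample_id), ]
  sp <- samples[match(colnames(polysome_log2cpm), samples$sample_id), ]
  fit_t <- fit_gene_models(total_log2cpm, st$age_months, st$batch)
  fit_p <- fit_gene_models(polysome_log2cpm, sp$age_months, sp$batch)
  if (is.null(contrasts)) {
    cmb <- utils::combn(sort(unique(st$age_months)), 2)
    contrasts <- sprintf("%gv%g", cmb[2, ], cmb[1, ])
  }
  do.call(rbind, lapply(contrasts, function(ct) {
    classify_modes(
      apv_fit(total_log2cpm, polysome_log2cpm, samples, ct, "translation"),
      apv_fit(total_log2cpm, polysome_log2cpm, samples, ct, "buffering"),
      test_contrast(fit_t, ct),
      test_contrast(fit_p, ct),
      alpha = alpha, min_eff = min_eff
    )
  }))
}

#' Summarize regulatory-mode calls
#'
#' @param calls table from [classify_modes()] / [regmode_analysis()].
#' @return list with `counts` (genes per mode per contrast), `overall`
#'   (genes per mode across contrasts, counting a gene once per mode) and
#'   `multi_mode_genes` (genes with >= 2 distinct non-none modes).
#' @export
summarize_modes <- function(calls) {
  if (nrow(calls) == 0) {
    return(list(counts = data.frame(), overall = integer(0),
                multi_mode_genes = character(0)))
  }
  nz <- calls[calls$mode != "none", , drop = FALSE]
  counts <- as.data.frame(table(contrast = nz$contrast, mode = nz$mode),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n_genes"
  per_gene <- lapply(split(nz$mode, nz$gene), unique)
  list(
    counts = counts,
    overall = vapply(split(nz$gene, nz$mode), function(g) length(unique(g)), integer(1)),
    multi_mode_genes = names(per_gene)[vapply(per_gene, length, integer(1)) >= 2]
  )
}
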