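## Moderated-variance engine.
##
## One shrinkage engine serves both differential expression and the
## regulatory-mode APV tests: per-gene residual variances are shrunk toward
## a common prior, s2_post = (d0*s0^2 + d*s2) / (d0 + d), with the prior
## (d0, s0^2) estimated by method of moments on log s2 across genes
## (scaled-inverse-chi-square model, so log s2 is a shifted log-F variate
## whose mean/variance involve di/trigamma functions).

# Invert the trigamma function by Newton iteration on 1/x (monotone,
# near-linear parametrization).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Shrink per-gene variances toward a common prior
#'
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar or per-gene vector).
#' @return list with `df_prior` (d0, may be `Inf`), `s2_prior` (s0^2) and
#'   `s2_post` (moderated variances).
#' @export
squeeze_var <- function(s2, df) {
  stopifnot(length(s2) >= 2)
  if (length(df) == 1) df <- rep(df, length(s2))
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  d <- df[ok]
  e_adj <- digamma(d / 2) - log(d / 2)
  z_c <- z - e_adj
  ev <- stats::var(z_c) - mean(trigamma(d / 2))
  if (!is.finite(ev) || ev <= 0) {
    # no detectable spread of true variances: all genes share one variance,
    # taken as the geometric mean (equal inputs pass through unchanged)
    df_prior <- Inf
    s2_prior <- exp(mean(z))
    s2_post <- rep(s2_prior, length(s2))
  } else {
    df_prior <- 2 * trigamma_inverse(ev)
    s2_prior <- exp(mean(z_c) + digamma(df_prior / 2) - log(df_prior / 2))
    s2_post <- (df_prior * s2_prior + df * s2) / (df_prior + df)
  }
  list(df_prior = df_prior, s2_prior = s2_prior, s2_post = s2_post)
}

# Ordinary least squares for every row of y on a shared design matrix,
# followed by variance moderation. Returns coefficients, (moderated)
# variances, residual df and the unscaled coefficient covariance.
moderated_lm <- function(y, design) {
  y <- as.matrix(y)
  n <- ncol(y)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop("design matrix is rank deficient")
  df_resid <- n - qrX$rank
  if (df_resid < 1) stop("no residual degrees of freedom")
  coef <- t(qr.coef(qrX, t(y)))
  res <- t(qr.resid(qrX, t(y)))
  s2 <- rowSums(res^2) / df_resid
  sq <- squeeze_var(s2, df_resid)
  list(
    coefficients = coef,
    design = design,
    cov_unscaled = chol2inv(qr.R(qrX)[seq_len(qrX$rank), seq_len(qrX$rank)]),
    s2 = s2,
    s2_post = sq$s2_post,
    df_resid = df_resid,
    df_prior = sq$df_prior,
    s2_prior = sq$s2_prior
  )
}

# Moderated t-test of a contrast c'beta for every gene of a moderated_lm fit.
moderated_contrast_test <- function(fit, contrast_vec) {
  stopifnot(length(contrast_vec) == ncol(fit$coefficients))
  fc <- drop(fit$coefficients %*% contrast_vec)
  vu <- drop(t(contrast_vec) %*% fit$cov_unscaled %*% contrast_vec)
  se <- sqrt(fit$s2_post * vu)
  tstat <- fc / se
  df_total <- fit$df_prior + fit$df_resid
  if (!is.finite(df_total)) df_total <- 1e6
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[fc == 0] <- 1
  data.frame(
    gene = rownames(fit$coefficients),
    fc = fc, t = tstat, p = p, df = df_total,
    s2_post = fit$s2_post,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
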