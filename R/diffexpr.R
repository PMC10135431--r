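## Differential expression across pairwise age contrasts.
##
## A moderated linear model on log2 CPM (limma-trend-style): per-gene least
## squares on a shared age-group + batch design, empirical-Bayes variance
## shrinkage, moderated t per contrast, BH correction within each contrast.
## This approximates the quasi-likelihood negative-binomial engine often
## used on counts; at these replicate counts the moderated linear model on
## log2 CPM is well calibrated and fully specified in-package.

#' Fit per-gene models for age-group differential expression
#'
#' @param log2cpm gene x sample matrix (one fraction).
#' @param age_months per-sample age group.
#' @param batch optional per-sample batch labels entered into the design.
#' @return a fit object (shared moderated-variance engine) with one
#'   coefficient per age group plus batch terms.
#' @export
fit_gene_models <- function(log2cpm, age_months, batch = NULL) {
  age_f <- factor(age_months, levels = sort(unique(age_months)))
  if (nlevels(age_f) < 2) stop("need >= 2 age groups")
  if (is.null(batch) || length(unique(batch)) == 1) {
    design <- stats::model.matrix(~ 0 + age_f)
  } else {
    design <- stats::model.matrix(~ 0 + age_f + factor(batch))
  }
  colnames(design)[seq_len(nlevels(age_f))] <- paste0("age", levels(age_f))
  fit <- moderated_lm(log2cpm, design)
  fit$ages <- as.numeric(levels(age_f))
  fit
}

#' Moderated t-test of one pairwise age contrast
#'
#' @param fit result of [fit_gene_models()].
#' @param contrast label `"AvB"` (e.g. `"20v6"`): age A minus age B, so
#'   positive fold changes mean higher at the later age.
#' @return data frame per gene: `gene`, `contrast`, `fc` (log2 fold change),
#'   `p`, `q` (BH within the contrast), `t`, `df`.
#' @export
test_contrast <- function(fit, contrast) {
  ages <- strsplit(contrast, "v", fixed = TRUE)[[1]]
  if (length(ages) != 2) stop("contrast must look like '20v6'")
  ia <- match(paste0("age", ages[1]), colnames(fit$design))
  ib <- match(paste0("age", ages[2]), colnames(fit$design))
  if (is.na(ia) || is.na(ib)) stop("contrast references an absent age group")
  cv <- numeric(ncol(fit$coefficients))
  cv[ia] <- 1
  cv[ib] <- -1
  res <- moderated_contrast_test(fit, cv)
  res$q <- bh_adjust(res$p)
  res$contrast <- contrast
  res[, c("gene", "contrast", "fc", "t", "p", "q", "df")]
}

#' Run all pairwise age contrasts
#'
#' @param fit result of [fit_gene_models()].
#' @param contrasts character vector of contrast labels; defaults to every
#'   pairwise comparison of the fitted ages.
#' @return row-bound contrast tables (BH applied within each contrast).
#' @export
test_all_contrasts <- function(fit, contrasts = NULL) {
  if (is.null(contrasts)) {
    cmb <- utils::combn(sort(fit$ages), 2)
    contrasts <- sprintf("%gv%g", cmb[2, ], cmb[1, ])
  }
  do.call(rbind, lapply(contrasts, function(ct) test_contrast(fit, ct)))
}

#' Select differentially expressed genes
#'
#' A gene is selected when `q < alpha` and `|fc| > min_abs_fc`, both strict,
#' matching the usual BH p < 0.05 and |FC| > log2(1.2) rule.
#'
#' @param table contrast table from [test_contrast()].
#' @param alpha BH-adjusted significance threshold.
#' @param min_abs_fc minimum absolute log2 fold change.
#' @return the selected subset of `table`, ordered by p (ties by |fc|
#'   descending).
#' @export
select_degs <- function(table, alpha = 0.05, min_abs_fc = log2(1.2)) {
  sel <- table[table$q < alpha & abs(table$fc) > min_abs_fc, , drop = FALSE]
  sel[order(sel$p, -abs(sel$fc)), , drop = FALSE]
}
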