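## Study design and the paired count container.
##
## The design mirrors a polysome-profiling time course: subjects sampled at
## ordered ages, each contributing one total-RNA and one polysomal-RNA
## library, with subjects allocated to processing batches.

#' Construct a paired total/polysome study design
#'
#' Describes the subjects of a time-course polysome-profiling experiment.
#' Every subject contributes exactly two libraries (fractions `total` and
#' `polysome`); the default group sizes follow the reference design of 5, 6,
#' 4 and 5 subjects at 3, 6, 12 and 20 months.
#'
#' @param group_sizes named integer vector, age (months, as names) to subject
#'   count. Ages must be strictly increasing, sizes >= 2.
#' @param n_batches number of processing batches; subjects are allocated
#'   round-robin so batches are age-balanced.
#' @return An object of class `study_design`: a list with `ages`,
#'   `group_sizes` and `samples`, a data frame with one row per library and
#'   columns `sample_id`, `subject_id`, `age_months`, `fraction`, `batch`.
#' @examples
#' d <- study_design()
#' table(d$samples$age_months, d$samples$fraction)
#' @export
study_design <- function(group_sizes = c("3" = 5, "6" = 6, "12" = 4, "20" = 5),
                         n_batches = 2) {
  ages <- as.numeric(names(group_sizes))
  if (any(is.na(ages)) || is.unsorted(ages, strictly = TRUE)) {
    stop("group_sizes must be named by strictly increasing ages (months)")
  }
  if (any(group_sizes < 2)) stop("every age group needs >= 2 subjects")
  if (length(ages) < 2) stop("a degenerate design (single age group) is not supported")

  subj <- data.frame(
    subject_id = sprintf("S%02d", seq_len(sum(group_sizes))),
    age_months = rep(ages, group_sizes)
  )
  subj$batch <- sprintf("B%d", ((seq_len(nrow(subj)) - 1L) %% n_batches) + 1L)

  samples <- do.call(rbind, lapply(c("total", "polysome"), function(fr) {
    data.frame(
      sample_id = paste0(subj$subject_id, "_", ifelse(fr == "total", "T", "P")),
      subject_id = subj$subject_id,
      age_months = subj$age_months,
      fraction = fr,
      batch = subj$batch,
      stringsAsFactors = FALSE
    )
  }))
  rownames(samples) <- NULL
  structure(
    list(ages = ages, group_sizes = group_sizes, samples = samples),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Paired total/polysome study design\n")
  cat("  ages (months):", paste(x$ages, collapse = ", "), "\n")
  cat("  subjects per age:", paste(x$group_sizes, collapse = ", "),
      sprintf("(%d libraries)\n", nrow(x$samples)))
  invisible(x)
}

#' All pairwise age contrasts of a design
#'
#' @param design a [study_design()].
#' @return data frame with columns `contrast`, `age_a` (later age) and
#'   `age_b` (earlier age); a contrast label `20v6` means 20 vs 6 months,
#'   with fold changes oriented later-over-earlier. The default four-age
#'   design yields the six comparisons 6v3, 12v3, 20v3, 12v6, 20v6, 20v12.
#' @export
age_contrasts <- function(design) {
  ages <- design$ages
  cmb <- utils::combn(ages, 2)
  data.frame(
    contrast = sprintf("%gv%g", cmb[2, ], cmb[1, ]),
    age_a = cmb[2, ],
    age_b = cmb[1, ],
    stringsAsFactors = FALSE
  )
}

#' Bundle a count matrix with its sample metadata
#'
#' Lightweight container (in the spirit of a `DGEList`) pairing a gene-by-
#' sample integer count matrix with the sample sheet rows describing its
#' columns.
#'
#' @param counts gene x sample matrix of non-negative finite counts.
#' @param samples data frame with at least `sample_id`, `subject_id`,
#'   `age_months`, `fraction`, `batch`; `sample_id` must match `colnames(counts)`.
#' @return object of class `count_experiment` (list with `counts`, `samples`).
#' @export
count_experiment <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have column names")
  if (!all(colnames(counts) %in% samples$sample_id)) {
    stop("every count column must have a sample sheet entry")
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat(sprintf("count_experiment: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$fraction), collapse = "+")))
  invisible(x)
}

# Split a paired experiment into its fraction sub-matrices.
fraction_counts <- function(experiment, fraction) {
  keep <- experiment$samples$fraction == fraction
  experiment$counts[, experiment$samples$sample_id[keep], drop = FALSE]
}
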