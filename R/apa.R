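## Alternative polyadenylation via terminal fragments.
##
## Each transcript's terminal fragment is its final two exons (one if
## monoexonic) in transcription direction; its 3' end is the fragment's
## transcription-direction end. Fragments with 3' ends within 25 nt
## (single-linkage, inclusive) define one APA site. Sites are ordered
## proximal -> distal and given positional weights w = m/(n-1); a gene's psi
## per sample is the weighted average of site usage fractions, so psi = 0
## means exclusive most-proximal usage and psi = 1 exclusive most-distal.

#' Terminal fragments of every transcript
#'
#' @param ann annotation data frame.
#' @return data frame per transcript: `transcript_id`, `gene_id`, `strand`,
#'   `frag_start`, `frag_end` (genomic span of the final two exons) and
#'   `end3` (3' end coordinate in transcription direction).
#' @export
terminal_fragments <- function(ann) {
  validate_annotation(ann)
  tc <- transcript_chains(ann)
  info <- tc$info
  out <- lapply(info$transcript_id, function(tid) {
    ex <- tc$chains[[tid]]
    strand <- info[tid, "strand"]
    n <- nrow(ex)
    idx <- if (strand == "+") max(1, n - 1):n else 1:min(2, n)
    frag <- ex[idx, , drop = FALSE]
    data.frame(
      transcript_id = tid,
      gene_id = info[tid, "gene_id"],
      strand = strand,
      frag_start = min(frag[, 1]),
      frag_end = max(frag[, 2]),
      end3 = if (strand == "+") max(frag[, 2]) else min(frag[, 1]),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group terminal fragments into APA sites
#'
#' Single-linkage grouping of 3' ends with link distance <= `window`
#' (inclusive), per gene. Sites are ordered proximal -> distal in
#' transcription direction and weighted `w = m/(n-1)` for site index
#' `m = 0..n-1`.
#'
#' @param fragments table from [terminal_fragments()].
#' @param window grouping window in nt (default 25).
#' @return data frame per site: `gene_id`, `site_index` (0-based, proximal
#'   first), `weight`, `end3` (mean member 3' end), `transcripts`
#'   (comma-separated), `n_sites` (sites of the gene).
#' @export
group_apa_sites <- function(fragments, window = 25) {
  out <- lapply(split(fragments, fragments$gene_id), function(fr) {
    strand <- fr$strand[1]
    if (length(unique(fr$strand)) != 1) stop("mixed strand within gene")
    ord <- order(fr$end3)
    fr <- fr[ord, ]
    # single-linkage chaining along sorted 3' ends
    grp <- cumsum(c(1, diff(fr$end3) > window))
    sites <- lapply(split(seq_len(nrow(fr)), grp), function(idx) {
      list(end3 = mean(fr$end3[idx]), transcripts = fr$transcript_id[idx])
    })
    # proximal -> distal in transcription direction
    if (strand == "-") sites <- rev(sites)
    n <- length(sites)
    data.frame(
      gene_id = fr$gene_id[1],
      site_index = seq_len(n) - 1L,
      weight = if (n == 1) 0 else (seq_len(n) - 1) / (n - 1),
      end3 = vapply(sites, `[[`, numeric(1), "end3"),
      transcripts = vapply(sites, function(s) paste(sort(s$transcripts), collapse = ","),
                           character(1)),
      n_sites = n,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Positional APA psi per gene and sample
#'
#' `psi[s] = sum_m w_m * f_m[s]` with `f_m` the site-m share of the gene's
#' terminal transcript abundance. Missing when the gene's total terminal
#' abundance is below `floor`. Genes with a single site are excluded
#' (untestable).
#'
#' @param sites table from [group_apa_sites()].
#' @param tpm transcript x sample TPM matrix.
#' @param floor minimum total TPM for a defined psi (default 1).
#' @return gene x sample psi matrix (genes with >= 2 sites only).
#' @export
compute_gene_psi <- function(sites, tpm, floor = 1.0) {
  tpm <- as.matrix(tpm)
  sites <- sites[sites$n_sites >= 2, , drop = FALSE]
  genes <- unique(sites$gene_id)
  psi <- matrix(NA_real_, nrow = length(genes), ncol = ncol(tpm),
                dimnames = list(genes, colnames(tpm)))
  for (g in genes) {
    ss <- sites[sites$gene_id == g, , drop = FALSE]
    site_tpm <- matrix(0, nrow(ss), ncol(tpm))
    for (i in seq_len(nrow(ss))) {
      txs <- strsplit(ss$transcripts[i], ",", fixed = TRUE)[[1]]
      site_tpm[i, ] <- colSums(tpm[txs, , drop = FALSE])
    }
    total <- colSums(site_tpm)
    val <- colSums(site_tpm * ss$weight) / total
    val[total < floor] <- NA_real_
    psi[g, ] <- val
  }
  psi
}

#' Welch t-test of APA psi between age groups
#'
#' @param psi gene x sample psi matrix from [compute_gene_psi()].
#' @param groups per-sample group (age) vector.
#' @param contrasts contrast labels; default all pairwise comparisons.
#' @param alpha threshold on BH q (default 0.05).
#' @return data frame per gene per contrast: `gene_id`, `contrast`, `dpsi`
#'   (later minus earlier group mean), `p`, `q`, `significant`. Genes with
#'   fewer than 2 non-missing psi values in either group get `NA`. With zero
#'   variance in both groups, p is 1 for equal means and ~0 otherwise.
#' @export
test_apa <- function(psi, groups, contrasts = NULL, alpha = 0.05) {
  stopifnot(length(groups) == ncol(psi))
  groups <- as.numeric(groups)
  if (is.null(contrasts)) {
    cmb <- utils::combn(sort(unique(groups)), 2)
    contrasts <- sprintf("%gv%g", cmb[2, ], cmb[1, ])
  }
  res <- lapply(contrasts, function(ct) {
    ages <- as.numeric(strsplit(ct, "v", fixed = TRUE)[[1]])
    a <- psi[, groups == ages[1], drop = FALSE]
    b <- psi[, groups == ages[2], drop = FALSE]
    stats_g <- t(vapply(seq_len(nrow(psi)), function(i) {
      x <- a[i, ][!is.na(a[i, ])]
      y <- b[i, ][!is.na(b[i, ])]
      if (length(x) < 2 || length(y) < 2) return(c(NA_real_, NA_real_))
      d <- mean(x) - mean(y)
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        return(c(d, if (d == 0) 1 else 0))
      }
      c(d, stats::t.test(x, y)$p.value)
    }, numeric(2)))
    q <- bh_adjust(stats_g[, 2])
    data.frame(
      gene_id = rownames(psi), contrast = ct,
      dpsi = stats_g[, 1], p = stats_g[, 2], q = q,
      significant = !is.na(q) & q < alpha,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, res)
}
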