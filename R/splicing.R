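## Alternative splicing: event enumeration, PSI, delta-PSI testing.
##
## Events are enumerated from pairwise comparison of transcript exon chains
## within a gene, yielding the seven classical types: SE (skipped exon),
## A5/A3 (alternative 5'/3' splice site, strand-resolved), MX (mutually
## exclusive exons), RI (retained intron), AF/AL (alternative first/last
## exon). PSI per event and sample is the inclusion-form share of the
## combined inclusion+exclusion transcript abundance. The delta-PSI test is
## empirical: observed between-group mean differences are referred to a
## pooled within-group replicate null, stratified by event expression.

# Introns of a sorted exon chain: matrix of (start, end), possibly 0 rows.
chain_introns <- function(ex) {
  n <- nrow(ex)
  if (n < 2) return(cbind(start = numeric(0), end = numeric(0)))
  cbind(start = ex[-n, 2] + 1, end = ex[-1, 1] - 1)
}

ranges_overlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

# Compare one ordered transcript pair; returns a list of candidate events
# (type, coords key, inclusion transcript, exclusion transcript).
pair_events <- function(ex1, ex2, id1, id2, strand) {
  ev <- list()
  add <- function(type, coords, incl, excl) {
    ev[[length(ev) + 1L]] <<- list(type = type, coords = coords,
                                   inclusion = incl, exclusion = excl)
  }
  in1 <- chain_introns(ex1)
  in2 <- chain_introns(ex2)
  n1 <- nrow(ex1); n2 <- nrow(ex2)

  has_intron <- function(introns, s, e) {
    any(introns[, 1] == s & introns[, 2] == e)
  }

  ## SE: internal exon of one chain absent from the other, which joins the
  ## flanking exons directly.
  se_scan <- function(exA, inA, exB, inB, idA, idB) {
    nA <- nrow(exA)
    if (nA < 3) return()
    for (i in 2:(nA - 1)) {
      s <- exA[i - 1, 2] + 1   # intron span replacing the exon in B
      e <- exA[i + 1, 1] - 1
      if (has_intron(inB, s, e) &&
          has_intron(inA, s, exA[i, 1] - 1) &&
          has_intron(inA, exA[i, 2] + 1, e)) {
        add("SE", sprintf("%g-%g^%g-%g", s - 1, exA[i, 1], exA[i, 2], e + 1),
            idA, idB)
      }
    }
  }
  se_scan(ex1, in1, ex2, in2, id1, id2)
  se_scan(ex2, in2, ex1, in1, id2, id1)

  ## RI: an exon of one chain spans two adjacent exons (plus intron) of the
  ## other. Inclusion = intron-retaining form.
  ri_scan <- function(exA, exB, inB, idA, idB) {
    for (i in seq_len(nrow(exA))) {
      js <- which(exB[, 1] == exA[i, 1])
      for (j in js) {
        if (j < nrow(exB) && exB[j + 1, 2] == exA[i, 2] &&
            has_intron(inB, exB[j, 2] + 1, exB[j + 1, 1] - 1)) {
          add("RI", sprintf("%g:%g^%g:%g", exA[i, 1], exB[j, 2],
                            exB[j + 1, 1], exA[i, 2]),
              idA, idB)
        }
      }
    }
  }
  ri_scan(ex1, ex2, in2, id1, id2)
  ri_scan(ex2, ex1, in1, id2, id1)

  ## A5/A3: introns sharing exactly one boundary, with the exons at the
  ## differing boundary overlapping (so the variation is within one exon
  ## body, not an SE flank).
  if (nrow(in1) && nrow(in2)) {
    for (i in seq_len(nrow(in1))) {
      for (j in seq_len(nrow(in2))) {
        s1 <- in1[i, 1]; e1 <- in1[i, 2]
        s2 <- in2[j, 1]; e2 <- in2[j, 2]
        if (e1 == e2 && s1 != s2) {
          # upstream exon ends differ (donor side on + strand)
          up1 <- ex1[ex1[, 2] == s1 - 1, , drop = FALSE]
          up2 <- ex2[ex2[, 2] == s2 - 1, , drop = FALSE]
          if (nrow(up1) && nrow(up2) &&
              ranges_overlap(up1[1, 1], up1[1, 2], up2[1, 1], up2[1, 2])) {
            type <- if (strand == "+") "A5" else "A3"
            incl <- if (s1 > s2) id1 else id2   # longer exon = inclusion
            excl <- if (s1 > s2) id2 else id1
            add(type, sprintf("%g^%g-%g", min(s1, s2), max(s1, s2), e1 + 1),
                incl, excl)
          }
        } else if (s1 == s2 && e1 != e2) {
          # downstream exon starts differ (acceptor side on + strand)
          dn1 <- ex1[ex1[, 1] == e1 + 1, , drop = FALSE]
          dn2 <- ex2[ex2[, 1] == e2 + 1, , drop = FALSE]
          if (nrow(dn1) && nrow(dn2) &&
              ranges_overlap(dn1[1, 1], dn1[1, 2], dn2[1, 1], dn2[1, 2])) {
            type <- if (strand == "+") "A3" else "A5"
            incl <- if (e1 < e2) id1 else id2
            excl <- if (e1 < e2) id2 else id1
            add(type, sprintf("%g-%g^%g", s1 - 1, min(e1, e2), max(e1, e2)),
                incl, excl)
          }
        }
      }
    }
  }

  ## MX: one exclusive internal exon per chain, non-overlapping, between
  ## shared flanking splice sites.
  if (n1 >= 3 && n2 >= 3) {
    for (i in 2:(n1 - 1)) {
      for (j in 2:(n2 - 1)) {
        e1i <- ex1[i, ]; e2j <- ex2[j, ]
        if (!ranges_overlap(e1i[1], e1i[2], e2j[1], e2j[2]) &&
            ex1[i - 1, 2] == ex2[j - 1, 2] &&
            ex1[i + 1, 1] == ex2[j + 1, 1]) {
          # 5'-proximal variable exon (transcription direction) = inclusion
          first_is_incl <- if (strand == "+") e1i[1] < e2j[1] else e1i[2] > e2j[2]
          lo <- if (e1i[1] < e2j[1]) e1i else e2j
          hi <- if (e1i[1] < e2j[1]) e2j else e1i
          add("MX", sprintf("%g-%g^%g|%g-%g^%g", ex1[i - 1, 2], lo[1], lo[2],
                            hi[1], hi[2], ex1[i + 1, 1]),
              if (first_is_incl) id1 else id2,
              if (first_is_incl) id2 else id1)
        }
      }
    }
  }

  ## AF/AL: distinct non-overlapping terminal exons joined to a shared
  ## splice site of a common neighbour exon.
  if (n1 >= 2 && n2 >= 2) {
    # coordinate-left terminal exons share the downstream acceptor
    if (!ranges_overlap(ex1[1, 1], ex1[1, 2], ex2[1, 1], ex2[1, 2]) &&
        ex1[2, 1] == ex2[2, 1]) {
      type <- if (strand == "+") "AF" else "AL"
      if (type == "AF") {
        first_is_incl <- ex1[1, 1] < ex2[1, 1]  # 5'-most first exon
      } else {
        first_is_incl <- ex1[1, 1] < ex2[1, 1]  # 3'-most last exon on '-'
      }
      lo <- if (ex1[1, 1] < ex2[1, 1]) ex1[1, ] else ex2[1, ]
      hi <- if (ex1[1, 1] < ex2[1, 1]) ex2[1, ] else ex1[1, ]
      add(type, sprintf("%g-%g|%g-%g^%g", lo[1], lo[2], hi[1], hi[2], ex1[2, 1]),
          if (first_is_incl) id1 else id2, if (first_is_incl) id2 else id1)
    }
    # coordinate-right terminal exons share the upstream donor
    if (!ranges_overlap(ex1[n1, 1], ex1[n1, 2], ex2[n2, 1], ex2[n2, 2]) &&
        ex1[n1 - 1, 2] == ex2[n2 - 1, 2]) {
      type <- if (strand == "+") "AL" else "AF"
      first_is_incl <- ex1[n1, 1] > ex2[n2, 1]
      # on '+' the coordinate-right exons are last exons: 3'-most (larger
      # start) is taken as... inclusion = 5'-proximal form for AF, distal
      # last exon for AL; fixed as the higher-coordinate exon here, which is
      # the 5'-most first exon on '-' and the distal last exon on '+'.
      lo <- if (ex1[n1, 1] < ex2[n2, 1]) ex1[n1, ] else ex2[n2, ]
      hi <- if (ex1[n1, 1] < ex2[n2, 1]) ex2[n2, ] else ex1[n1, ]
      add(type, sprintf("%g^%g-%g|%g-%g", ex1[n1 - 1, 2], lo[1], lo[2], hi[1], hi[2]),
          if (first_is_incl) id1 else id2, if (first_is_incl) id2 else id1)
    }
  }
  ev
}

#' Enumerate alternative-splicing events from transcript models
#'
#' Pairwise comparison of transcript exon chains within each gene. Duplicate
#' events (same gene, type and coordinates) found in several transcript
#' pairs are merged with their transcript sets unioned.
#'
#' @param ann annotation data frame ([build_toy_annotation()] / [read_gtf()]).
#' @return data frame with one row per event: `event_id`, `gene_id`, `type`,
#'   `seqnames`, `strand`, `coords`, `inclusion` and `exclusion`
#'   (comma-separated transcript ids).
#' @export
enumerate_events <- function(ann) {
  validate_annotation(ann)
  tc <- transcript_chains(ann)
  out <- list()
  for (gid in unique(tc$info$gene_id)) {
    txs <- tc$info$transcript_id[tc$info$gene_id == gid]
    if (length(txs) < 2) next
    strand <- tc$info[txs[1], "strand"]
    chrom <- tc$info[txs[1], "seqnames"]
    found <- list()
    for (i in seq_len(length(txs) - 1)) {
      for (j in (i + 1):length(txs)) {
        evs <- pair_events(tc$chains[[txs[i]]], tc$chains[[txs[j]]],
                           txs[i], txs[j], strand)
        for (e in evs) {
          key <- paste(e$type, e$coords, sep = ":")
          if (is.null(found[[key]])) {
            found[[key]] <- e
          } else {
            found[[key]]$inclusion <- union(found[[key]]$inclusion, e$inclusion)
            found[[key]]$exclusion <- union(found[[key]]$exclusion, e$exclusion)
          }
        }
      }
    }
    for (key in names(found)) {
      e <- found[[key]]
      out[[length(out) + 1L]] <- data.frame(
        event_id = sprintf("%s;%s:%s:%s:%s", gid, e$type, chrom, e$coords, strand),
        gene_id = gid, type = e$type, seqnames = chrom, strand = strand,
        coords = e$coords,
        inclusion = paste(sort(e$inclusion), collapse = ","),
        exclusion = paste(sort(e$exclusion), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(event_id = character(0), gene_id = character(0),
                      type = character(0), seqnames = character(0),
                      strand = character(0), coords = character(0),
                      inclusion = character(0), exclusion = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percent-spliced-in per event and sample
#'
#' `PSI = sum TPM(inclusion) / (sum TPM(inclusion) + sum TPM(exclusion))`;
#' missing (`NA`) when the combined abundance is below `floor`.
#'
#' @param events table from [enumerate_events()].
#' @param tpm transcript x sample TPM matrix.
#' @param floor minimum combined TPM for a defined PSI (default 1).
#' @return event x sample PSI matrix (rownames = event ids).
#' @export
compute_psi <- function(events, tpm, floor = 1.0) {
  tpm <- as.matrix(tpm)
  psi <- matrix(NA_real_, nrow = nrow(events), ncol = ncol(tpm),
                dimnames = list(events$event_id, colnames(tpm)))
  for (i in seq_len(nrow(events))) {
    incl <- strsplit(events$inclusion[i], ",", fixed = TRUE)[[1]]
    excl <- strsplit(events$exclusion[i], ",", fixed = TRUE)[[1]]
    if (!all(c(incl, excl) %in% rownames(tpm))) {
      stop("unresolvable transcript id for event ", events$event_id[i])
    }
    inc <- colSums(tpm[incl, , drop = FALSE])
    exc <- colSums(tpm[excl, , drop = FALSE])
    denom <- inc + exc
    val <- inc / denom
    val[denom < floor] <- NA_real_
    psi[i, ] <- val
  }
  psi
}

#' Empirical delta-PSI test between age groups
#'
#' For each event and pairwise group contrast, `dPSI` is the later-group
#' mean PSI minus the earlier-group mean. Significance is empirical: the
#' null pool collects absolute within-group replicate PSI differences
#' (rescaled by `sqrt((1/n1 + 1/n2)/2)` to the sampling scale of a
#' between-group mean difference), stratified into `n_bins` expression bins
#' by the event's mean log2 transcript TPM; `p = (1 + #null >= |dPSI|) /
#' (1 + #null in bin)`, BH-adjusted across events per contrast.
#'
#' @param psi event x sample PSI matrix from [compute_psi()].
#' @param tpm transcript x sample TPM matrix (for expression binning).
#' @param events events table (to resolve transcripts per event).
#' @param groups per-sample group (age) vector aligned with `psi` columns.
#' @param contrasts contrast labels; default all pairwise group comparisons.
#' @param n_bins number of expression strata (default 10).
#' @param alpha significance threshold on BH q (default 0.05).
#' @return data frame per event per contrast: `event_id`, `gene_id`, `type`,
#'   `contrast`, `dpsi`, `p`, `q`, `significant`.
#' @export
test_dpsi <- function(psi, tpm, events, groups, contrasts = NULL,
                      n_bins = 10, alpha = 0.05) {
  stopifnot(length(groups) == ncol(psi))
  groups <- as.numeric(groups)
  if (is.null(contrasts)) {
    cmb <- utils::combn(sort(unique(groups)), 2)
    contrasts <- sprintf("%gv%g", cmb[2, ], cmb[1, ])
  }
  # expression level per event: mean log2(TPM+1) over the event transcripts
  expr <- vapply(seq_len(nrow(events)), function(i) {
    txs <- unique(unlist(strsplit(c(events$inclusion[i], events$exclusion[i]),
                                  ",", fixed = TRUE)))
    mean(log2(tpm[txs, , drop = FALSE] + 1))
  }, numeric(1))
  bins <- if (length(unique(expr)) < n_bins) {
    rep(1L, length(expr))
  } else {
    cut(rank(expr, ties.method = "first"), breaks = n_bins, labels = FALSE)
  }

  res <- lapply(contrasts, function(ct) {
    ages <- as.numeric(strsplit(ct, "v", fixed = TRUE)[[1]])
    ia <- which(groups == ages[1])
    ib <- which(groups == ages[2])
    n1 <- length(ia); n2 <- length(ib)
    scale_fac <- sqrt((1 / n1 + 1 / n2) / 2)
    # pooled within-group null, per expression bin
    null_by_bin <- vector("list", max(bins))
    for (b in seq_len(max(bins))) {
      idx <- which(bins == b)
      vals <- numeric(0)
      for (set in list(ia, ib)) {
        if (length(set) < 2) next
        prs <- utils::combn(set, 2)
        d <- abs(psi[idx, prs[1, ], drop = FALSE] - psi[idx, prs[2, ], drop = FALSE])
        vals <- c(vals, d[!is.na(d)])
      }
      null_by_bin[[b]] <- vals * scale_fac
    }
    global_null <- unlist(null_by_bin)

    m1 <- rowMeans(psi[, ia, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(psi[, ib, drop = FALSE], na.rm = TRUE)
    n_ok1 <- rowSums(!is.na(psi[, ia, drop = FALSE]))
    n_ok2 <- rowSums(!is.na(psi[, ib, drop = FALSE]))
    dpsi <- m1 - m2
    dpsi[n_ok1 < 2 | n_ok2 < 2] <- NA_real_

    p <- rep(NA_real_, nrow(psi))
    for (i in seq_len(nrow(psi))) {
      if (is.na(dpsi[i])) next
      nullv <- null_by_bin[[bins[i]]]
      if (!length(nullv)) nullv <- global_null  # empty-bin fallback
      p[i] <- (1 + sum(nullv >= abs(dpsi[i]))) / (1 + length(nullv))
    }
    q <- bh_adjust(p)
    data.frame(
      event_id = events$event_id, gene_id = events$gene_id,
      type = events$type, contrast = ct,
      dpsi = dpsi, p = p, q = q,
      significant = !is.na(q) & q < alpha,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, res)
}

#' One-sided overlap (Fisher/hypergeometric) test
#'
#' Upper-tail probability of observing at least `n_both` shared elements
#' between a size-`n_a` and a size-`n_b` selection from `universe` items,
#' computed in log space.
#'
#' @param n_a,n_b sizes of the two selections.
#' @param n_both observed overlap.
#' @param universe universe size.
#' @return list with `expected` overlap under independence, `p`, and
#'   `log10_p`.
#' @export
overlap_test <- function(n_a, n_b, n_both, universe) {
  lp <- hyper_upper_log(n_both, n_a, n_b, universe)
  list(expected = n_a * n_b / universe, p = exp(lp), log10_p = lp / log(10))
}

#' Chi-square test of event counts against a uniform expectation
#'
#' Pearson chi-square of observed counts across ordered comparisons versus
#' equal expected counts.
#'
#' @param counts non-negative counts, one per category (>= 2 categories).
#' @return list with `statistic`, `df` and `p`.
#' @export
trend_test <- function(counts) {
  stopifnot(length(counts) >= 2, all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero counts")
  expected <- mean(counts)
  stat <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
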