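## Gene-set enrichment: hypergeometric over-representation analysis (ORA)
## and permutation GSEA over ranked lists of the four regulatory axes
## (total RNA change, translated-RNA change, translation effect, buffering
## effect).

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated gene ids).
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p for the overlap of a selected gene list with
#' each set, against a fixed universe; BH-adjusted across the collection.
#' Uses the same hypergeometric core as [overlap_test()].
#'
#' @param selected selected gene ids (must lie within `universe`).
#' @param gene_sets named list of gene-id vectors.
#' @param universe background gene ids.
#' @return data frame per set: `set`, `set_size` (after universe
#'   intersection), `overlap`, `expected`, `p`, `fdr`. Sets empty after
#'   intersection are dropped.
#' @export
ora <- function(selected, gene_sets, universe) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (!all(selected %in% universe)) stop("selected genes must be in the universe")
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  if (!length(sets)) stop("no gene set intersects the universe")
  n_u <- length(universe)
  n_sel <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    m <- length(sets[[nm]])
    ov <- length(intersect(selected, sets[[nm]]))
    data.frame(
      set = nm, set_size = m, overlap = ov,
      expected = n_sel * m / n_u,
      p = exp(hyper_upper_log(ov, m, n_sel, n_u)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p)
  res[order(res$p), ]
}

#' Ranked gene list for a regulatory axis
#'
#' Scores: `totalRNA` = total-RNA log2 FC, `translated` = polysome log2 FC,
#' `translation` = APV translational effect (gamma), `buffering` = APV
#' buffering effect (gamma_b), all per contrast. Genes are sorted by
#' descending score, ties broken by gene id (stable).
#'
#' @param calls [regmode_analysis()] table (carries all four effects).
#' @param axis one of `"totalRNA"`, `"translated"`, `"translation"`,
#'   `"buffering"`.
#' @param contrast contrast label to extract.
#' @return data frame `gene`, `score`, ranked.
#' @export
rank_genes <- function(calls, axis = c("totalRNA", "translated",
                                       "translation", "buffering"),
                       contrast) {
  axis <- match.arg(axis)
  cc <- calls[calls$contrast == contrast, , drop = FALSE]
  if (!nrow(cc)) stop("contrast not present in calls")
  score <- switch(axis,
    totalRNA = cc$delta_t,
    translated = cc$delta_p,
    translation = cc$gamma,
    buffering = cc$gamma_b
  )
  if (all(is.na(score))) stop("axis effects missing")
  ord <- order(-score, cc$gene)
  data.frame(gene = cc$gene[ord], score = score[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score of one set in a
# ranked list (scores descending). Hit steps proportional to |score|^weight.
gsea_es <- function(in_set, scores, weight = 1) {
  n <- length(scores)
  nh <- sum(in_set)
  if (nh == 0 || nh == n) return(0)
  hit <- abs(scores)^weight * in_set
  denom_hit <- sum(hit)
  if (denom_hit == 0) hit[in_set] <- 1 / nh else hit <- hit / denom_hit
  run <- cumsum(hit - (!in_set) / (n - nh))
  run[which.max(abs(run))]
}

#' Permutation GSEA over a ranked gene list
#'
#' Weighted KS running-sum enrichment scores with a gene-label permutation
#' null: for each set, `n_perm` random same-size sets give the null ES
#' distribution. `NES = ES / mean(|null ES| of matching sign)`; p is the
#' matching-sign permutation tail with a +1 pseudo-count; FDR follows the
#' standard positive/negative-pool normalization of NES.
#'
#' @param ranked data frame `gene`, `score` from [rank_genes()] (descending).
#' @param gene_sets named list of gene-id vectors.
#' @param n_perm permutations (default 1000).
#' @param weight running-sum weight exponent (default 1; 0 = unweighted KS).
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked list (defaults 5 and 500); smaller/larger sets are skipped.
#' @param seed integer seed.
#' @return data frame per retained set: `set`, `size`, `es`, `nes`, `p`,
#'   `fdr`, `direction` (+/-).
#' @export
gsea <- function(ranked, gene_sets, n_perm = 1000, weight = 1,
                 min_size = 5, max_size = 500, seed = 1) {
  genes <- ranked$gene
  scores <- ranked$score
  n <- length(genes)
  sizes <- vapply(gene_sets, function(s) length(intersect(s, genes)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep)) {
    message(sum(!keep), " gene set(s) outside size bounds skipped")
  }
  gene_sets <- gene_sets[keep]
  if (!length(gene_sets)) stop("no gene set within size bounds")

  es <- vapply(gene_sets, function(s) {
    gsea_es(genes %in% s, scores, weight)
  }, numeric(1))

  with_seed(seed, {
    used_sizes <- sort(unique(sizes[keep]))
    null_by_size <- lapply(used_sizes, function(m) {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, m)
        member <- logical(n); member[idx] <- TRUE
        gsea_es(member, scores, weight)
      }, numeric(1))
    })
    names(null_by_size) <- as.character(used_sizes)

    nes <- p <- numeric(length(es))
    null_nes <- numeric(0)
    for (i in seq_along(es)) {
      nullv <- null_by_size[[as.character(sizes[keep][i])]]
      pos_mean <- mean(abs(nullv[nullv >= 0]))
      neg_mean <- mean(abs(nullv[nullv < 0]))
      if (!is.finite(pos_mean) || pos_mean == 0) pos_mean <- 1
      if (!is.finite(neg_mean) || neg_mean == 0) neg_mean <- 1
      if (es[i] >= 0) {
        same <- nullv[nullv >= 0]
        nes[i] <- es[i] / pos_mean
        p[i] <- (1 + sum(same >= es[i])) / (1 + length(same))
      } else {
        same <- nullv[nullv < 0]
        nes[i] <- es[i] / neg_mean
        p[i] <- (1 + sum(same <= es[i])) / (1 + length(same))
      }
      null_nes <- c(null_nes, nullv / ifelse(nullv >= 0, pos_mean, neg_mean))
    }

    fdr <- vapply(seq_along(nes), function(i) {
      if (nes[i] >= 0) {
        num <- mean(null_nes[null_nes >= 0] >= nes[i])
        den <- mean(nes[nes >= 0] >= nes[i])
      } else {
        num <- mean(null_nes[null_nes < 0] <= nes[i])
        den <- mean(nes[nes < 0] <= nes[i])
      }
      if (!is.finite(den) || den == 0) return(1)
      min(1, num / den)
    }, numeric(1))

    data.frame(
      set = names(gene_sets), size = sizes[keep],
      es = es, nes = nes, p = p, fdr = fdr,
      direction = ifelse(es >= 0, "+", "-"),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
}
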