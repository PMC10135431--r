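# Shared fixture builders (all generated in code; no stored data).

# Small two-group count matrix with named dimensions.
toy_counts <- function(n_genes = 50, n_samples = 6, lambda = 100, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_samples, lambda), n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  })
}

# Independent brute-force TMM factor for one sample against a reference
# column (Robinson-Oshlack definition), used as an oracle.
brute_tmm_pair <- function(obs, ref) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  No <- sum(obs); Nr <- sum(ref)
  M <- log2((obs / No) / (ref / Nr))
  A <- 0.5 * (log2(obs / No) + log2(ref / Nr))
  w <- 1 / ((No - obs) / (No * obs) + (Nr - ref) / (Nr * ref))
  lm <- quantile(M, c(0.3, 0.7), type = 7)
  la <- quantile(A, c(0.05, 0.95), type = 7)
  keep2 <- M >= lm[1] & M <= lm[2] & A >= la[1] & A <= la[2]
  2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
}

# Adjusted Rand index (simple exact implementation; cross-checked against
# mclust in the trajectory tests).
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Reflect a toy annotation around a fixed span, optionally flipping strand.
# Reflect+flip yields the identical molecule (event types preserved);
# reflect-only swaps donor/acceptor sides (A5<->A3, AF<->AL).
reflect_annotation <- function(ann, span = 1e7, flip_strand = TRUE) {
  out <- ann
  out$start <- span - ann$end
  out$end <- span - ann$start
  if (flip_strand) out$strand <- ifelse(ann$strand == "+", "-", "+")
  class(out) <- c("toy_annotation", "data.frame")
  out
}
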