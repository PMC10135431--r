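#' @keywords internal
"_PACKAGE"

## Shared low-level helpers: seeded evaluation, the hypergeometric core used
## by both the splicing overlap test and ORA, and TSV I/O with `#` metadata
## headers.

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive a stream-specific child seed from a master seed. Kept below 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483587L
}

# Upper-tail hypergeometric log-probability: P(X >= n_both) where X counts
# elements of a size-n_A set falling in a size-n_B set drawn from `universe`.
# Shared by overlap_test() (splicing) and ora() (enrichment).
hyper_upper_log <- function(n_both, n_a, n_b, universe) {
  stopifnot(
    n_both >= 0, n_a >= 0, n_b >= 0,
    n_both <= min(n_a, n_b), max(n_a, n_b) <= universe
  )
  if (n_both == 0) return(0) # log(1)
  stats::phyper(n_both - 1, n_a, universe - n_a, n_b, lower.tail = FALSE,
                log.p = TRUE)
}

#' Write a TSV table with `#`-prefixed metadata header lines
#'
#' All pipeline outputs are plain TSV. Parameter provenance is recorded as
#' `# key: value` comment lines above the column header so downstream tools
#' that skip comments read the table unchanged.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @param meta named list of scalar metadata values echoed into the header.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(meta)) {
    for (k in names(meta)) {
      writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = ",")), con)
    }
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv_meta()]
#'
#' @param path file path.
#' @return data frame (metadata comment lines are skipped).
#' @export
read_tsv_meta <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Matrix -> data frame with an id first column (for TSV output).
matrix_to_df <- function(m, id_name = "gene_id") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  rownames(df) <- NULL
  df
}

# data frame (id first column) -> matrix.
df_to_matrix <- function(df) {
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# Benjamini-Hochberg wrapper kept in one place so every module adjusts the
# same way (NAs preserved).
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
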