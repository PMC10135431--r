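## Toy transcript annotation.
##
## A toy annotation is an exon table: one row per exon with columns
## `gene_id`, `transcript_id`, `seqnames`, `start`, `end` (1-based inclusive,
## GTF convention), `strand`. Gene models are built in transcription-direction
## local coordinates and reflected for minus-strand genes, so every event
## type exists on both strands and strand handling is exercised end to end.

# Local-coordinate templates (plus strand, transcription direction).
# Each template is a list of transcripts; each transcript a 2-column matrix
# of (start, end). The first transcript is the inclusion form of the event.
event_templates <- function() {
  list(
    SE = list(t1 = rbind(c(100, 200), c(300, 400), c(500, 600)),
              t2 = rbind(c(100, 200), c(500, 600))),
    A5 = list(t1 = rbind(c(100, 250), c(400, 500)),
              t2 = rbind(c(100, 200), c(400, 500))),
    A3 = list(t1 = rbind(c(100, 200), c(300, 500)),
              t2 = rbind(c(100, 200), c(350, 500))),
    MX = list(t1 = rbind(c(100, 200), c(300, 400), c(700, 800)),
              t2 = rbind(c(100, 200), c(500, 600), c(700, 800))),
    RI = list(t1 = rbind(c(100, 400)),
              t2 = rbind(c(100, 200), c(300, 400))),
    AF = list(t1 = rbind(c(100, 150), c(500, 600)),
              t2 = rbind(c(250, 300), c(500, 600))),
    AL = list(t1 = rbind(c(100, 200), c(500, 550)),
              t2 = rbind(c(100, 200), c(700, 750)))
  )
}

# Two transcripts sharing all introns but ending at 3' ends 100 nt apart:
# two distinct polyadenylation sites, no splicing event.
apa_template <- function() {
  list(t1 = rbind(c(100, 200), c(300, 400)),
       t2 = rbind(c(100, 200), c(300, 500)))
}

# Reflect a local-coordinate transcript around a span of length L so that a
# plus-strand construction becomes the equivalent minus-strand gene.
reflect_exons <- function(exons, L = 1000) {
  out <- cbind(L - exons[, 2], L - exons[, 1])
  out[order(out[, 1]), , drop = FALSE]
}

#' Build a toy annotation with planted splicing and APA structure
#'
#' Emits gene models realizing each of the seven alternative-splicing event
#' types (SE, A5, A3, MX, RI, AF, AL) plus genes with two distinct
#' polyadenylation sites (terminal 3' ends > 25 nt apart). Strands alternate
#' across genes so both orientations are represented.
#'
#' @param n_genes_per_event_type genes to emit per event type (>= 1).
#' @param n_apa_genes genes with two APA sites (>= 1).
#' @param seed integer seed; genes beyond the first of each type receive
#'   seeded coordinate jitter so repeated calls are reproducible.
#' @return data frame of exons (class `toy_annotation`) with columns
#'   `gene_id`, `transcript_id`, `seqnames`, `start`, `end`, `strand`, and an
#'   attribute `event_type` mapping event/APA genes to the planted structure.
#' @examples
#' ann <- build_toy_annotation(1, 1, seed = 1)
#' subset(ann, gene_id == "gSE1")
#' @export
build_toy_annotation <- function(n_genes_per_event_type = 1, n_apa_genes = 1,
                                 seed = 1) {
  stopifnot(n_genes_per_event_type >= 1, n_apa_genes >= 1)
  templates <- event_templates()
  specs <- c(
    lapply(names(templates), function(ty) list(type = ty, n = n_genes_per_event_type)),
    list(list(type = "APA", n = n_apa_genes))
  )
  with_seed(seed, {
    rows <- list()
    gene_types <- character()
    gene_index <- 0L
    for (sp in specs) {
      tmpl <- if (sp$type == "APA") apa_template() else templates[[sp$type]]
      for (i in seq_len(sp$n)) {
        gene_index <- gene_index + 1L
        gid <- sprintf("g%s%d", sp$type, i)
        gene_types[gid] <- sp$type
        strand <- if (gene_index %% 2L == 1L) "+" else "-"
        offset <- (gene_index - 1L) * 10000L
        jitter <- if (i == 1L) 0L else sample.int(50L, 1L)
        for (tn in names(tmpl)) {
          ex <- tmpl[[tn]]
          if (strand == "-") ex <- reflect_exons(ex)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = gid,
            transcript_id = paste0(gid, ".", tn),
            seqnames = "chrS",
            start = ex[, 1] + offset + jitter,
            end = ex[, 2] + offset + jitter,
            strand = strand,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    ann <- do.call(rbind, rows)
    rownames(ann) <- NULL
    attr(ann, "event_type") <- gene_types
    class(ann) <- c("toy_annotation", "data.frame")
    validate_annotation(ann)
    ann
  })
}

# Structural checks shared by generated and imported annotations.
validate_annotation <- function(ann) {
  need <- c("gene_id", "transcript_id", "seqnames", "start", "end", "strand")
  if (!all(need %in% names(ann))) stop("annotation lacks required columns")
  if (any(ann$end < ann$start)) stop("malformed exon: end < start")
  for (tx in split(ann, ann$transcript_id)) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) > 1 && any(tx$start[-1] <= tx$end[-nrow(tx)])) {
      stop("malformed transcript (overlapping exons): ", tx$transcript_id[1])
    }
    if (length(unique(tx$strand)) != 1) stop("mixed strand within transcript")
  }
  invisible(ann)
}

# Exon chains per transcript: list of matrices (start, end) sorted by
# coordinate, plus strand/gene lookup tables.
transcript_chains <- function(ann) {
  ann <- ann[order(ann$transcript_id, ann$start), ]
  chains <- lapply(split(seq_len(nrow(ann)), ann$transcript_id), function(idx) {
    cbind(start = ann$start[idx], end = ann$end[idx])
  })
  first <- !duplicated(ann$transcript_id)
  info <- ann[first, c("transcript_id", "gene_id", "strand", "seqnames")]
  rownames(info) <- info$transcript_id
  list(chains = chains, info = info)
}

#' Write an annotation as GTF
#'
#' Exon rows only, 1-based inclusive coordinates, `gene_id`/`transcript_id`
#' attributes (standard GTF).
#'
#' @param ann annotation data frame as from [build_toy_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$seqnames,
    ranges = IRanges::IRanges(ann$start, ann$end),
    strand = ann$strand
  )
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "polysomics"
  S4Vectors::mcols(gr)$gene_id <- ann$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ann$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read exon models from a GTF file
#'
#' @param path GTF file; rows with `type == "exon"` are used.
#' @return annotation data frame in the same layout as
#'   [build_toy_annotation()].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  ann <- data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("toy_annotation", "data.frame")
  validate_annotation(ann)
  ann
}
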