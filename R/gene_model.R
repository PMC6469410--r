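#' Gene model container
#'
#' A `gene_model` holds a gene -> transcript -> exon hierarchy over a genome.
#' Exons of a transcript are kept sorted by start and must be disjoint;
#' introns are derived as the gaps between consecutive exons.  Every feature
#' carries a `provenance` flag, `"annotated"` for features read from the
#' input annotation and `"novel"` for features added by
#' [augment_model()].
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `provenance`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `provenance`.
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `provenance`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(genes = empty_genes(), transcripts = empty_transcripts(),
                       exons = empty_exons()) {
  m <- structure(list(genes = genes, transcripts = transcripts, exons = exons),
                 class = "gene_model")
  validate_gene_model(m)
}

empty_genes <- function() {
  data.frame(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), provenance = character(),
             stringsAsFactors = FALSE)
}
empty_transcripts <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             provenance = character(), stringsAsFactors = FALSE)
}
empty_exons <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), provenance = character(),
             stringsAsFactors = FALSE)
}

validate_gene_model <- function(m) {
  ex <- m$exons
  if (nrow(ex) > 0L) {
    validate_intervals(ex)
    ord <- order(ex$transcript_id, ex$start)
    ex <- ex[ord, , drop = FALSE]
    # disjoint within transcript
    by_tx <- split(seq_len(nrow(ex)), ex$transcript_id)
    for (idx in by_tx) {
      if (length(idx) > 1L) {
        s <- ex$start[idx]; e <- ex$end[idx]
        if (any(s[-1L] < e[-length(e)])) {
          stop("overlapping exons within transcript ", ex$transcript_id[idx[1L]])
        }
      }
    }
    orphan <- !ex$transcript_id %in% m$transcripts$transcript_id
    if (any(orphan)) {
      stop("exon with unknown Parent transcript: ", ex$transcript_id[orphan][1L])
    }
    m$exons <- ex
  }
  if (nrow(m$transcripts) > 0L) {
    orphan <- !m$transcripts$gene_id %in% m$genes$gene_id
    if (any(orphan)) {
      stop("transcript with unknown Parent gene: ",
           m$transcripts$transcript_id[orphan][1L])
    }
  }
  rownames(m$genes) <- rownames(m$transcripts) <- rownames(m$exons) <- NULL
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons",
      sprintf("(%d novel)\n", sum(x$exons$provenance == "novel")))
  invisible(x)
}

#' Derived introns of a gene model
#'
#' Introns are the gaps between consecutive exons of each transcript, in
#' 0-based half-open coordinates (first intronic base to one past the last).
#' Flanking exon coordinates are carried along so inclusion-ratio formulas
#' can be evaluated without another lookup: `a`,`b` bound the upstream (in
#' genome order) exon and `c`,`d` the downstream one, so the intron itself
#' is `b`..`c`.
#'
#' @param model a [gene_model()].
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `a`, `b`, `c`, `d`.
#' @export
model_introns <- function(model) {
  ex <- model$exons
  out <- data.frame(transcript_id = character(), gene_id = character(),
                    chrom = character(), start = integer(), end = integer(),
                    strand = character(), a = integer(), b = integer(),
                    c = integer(), d = integer(), stringsAsFactors = FALSE)
  if (nrow(ex) == 0L) return(out)
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  parts <- split(ex, ex$transcript_id)
  res <- lapply(parts, function(e) {
    k <- nrow(e)
    if (k < 2L) return(NULL)
    data.frame(transcript_id = e$transcript_id[1L], gene_id = e$gene_id[1L],
               chrom = e$chrom[1L], start = e$end[-k], end = e$start[-1L],
               strand = e$strand[1L],
               a = e$start[-k], b = e$end[-k],
               c = e$start[-1L], d = e$end[-1L],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start, res$end), , drop = FALSE]
}

#' Annotated exon boundary sets of a model
#'
#' Returns, per chromosome+strand, the set of intron-start boundaries (exon
#' ends) and intron-end boundaries (exon starts) used to classify splice
#' junction sites as known or novel.
#' @noRd
boundary_key <- function(chrom, strand, pos) paste(chrom, strand, pos)

model_boundaries <- function(model) {
  ex <- model$exons
  list(
    starts = unique(boundary_key(ex$chrom, ex$strand, ex$end)),   # intron starts
    ends = unique(boundary_key(ex$chrom, ex$strand, ex$start))    # intron ends
  )
}
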