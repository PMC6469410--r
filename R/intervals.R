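#' Genomic intervals
#'
#' All coordinates inside the package are 0-based half-open: `start` is the
#' first base of the feature, `end` is one past the last.  GFF3 on disk is
#' 1-based closed and is converted at the I/O boundary, nowhere else.
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("interval start must be < end")
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

#' @return logical: does any interval in `a` overlap any in `b` (same chrom;
#'   strand ignored unless `stranded`)?
#' @noRd
overlaps_any <- function(chrom, start, end, b, stranded = FALSE, strand = NULL) {
  if (nrow(b) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    hit <- b$chrom == chrom[i] & b$start < end[i] & b$end > start[i]
    if (stranded && !is.null(strand)) hit <- hit & b$strand == strand[i]
    any(hit)
  }, logical(1))
}

# extract the + strand sequence of a 0-based half-open interval
interval_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0L || end > len) stop("interval off chromosome end")
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}
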