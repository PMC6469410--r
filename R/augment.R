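#' Filter and partition splice junctions against a gene model
#'
#' Junctions with confidence score <= `min_score` are discarded (strictly
#' greater than the threshold is required, so a score of exactly 0.5 is
#' dropped at the default).  Survivors are partitioned by whether both, one,
#' or neither splice site matches an annotated exon boundary of the model on
#' the same chromosome and strand (exact coordinate match): a junction start
#' is known when it equals some exon end, a junction end when it equals some
#' exon start.
#'
#' @param junctions junction data.frame ([read_junctions()]).
#' @param model a [gene_model()].
#' @param min_score confidence threshold; junctions must score strictly
#'   above it to be retained (default 0.5).
#' @return list with elements `known`, `half_known`, `both_novel`, each a
#'   junction data.frame; `half_known` gains a `novel_side` column
#'   (`"start"` or `"end"`).
#' @export
filter_junctions <- function(junctions, model, min_score = 0.5) {
  j <- junctions[junctions$score > min_score, , drop = FALSE]
  b <- model_boundaries(model)
  start_known <- boundary_key(j$chrom, j$strand, j$start) %in% b$starts
  end_known <- boundary_key(j$chrom, j$strand, j$end) %in% b$ends
  known <- j[start_known & end_known, , drop = FALSE]
  half <- j[xor(start_known, end_known), , drop = FALSE]
  half$novel_side <- ifelse(start_known[xor(start_known, end_known)],
                            "end", "start")
  novel <- j[!start_known & !end_known, , drop = FALSE]
  rownames(known) <- rownames(half) <- rownames(novel) <- NULL
  list(known = known, half_known = half, both_novel = novel)
}

#' Find transcribed islands in a coverage track
#'
#' A transcribed island is a maximal run of bases with depth >=
#' `min_depth`; runs separated by gaps of at most `max_gap` low-coverage
#' bases are merged, and merged runs shorter than `min_len` are dropped.
#' Islands overlapping any annotated exon of `model` (either strand) are
#' discarded: they are evidence for novel, not known, transcription.
#'
#' @param coverage a `coverage_track`.
#' @param model a [gene_model()] whose exons mask known transcription.
#' @param min_depth minimum per-base depth (default 5).
#' @param min_len minimum island length in bp (default 50).
#' @param max_gap maximum low-coverage gap bridged when merging (default 10).
#' @return data.frame of intervals (`chrom`, `start`, `end`, `strand = "."`).
#' @export
find_transcribed_islands <- function(coverage, model, min_depth = 5,
                                     min_len = 50, max_gap = 10) {
  out <- list()
  for (cn in sort(names(coverage))) {
    v <- coverage[[cn]] >= min_depth
    if (!any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge runs separated by short gaps
    if (nrow(runs) > 1L) {
      gap <- runs$start[-1L] - runs$end[-nrow(runs)]
      grp <- cumsum(c(0L, as.integer(gap > max_gap)))
      runs <- data.frame(start = tapply(runs$start, grp, min),
                         end = tapply(runs$end, grp, max))
    }
    runs <- runs[runs$end - runs$start >= min_len, , drop = FALSE]
    if (nrow(runs) > 0L) {
      out[[cn]] <- data.frame(chrom = cn, start = as.integer(runs$start),
                              end = as.integer(runs$end), strand = ".",
                              stringsAsFactors = FALSE)
    }
  }
  isl <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  rownames(isl) <- NULL
  if (nrow(isl) == 0L) return(isl)
  hit <- overlaps_any(isl$chrom, isl$start, isl$end, model$exons)
  isl <- isl[!hit, , drop = FALSE]
  rownames(isl) <- NULL
  isl
}

#' Augment a gene model with novel exons and intergenic transcripts
#'
#' Two augmentation routes, both additive (annotated features are never
#' modified or removed):
#'
#' * a half-known junction whose novel end falls inside a transcribed
#'   island creates a novel exon bounded by the junction end (exact) and the
#'   island edge, attached to the gene owning the known side as a new
#'   two-exon novel transcript;
#' * a both-novel junction bridging two islands in intergenic space (no
#'   overlap with any annotated gene span, either strand) creates a novel
#'   two-exon transcript in a new novel gene.
#'
#' Novel exons that would overlap an annotated exon on the same strand, or
#' that already exist in the model, are skipped, which also makes the
#' operation idempotent.  When a junction record carries strand `"."` the
#' strand is inferred from the GT/AG orientation of its terminal
#' dinucleotides in `genome`.
#'
#' @param model a [gene_model()].
#' @param partition junction partition from [filter_junctions()].
#' @param islands island intervals from [find_transcribed_islands()].
#' @param genome optional `DNAStringSet` for strand inference.
#' @return The augmented [gene_model()]; additions carry
#'   `provenance = "novel"`.
#' @export
augment_model <- function(model, partition, islands, genome = NULL) {
  half <- partition$half_known
  novel <- partition$both_novel
  island_hit <- function(chrom, pos) {
    which(islands$chrom == chrom & islands$start <= pos & islands$end > pos)
  }
  infer_strand <- function(chrom, start, end, strand) {
    if (strand != "." || is.null(genome)) return(strand)
    don <- interval_seq(genome, chrom, start, start + 2L)
    acc <- interval_seq(genome, chrom, end - 2L, end)
    if (don == "GT" && acc == "AG") "+"
    else if (don == "CT" && acc == "AC") "-" else "."
  }
  exon_exists <- function(chrom, start, end, strand) {
    any(model$exons$chrom == chrom & model$exons$start == start &
          model$exons$end == end & model$exons$strand == strand)
  }
  exon_clash <- function(chrom, start, end, strand) {
    any(model$exons$chrom == chrom & model$exons$strand == strand &
          model$exons$start < end & model$exons$end > start &
          !(model$exons$start == start & model$exons$end == end))
  }
  novel_counter <- sum(model$transcripts$provenance == "novel")
  add_transcript <- function(gene_id, chrom, strand, exon_list) {
    novel_counter <<- novel_counter + 1L
    tid <- sprintf("%s.nov%d", gene_id, novel_counter)
    model$transcripts <<- rbind(model$transcripts, data.frame(
      transcript_id = tid, gene_id = gene_id, provenance = "novel",
      stringsAsFactors = FALSE))
    for (e in exon_list) {
      model$exons <<- rbind(model$exons, data.frame(
        transcript_id = tid, gene_id = gene_id, chrom = chrom,
        start = e[1L], end = e[2L], strand = strand, provenance = "novel",
        stringsAsFactors = FALSE))
    }
    gi <- model$genes$gene_id == gene_id
    if (any(gi)) {
      lo <- min(vapply(exon_list, `[`, integer(1), 1L))
      hi <- max(vapply(exon_list, `[`, integer(1), 2L))
      model$genes$start[gi] <<- min(model$genes$start[gi], lo)
      model$genes$end[gi] <<- max(model$genes$end[gi], hi)
    }
  }

  # route 1: half-known junction whose novel end lands in an island
  for (i in seq_len(nrow(half))) {
    chrom <- half$chrom[i]
    strand <- infer_strand(chrom, half$start[i], half$end[i], half$strand[i])
    if (strand == ".") next
    if (half$novel_side[i] == "end") {
      hit <- island_hit(chrom, half$end[i])
      if (length(hit) == 0L) next
      isl <- islands[hit[1L], ]
      new_exon <- c(half$end[i], isl$end)        # junction-side edge exact
      anchor <- model$exons[model$exons$chrom == chrom &
                              model$exons$strand == strand &
                              model$exons$end == half$start[i], , drop = FALSE]
    } else {
      hit <- island_hit(chrom, half$start[i] - 1L)
      if (length(hit) == 0L) next
      isl <- islands[hit[1L], ]
      new_exon <- c(isl$start, half$start[i])
      anchor <- model$exons[model$exons$chrom == chrom &
                              model$exons$strand == strand &
                              model$exons$start == half$end[i], , drop = FALSE]
    }
    if (new_exon[1L] >= new_exon[2L] || nrow(anchor) == 0L) next
    if (exon_exists(chrom, new_exon[1L], new_exon[2L], strand)) next
    if (exon_clash(chrom, new_exon[1L], new_exon[2L], strand)) {
      message("skipping novel exon overlapping annotated exon at ", chrom,
              ":", new_exon[1L], "-", new_exon[2L])
      next
    }
    anchor <- anchor[1L, ]
    add_transcript(anchor$gene_id, chrom, strand,
                   list(c(anchor$start, anchor$end), new_exon))
  }

  # route 2: both-novel junction bridging two intergenic islands
  for (i in seq_len(nrow(novel))) {
    chrom <- novel$chrom[i]
    strand <- infer_strand(chrom, novel$start[i], novel$end[i],
                           novel$strand[i])
    if (strand == ".") next
    h1 <- island_hit(chrom, novel$start[i] - 1L)
    h2 <- island_hit(chrom, novel$end[i])
    if (length(h1) == 0L || length(h2) == 0L || h1[1L] == h2[1L]) next
    e1 <- c(islands$start[h1[1L]], novel$start[i])
    e2 <- c(novel$end[i], islands$end[h2[1L]])
    if (e1[1L] >= e1[2L] || e2[1L] >= e2[2L]) next
    span_lo <- e1[1L]; span_hi <- e2[2L]
    genic <- overlaps_any(chrom, span_lo, span_hi, model$genes)
    if (genic) next
    if (exon_exists(chrom, e1[1L], e1[2L], strand) &&
          exon_exists(chrom, e2[1L], e2[2L], strand)) next
    gid <- sprintf("novelgene_%s_%d_%d", chrom, span_lo, span_hi)
    if (gid %in% model$genes$gene_id) next
    model$genes <- rbind(model$genes, data.frame(
      gene_id = gid, chrom = chrom, start = span_lo, end = span_hi,
      strand = strand, provenance = "novel", stringsAsFactors = FALSE))
    add_transcript(gid, chrom, strand, list(e1, e2))
  }

  validate_gene_model(model)
}
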