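#' CpG observed/expected ratio of a region
#'
#' CpG(o/e) = P_CpG / (P_C x P_G), with P_CpG the frequency of overlapping
#' CG dinucleotides over the L-1 dinucleotide windows of the region and
#' P_C, P_G the base frequencies over its L bases, computed on the plus
#' strand regardless of feature strand (a CpG is its own reverse
#' complement).  Low values indicate CpG depletion, the evolutionary
#' footprint of germline hyper-methylation; values near 1 indicate no
#' depletion.
#'
#' @param genome a `DNAStringSet`.
#' @param chrom,start,end region, 0-based half-open, length >= 2.
#' @return list with `p_cpg`, `p_c`, `p_g`, `oe` (`NA` when the region has
#'   no C or no G, or contains only N).
#' @export
cpg_oe <- function(genome, chrom, start, end) {
  if (end - start < 2L) stop("region too short for dinucleotide counting")
  s <- interval_seq(genome, chrom, start, end)
  cpg_oe_seq(s)
}

# sequence-level worker, exported for direct use on character sequences
#' @param sequence character DNA string (used instead of a genome region).
#' @rdname cpg_oe
#' @export
cpg_oe_seq <- function(sequence) {
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < 2L) stop("sequence too short for dinucleotide counting")
  dna <- Biostrings::DNAString(s)
  n_valid <- sum(Biostrings::alphabetFrequency(dna)[c("A", "C", "G", "T")])
  if (n_valid == 0L) {
    return(list(p_cpg = NA_real_, p_c = NA_real_, p_g = NA_real_,
                oe = NA_real_))
  }
  n_cg <- Biostrings::countPattern("CG", dna)
  p_cpg <- n_cg / (L - 1L)
  p_c <- Biostrings::countPattern("C", dna) / L
  p_g <- Biostrings::countPattern("G", dna) / L
  oe <- if (p_c > 0 && p_g > 0) p_cpg / (p_c * p_g) else NA_real_
  list(p_cpg = p_cpg, p_c = p_c, p_g = p_g, oe = oe)
}

#' Relative CpG score of an alternative-exon-boundary event
#'
#' The absolute difference between CpG(o/e) of the exon built with one
#' boundary variant and CpG(o/e) of the exon built with the other,
#' capturing how much the boundary region shifts the exon's methylation
#' proxy.  Symmetric in the two variants, so major/minor ranking does not
#' matter; a degenerate event with identical boundaries scores 0.
#'
#' @param events AEB event data.frame (rows with `p2` or `q2` set).
#' @param genome a `DNAStringSet`.
#' @return numeric vector of relative CpG scores (>= 0, `NA` when either
#'   exon variant has an undefined o/e).
#' @export
relative_cpg_for_aeb <- function(events, genome) {
  vapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    if (!is.na(ev$p2)) {
      e1 <- c(ev$p, ev$q); e2 <- c(ev$p2, ev$q)
    } else if (!is.na(ev$q2)) {
      e1 <- c(ev$p, ev$q); e2 <- c(ev$p, ev$q2)
    } else {
      return(NA_real_)
    }
    if (identical(e1, e2)) return(0)
    o1 <- cpg_oe(genome, ev$chrom, e1[1L], e1[2L])$oe
    o2 <- cpg_oe(genome, ev$chrom, e2[1L], e2[2L])$oe
    if (is.na(o1) || is.na(o2)) return(NA_real_)
    abs(o1 - o2)
  }, numeric(1))
}

#' Classify a region's methylation status from bisulfite calls
#'
#' `"methylated"` when at least one covered CpG cytosine in the region has
#' a methylated read count above zero; `"unmethylated"` when the region
#' contains covered CpGs and none is methylated; `"no_data"` when no
#' covered CpG falls in the region.  A methylated C on either strand of a
#' CpG marks the pair.
#'
#' @param chrom,start,end region, 0-based half-open.
#' @param methylation methylation data.frame ([read_methylation()]).
#' @param min_total minimum total read count for a call to count as
#'   covered (default 1).
#' @return one of `"methylated"`, `"unmethylated"`, `"no_data"`.
#' @export
region_methylation_status <- function(chrom, start, end, methylation,
                                      min_total = 1L) {
  hit <- methylation[methylation$chrom == chrom & methylation$pos >= start &
                       methylation$pos < end &
                       methylation$total >= min_total, , drop = FALSE]
  if (nrow(hit) == 0L) return("no_data")
  if (any(hit$methylated > 0L)) "methylated" else "unmethylated"
}

#' CpG / methylation level versus inclusion ratio
#'
#' Bins events by inclusion ratio and reports per-bin medians of the
#' methylation proxy: relative CpG score for AEB events, region CpG(o/e)
#' for cassette exons (the exon) and retained introns (the intron).  The
#' lowest and highest occupied bins are compared with a Mann-Whitney test.
#' For IR events a two-tailed t-test of retained-intron CpG(o/e) against
#' CpG(o/e) of all annotated introns is added when `model` is supplied.
#'
#' @param events event data.frame with `inclusion_ratio` filled.
#' @param genome a `DNAStringSet`.
#' @param bins inclusion-ratio bin edges.
#' @param model optional [gene_model()] supplying the all-introns reference
#'   set for the IR t-test.
#' @return list with `table`, `tests` (as in [strength_vs_inclusion()])
#'   and, when computed, `ir_ttest` (list with `p_value`,
#'   `median_retained`, `median_all`).
#' @export
methylation_vs_inclusion <- function(events, genome,
                                     bins = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                                     model = NULL) {
  rows <- list()
  aeb <- events[events$kind %in% c("ALT_DONOR", "ALT_ACCEPTOR") &
                  !is.na(events$inclusion_ratio), , drop = FALSE]
  if (nrow(aeb) > 0L) {
    rel <- relative_cpg_for_aeb(aeb, genome)
    rows[[length(rows) + 1L]] <- data.frame(
      family = "AEB", site = "relative_cpg", ratio = aeb$inclusion_ratio,
      score = rel, stringsAsFactors = FALSE)
  }
  for (kind in c("CE", "IR")) {
    sub <- events[events$kind == kind & !is.na(events$inclusion_ratio), ,
                  drop = FALSE]
    if (nrow(sub) == 0L) next
    oe <- vapply(seq_len(nrow(sub)), function(i) {
      cpg_oe(genome, sub$chrom[i], sub$p[i], sub$q[i])$oe
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      family = kind, site = "cpg_oe", ratio = sub$inclusion_ratio,
      score = oe, stringsAsFactors = FALSE)
  }
  out <- binned_comparison(rows, bins, "ratio")
  ir <- events[events$kind == "IR", , drop = FALSE]
  if (!is.null(model) && nrow(ir) > 0L) {
    all_introns <- unique(model_introns(model)[, c("chrom", "start", "end")])
    oe_all <- vapply(seq_len(nrow(all_introns)), function(i) {
      cpg_oe(genome, all_introns$chrom[i], all_introns$start[i],
             all_introns$end[i])$oe
    }, numeric(1))
    oe_ret <- vapply(seq_len(nrow(ir)), function(i) {
      cpg_oe(genome, ir$chrom[i], ir$p[i], ir$q[i])$oe
    }, numeric(1))
    oe_all <- oe_all[!is.na(oe_all)]; oe_ret <- oe_ret[!is.na(oe_ret)]
    if (length(oe_ret) >= 2L && length(oe_all) >= 2L) {
      tt <- stats::t.test(oe_ret, oe_all, alternative = "two.sided")
      out$ir_ttest <- list(p_value = tt$p.value,
                           median_retained = stats::median(oe_ret),
                           median_all = stats::median(oe_all))
    }
  }
  out
}

#' Methylation status breakdown of AS event regions
#'
#' Classifies every event region ([region_methylation_status()]) and
#' reports counts and mean CpG(o/e) per status class.
#'
#' @param events event data.frame.
#' @param genome a `DNAStringSet`.
#' @param methylation methylation data.frame.
#' @return data.frame with columns `status`, `n`, `mean_cpg_oe`.
#' @export
methylation_status_summary <- function(events, genome, methylation) {
  if (nrow(events) == 0L) {
    return(data.frame(status = character(), n = integer(),
                      mean_cpg_oe = numeric(), stringsAsFactors = FALSE))
  }
  status <- character(nrow(events)); oe <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    reg <- c(ev$p, ev$q)
    status[i] <- region_methylation_status(ev$chrom, reg[1L], reg[2L],
                                           methylation)
    oe[i] <- cpg_oe(genome, ev$chrom, reg[1L], reg[2L])$oe
  }
  out <- data.frame(status = sort(unique(status)), stringsAsFactors = FALSE)
  out$n <- vapply(out$status, function(s) sum(status == s), integer(1))
  out$mean_cpg_oe <- vapply(out$status, function(s)
    mean(oe[status == s], na.rm = TRUE), numeric(1))
  rownames(out) <- NULL
  out
}
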