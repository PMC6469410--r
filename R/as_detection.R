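#' Alternative-splicing event records
#'
#' Events are rows of a data.frame using the three-exon coordinate scheme:
#' upstream exon `a`..`b`, event exon/intron `p`..`q` (with alternative
#' boundaries `p2`/`q2` where applicable), downstream exon `c`..`d`, all
#' 0-based half-open genome coordinates.  `kind` is one of `IR`, `CE`,
#' `ALT_DONOR`, `ALT_ACCEPTOR`, `AFE`, `ALE`.  Donor/acceptor labels are in
#' transcription orientation: on the minus strand the donor lies at the
#' genome-rightmost end of its intron.
#' @noRd
empty_events <- function() {
  data.frame(kind = character(), gene_id = character(), chrom = character(),
             strand = character(), a = integer(), b = integer(),
             p = integer(), q = integer(), p2 = integer(), q2 = integer(),
             c = integer(), d = integer(), displacement = integer(),
             inclusion_ratio = numeric(), splicing_ratio = numeric(),
             stringsAsFactors = FALSE)
}

event_row <- function(kind, gene_id, chrom, strand, a = NA, b = NA, p = NA,
                      q = NA, p2 = NA, q2 = NA, c = NA, d = NA,
                      displacement = NA) {
  data.frame(kind = kind, gene_id = gene_id, chrom = chrom, strand = strand,
             a = as.integer(a), b = as.integer(b), p = as.integer(p),
             q = as.integer(q), p2 = as.integer(p2), q2 = as.integer(q2),
             c = as.integer(c), d = as.integer(d),
             displacement = as.integer(displacement),
             inclusion_ratio = NA_real_, splicing_ratio = NA_real_,
             stringsAsFactors = FALSE)
}

bind_events <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
  if (length(lst) == 0L) return(empty_events())
  out <- do.call(rbind, lst)
  # per-gene dedup on (kind, coordinates)
  key <- do.call(paste, out[c("kind", "gene_id", "chrom", "strand", "a", "b",
                              "p", "q", "p2", "q2", "c", "d")])
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chrom, out$kind, out$gene_id, out$p, out$q), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# support of junction (chrom, start, end, strand); missing junction -> 0
junction_support <- function(junctions, chrom, start, end, strand) {
  hit <- junctions$chrom == chrom & junctions$start == start &
    junctions$end == end & junctions$strand == strand
  if (!any(hit)) 0L else sum(junctions$support[hit])
}

#' Detect cassette exons
#'
#' A junction whose both ends are annotated boundaries of non-adjacent
#' exons of one transcript is evidence of exon skipping: every annotated
#' exon lying strictly between the joined exons is emitted as a cassette
#' exon (CE).  Duplicate calls across transcripts of a gene are collapsed.
#'
#' @param model a [gene_model()].
#' @param junctions score-filtered junction data.frame (see
#'   [filter_junctions()]).
#' @return event data.frame (`kind == "CE"`) with flanking exon coordinates
#'   `a`..`b` and `c`..`d` and the cassette exon at `p`..`q`.
#' @export
detect_ce <- function(model, junctions) {
  ex <- model$exons[order(model$exons$transcript_id, model$exons$start), ,
                    drop = FALSE]
  by_tx <- split(ex, ex$transcript_id)
  events <- list()
  for (jx in seq_len(nrow(junctions))) {
    jc <- junctions[jx, ]
    for (e in by_tx) {
      if (nrow(e) < 3L || e$chrom[1L] != jc$chrom || e$strand[1L] != jc$strand)
        next
      i <- match(jc$start, e$end)
      k <- match(jc$end, e$start)
      if (is.na(i) || is.na(k) || k <= i + 1L) next
      for (m in (i + 1L):(k - 1L)) {
        events[[length(events) + 1L]] <- event_row(
          "CE", e$gene_id[1L], e$chrom[1L], e$strand[1L],
          a = e$start[i], b = e$end[i], p = e$start[m], q = e$end[m],
          c = e$start[k], d = e$end[k])
      }
    }
  }
  bind_events(events)
}

#' Cassette-exon inclusion ratio
#'
#' For a cassette exon `p`..`q` between constitutive exons `a`..`b` and
#' `c`..`d`, the inclusion ratio is
#' \deqn{\frac{(N(b{\sim}p)+N(q{\sim}c))/2}{(N(b{\sim}p)+N(q{\sim}c))/2 + N(b{\sim}c)}}
#' where `N(x~y)` is the read support of junction `x`..`y`.  Missing
#' junctions contribute support 0; when all three supports are 0 the ratio
#' is `NA` and the event is retained.
#'
#' @param events CE event data.frame ([detect_ce()]).
#' @param junctions junction data.frame supplying supports.
#' @return numeric vector of inclusion ratios in \[0,1\] (or `NA`).
#' @export
compute_ce_ratio <- function(events, junctions) {
  vapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    n_in1 <- junction_support(junctions, ev$chrom, ev$b, ev$p, ev$strand)
    n_in2 <- junction_support(junctions, ev$chrom, ev$q, ev$c, ev$strand)
    n_skip <- junction_support(junctions, ev$chrom, ev$b, ev$c, ev$strand)
    inc <- (n_in1 + n_in2) / 2
    if (inc + n_skip == 0) return(NA_real_)
    inc / (inc + n_skip)
  }, numeric(1))
}

#' Intron-retention inclusion ratio
#'
#' For a retained intron `p`..`q` with adjacent exons `a`..`p` and `q`..`d`,
#' \deqn{2\,\mathrm{Cov}(p,q) / (\mathrm{Cov}(a,p)+\mathrm{Cov}(q,d))}
#' where `Cov(x,y)` is mean per-base depth over `x`..`y`.  The value is not
#' clamped and may exceed 1; a zero denominator yields `NA`.
#'
#' @param events IR event data.frame ([detect_ir()]); only `a`, `p`, `q`,
#'   `d` and `chrom` are used.
#' @param coverage a `coverage_track`.
#' @return numeric vector of inclusion ratios (>= 0 or `NA`).
#' @export
compute_ir_ratio <- function(events, coverage) {
  vapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    denom <- cov_mean(coverage, ev$chrom, ev$a, ev$p) +
      cov_mean(coverage, ev$chrom, ev$q, ev$d)
    if (denom == 0) return(NA_real_)
    2 * cov_mean(coverage, ev$chrom, ev$p, ev$q) / denom
  }, numeric(1))
}

#' Detect intron retention
#'
#' An annotated intron is called retained when (i) every intronic base has
#' depth strictly greater than `min_depth` and (ii) its inclusion ratio
#' ([compute_ir_ratio()]) is at least `3 * baseline`, screening out spurious
#' intronic signal.  `baseline` defaults to 0.017, a genome-wide average
#' intron inclusion ratio; on other data it can be recomputed from all
#' annotated introns.  Both flanking exons are recorded as involved.
#'
#' @param model a [gene_model()].
#' @param coverage a `coverage_track`.
#' @param baseline genome-wide average intron inclusion ratio.
#' @param min_depth per-base depth that every intronic base must exceed.
#' @return event data.frame (`kind == "IR"`), intron at `p`..`q`, flanking
#'   exons `a`..`b` and `c`..`d` (so `b == p`, `c == q`), with
#'   `inclusion_ratio` filled in.
#' @export
detect_ir <- function(model, coverage, baseline = 0.017, min_depth = 5) {
  introns <- model_introns(model)
  events <- list()
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    if (is.null(coverage[[it$chrom]])) next
    if (cov_min(coverage, it$chrom, it$start, it$end) <= min_depth) next
    ev <- event_row("IR", it$gene_id, it$chrom, it$strand,
                    a = it$a, b = it$b, p = it$start, q = it$end,
                    c = it$c, d = it$d)
    ratio <- compute_ir_ratio(ev, coverage)
    # tolerance guards the >= comparison against float artifacts
    # (3 * 0.017 is not exactly representable)
    if (is.na(ratio) || ratio < 3 * baseline - 1e-9) next
    ev$inclusion_ratio <- ratio
    events[[length(events) + 1L]] <- ev
  }
  bind_events(events)
}

#' Detect alternative exon boundaries (alternative donor/acceptor sites)
#'
#' For an annotated intron `b`..`c` (between exons `a`..`b` and `c`..`d`), a
#' half-known junction sharing one splice site defines an alternative
#' boundary when the novel end is displaced by strictly less than
#' `max_displacement` and stays within the flanked exon (the novel boundary
#' may not cross the exon's opposite edge).  Whether the event is an
#' alternative donor or acceptor follows the transcription orientation:
#' the intron-start side is the donor on `+` and the acceptor on `-`.
#'
#' @param model a [gene_model()].
#' @param half_known half-known junction data.frame with a `novel_side`
#'   column, as produced by [filter_junctions()].
#' @param max_displacement displacement bound in bp, exclusive (default 200).
#' @return event data.frame with `kind` in `ALT_DONOR`/`ALT_ACCEPTOR`; the
#'   affected exon sits at `p`..`q` with the alternative boundary in `p2`
#'   (moved exon start) or `q2` (moved exon end), and `displacement` filled.
#' @export
detect_aeb <- function(model, half_known, max_displacement = 200) {
  introns <- model_introns(model)
  events <- list()
  for (i in seq_len(nrow(half_known))) {
    jc <- half_known[i, ]
    if (jc$novel_side == "end") {
      # shared intron start; exon start p moved to p2 = jc$end
      hits <- introns[introns$chrom == jc$chrom & introns$strand == jc$strand &
                        introns$start == jc$start, , drop = FALSE]
      for (h in seq_len(nrow(hits))) {
        it <- hits[h, ]
        disp <- abs(jc$end - it$end)
        if (disp == 0L || disp >= max_displacement) next
        if (jc$end >= it$d) next            # crosses far exon edge: novel exon
        kind <- if (it$strand == "+") "ALT_ACCEPTOR" else "ALT_DONOR"
        events[[length(events) + 1L]] <- event_row(
          kind, it$gene_id, it$chrom, it$strand,
          a = it$a, b = it$b, p = it$c, q = it$d, p2 = jc$end,
          displacement = disp)
      }
    } else {
      # shared intron end; exon end q moved to q2 = jc$start
      hits <- introns[introns$chrom == jc$chrom & introns$strand == jc$strand &
                        introns$end == jc$end, , drop = FALSE]
      for (h in seq_len(nrow(hits))) {
        it <- hits[h, ]
        disp <- abs(jc$start - it$start)
        if (disp == 0L || disp >= max_displacement) next
        if (jc$start <= it$a) next
        kind <- if (it$strand == "+") "ALT_DONOR" else "ALT_ACCEPTOR"
        events[[length(events) + 1L]] <- event_row(
          kind, it$gene_id, it$chrom, it$strand,
          a = NA, b = NA, p = it$a, q = it$b, q2 = jc$start,
          c = it$c, d = it$d, displacement = disp)
      }
    }
  }
  bind_events(events)
}

#' Splicing and inclusion ratios for alternative exon boundaries
#'
#' With annotated and alternative junction supports `N` and `N'`:
#' * splicing ratio = `min(N, N') / max(N, N')` (minor over major; 1 on a
#'   tie, `NA` when both are 0);
#' * inclusion ratio of the boundary region = support of the junction
#'   retaining the region over `N + N'`: for a moved exon start,
#'   `N(b~min(p,p2)) / (N(b~p)+N(b~p2))`; for a moved exon end,
#'   `N(max(q,q2)~c) / (N(q~c)+N(q2~c))`.
#'
#' Also applies to alternative terminal exons, whose splicing ratio uses
#' the two junctions into the shared constitutive site.
#'
#' @param events AEB/ATE event data.frame ([detect_aeb()], [detect_ate()]).
#' @param junctions junction data.frame supplying supports.
#' @return data.frame with columns `splicing_ratio`, `inclusion_ratio`.
#' @export
compute_aeb_ratios <- function(events, junctions) {
  out <- data.frame(splicing_ratio = rep(NA_real_, nrow(events)),
                    inclusion_ratio = rep(NA_real_, nrow(events)))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$kind %in% c("AFE", "ALE")) {
      if (!is.na(ev$c)) {
        # terminal exons ending at q / q2 splice into shared site c
        n1 <- junction_support(junctions, ev$chrom, ev$q, ev$c, ev$strand)
        n2 <- junction_support(junctions, ev$chrom, ev$q2, ev$c, ev$strand)
      } else {
        # shared site b splices into terminal exons starting at p / p2
        n1 <- junction_support(junctions, ev$chrom, ev$b, ev$p, ev$strand)
        n2 <- junction_support(junctions, ev$chrom, ev$b, ev$p2, ev$strand)
      }
      if (max(n1, n2) > 0) out$splicing_ratio[i] <- min(n1, n2) / max(n1, n2)
      next
    }
    if (!is.na(ev$p2)) {
      n_annot <- junction_support(junctions, ev$chrom, ev$b, ev$p, ev$strand)
      n_alt <- junction_support(junctions, ev$chrom, ev$b, ev$p2, ev$strand)
      n_long <- if (ev$p <= ev$p2) n_annot else n_alt
    } else {
      n_annot <- junction_support(junctions, ev$chrom, ev$q, ev$c, ev$strand)
      n_alt <- junction_support(junctions, ev$chrom, ev$q2, ev$c, ev$strand)
      n_long <- if (ev$q >= ev$q2) n_annot else n_alt
    }
    if (n_annot + n_alt > 0) {
      out$inclusion_ratio[i] <- n_long / (n_annot + n_alt)
    }
    if (max(n_annot, n_alt) > 0) {
      out$splicing_ratio[i] <- min(n_annot, n_alt) / max(n_annot, n_alt)
    }
  }
  out
}

#' Detect alternative terminal exons (AFE/ALE)
#'
#' Two distinct first exons of a gene whose introns splice into the same
#' acceptor site of a constitutive exon form an alternative-first-exon
#' (AFE) pair; mirrored at a shared donor for alternative last exons (ALE).
#' First/last is in transcription orientation, so on the minus strand the
#' first exon is the genome-rightmost.  Terminal exons not linking to the
#' same constitutive site are not called.  Single-exon transcripts are
#' skipped.
#'
#' @param model a [gene_model()].
#' @param junctions junction data.frame used to rank major/minor usage (a
#'   terminal exon's junction missing from the table counts as support 0).
#' @return event data.frame with `kind` in `AFE`/`ALE`; the major terminal
#'   exon sits at `p`..`q`, the minor at `p2`..`q2`, and the shared
#'   constitutive site in `c` (AFE) or `b` (ALE).
#' @export
detect_ate <- function(model, junctions) {
  ex <- model$exons[order(model$exons$transcript_id, model$exons$start), ,
                    drop = FALSE]
  by_tx <- split(ex, ex$transcript_id)
  term <- lapply(by_tx, function(e) {
    if (nrow(e) < 2L) return(NULL)
    k <- nrow(e)
    plus <- e$strand[1L] == "+"
    data.frame(
      gene_id = e$gene_id[1L], chrom = e$chrom[1L], strand = e$strand[1L],
      # first exon and the shared site its intron targets
      f_start = if (plus) e$start[1L] else e$start[k],
      f_end = if (plus) e$end[1L] else e$end[k],
      f_site = if (plus) e$start[2L] else e$end[k - 1L],
      # last exon and the shared donor-side site
      l_start = if (plus) e$start[k] else e$start[1L],
      l_end = if (plus) e$end[k] else e$end[1L],
      l_site = if (plus) e$end[k - 1L] else e$start[2L],
      stringsAsFactors = FALSE)
  })
  term <- do.call(rbind, term)
  events <- list()
  if (is.null(term)) return(empty_events())
  emit_pairs <- function(tt, first) {
    cols <- if (first) c("f_start", "f_end", "f_site") else
      c("l_start", "l_end", "l_site")
    tt <- unique(tt[, c("gene_id", "chrom", "strand", cols)])
    names(tt)[4:6] <- c("e_start", "e_end", "site")
    by_site <- split(tt, paste(tt$gene_id, tt$site))
    for (g in by_site) {
      if (nrow(g) < 2L) next
      g <- g[order(g$e_start, g$e_end), , drop = FALSE]
      for (i in seq_len(nrow(g) - 1L)) for (k in (i + 1L):nrow(g)) {
        e1 <- g[i, ]; e2 <- g[k, ]
        plus <- e1$strand == "+"
        if (first) {
          sup <- function(e) if (plus)
            junction_support(junctions, e$chrom, e$e_end, e$site, e$strand)
          else junction_support(junctions, e$chrom, e$site, e$e_start, e$strand)
          kind <- "AFE"
        } else {
          sup <- function(e) if (plus)
            junction_support(junctions, e$chrom, e$site, e$e_start, e$strand)
          else junction_support(junctions, e$chrom, e$e_end, e$site, e$strand)
          kind <- "ALE"
        }
        s1 <- sup(e1); s2 <- sup(e2)
        maj <- if (s2 > s1) e2 else e1
        mino <- if (s2 > s1) e1 else e2
        # in genome coordinates: AFE(+)/ALE(-) share a downstream acceptor
        # stored in c; ALE(+)/AFE(-) share an upstream donor stored in b
        shared_right <- (first && plus) || (!first && !plus)
        events[[length(events) + 1L]] <<- event_row(
          kind, e1$gene_id, e1$chrom, e1$strand,
          b = if (shared_right) NA else e1$site,
          p = maj$e_start, q = maj$e_end,
          p2 = mino$e_start, q2 = mino$e_end,
          c = if (shared_right) e1$site else NA)
      }
    }
  }
  emit_pairs(term, first = TRUE)
  emit_pairs(term, first = FALSE)
  bind_events(events)
}

#' Displacement and frame-preservation spectrum
#'
#' Tabulates AEB displacement distances split by donor/acceptor, the
#' fraction of displacements that are multiples of 3 (reading-frame
#' preserving), and the fraction of cassette exons whose length is a
#' multiple of 3.
#'
#' @param events event data.frame containing AEB and/or CE rows.
#' @return list with `histogram` (kind, displacement, count),
#'   `aeb_mod3_fraction`, and `ce_mod3_fraction` (`NA` when no events of
#'   that family are present).
#' @export
displacement_spectrum <- function(events) {
  aeb <- events[events$kind %in% c("ALT_DONOR", "ALT_ACCEPTOR") &
                  !is.na(events$displacement), , drop = FALSE]
  if (nrow(aeb) > 0L) {
    tab <- as.data.frame(table(kind = aeb$kind,
                               displacement = aeb$displacement),
                         stringsAsFactors = FALSE)
    tab$displacement <- as.integer(tab$displacement)
    names(tab)[3L] <- "count"
    tab <- tab[tab$count > 0L, , drop = FALSE]
    tab <- tab[order(tab$kind, tab$displacement), , drop = FALSE]
    rownames(tab) <- NULL
    mod3 <- mean(aeb$displacement %% 3L == 0L)
  } else {
    tab <- data.frame(kind = character(), displacement = integer(),
                      count = integer(), stringsAsFactors = FALSE)
    mod3 <- NA_real_
  }
  ce <- events[events$kind == "CE", , drop = FALSE]
  ce_mod3 <- if (nrow(ce) > 0L) mean((ce$q - ce$p) %% 3L == 0L) else NA_real_
  list(histogram = tab, aeb_mod3_fraction = mod3, ce_mod3_fraction = ce_mod3)
}

#' Run all event detectors and fill in ratio metrics
#'
#' Convenience wrapper: filters junctions against the model, runs
#' [detect_ce()], [detect_ir()], [detect_aeb()] and [detect_ate()], and
#' computes every ratio metric defined for each kind.
#'
#' @param model a [gene_model()].
#' @param junctions raw junction data.frame.
#' @param coverage a `coverage_track`.
#' @param min_score junction confidence threshold (strict; default 0.5).
#' @param baseline,min_depth IR parameters (see [detect_ir()]).
#' @param max_displacement AEB displacement bound (default 200).
#' @return event data.frame with `inclusion_ratio`/`splicing_ratio` filled.
#' @export
detect_as <- function(model, junctions, coverage, min_score = 0.5,
                      baseline = 0.017, min_depth = 5,
                      max_displacement = 200) {
  part <- filter_junctions(junctions, model, min_score)
  retained <- rbind(part$known,
                    part$half_known[, names(part$known), drop = FALSE])
  ce <- detect_ce(model, part$known)
  if (nrow(ce) > 0L) ce$inclusion_ratio <- compute_ce_ratio(ce, retained)
  ir <- detect_ir(model, coverage, baseline, min_depth)
  aeb <- detect_aeb(model, part$half_known, max_displacement)
  ate <- detect_ate(model, retained)
  for (nm in c("aeb", "ate")) {
    ev <- get(nm)
    if (nrow(ev) > 0L) {
      r <- compute_aeb_ratios(ev, retained)
      ev$splicing_ratio <- r$splicing_ratio
      ev$inclusion_ratio <- ifelse(is.na(r$inclusion_ratio),
                                   ev$inclusion_ratio, r$inclusion_ratio)
      assign(nm, ev)
    }
  }
  bind_events(list(ce, ir, aeb, ate))
}

#' Write / read the event table as TSV
#'
#' @param events event data.frame.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
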