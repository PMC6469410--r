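#' Maximum-entropy splice-site model
#'
#' Models the distribution of fixed-width splice-site motifs under the
#' maximum-entropy principle: the fitted distribution is the one of maximal
#' entropy whose position marginals (and, at `constraint_order = 2`,
#' adjacent-pairwise marginals) match the training set.  With first-order
#' constraints only, the solution is exactly the independence
#' (position-weight-matrix) model; with adjacent pairs it is a first-order
#' Markov chain, fitted by iterative proportional scaling with exact
#' forward-backward normalization, so the 23-mer acceptor window never
#' requires enumerating 4^23 motifs.
#'
#' Window geometry follows the common convention for these models: donors
#' span 3 exonic + 6 intronic bases (9 nt), acceptors 20 intronic + 3
#' exonic bases (23 nt).
#'
#' @param site_sequences character vector of aligned training motifs, all
#'   the same length, alphabet ACGT.
#' @param site_type `"donor"` or `"acceptor"` (sets the expected window
#'   length: 9 or 23).
#' @param constraint_order 1 (position marginals only) or 2 (adds adjacent
#'   pairwise marginals).
#' @param background length-4 background nucleotide distribution (A,C,G,T)
#'   used for log-odds scoring; typically [genome_base_freq()].
#' @param tol convergence tolerance: maximal absolute deviation between
#'   fitted and empirical constraint marginals (default 1e-4).
#' @param max_iter iteration cap for the scaling loop.
#' @return An object of class `splice_site_model`.
#' @export
train_splice_model <- function(site_sequences, site_type = c("donor", "acceptor"),
                               constraint_order = 2,
                               background = rep(0.25, 4),
                               tol = 1e-4, max_iter = 500L) {
  site_type <- match.arg(site_type)
  L <- if (site_type == "donor") 9L else 23L
  if (length(site_sequences) < 1L) stop("no training sequences")
  if (any(nchar(site_sequences) != L)) {
    stop("training sequence of wrong length for ", site_type,
         " (expected ", L, ")")
  }
  mat <- do.call(rbind, strsplit(toupper(site_sequences), ""))
  if (!all(mat %in% c("A", "C", "G", "T"))) {
    stop("non-ACGT symbol in training sequences")
  }
  bases <- c("A", "C", "G", "T")
  idx <- matrix(match(mat, bases), nrow = nrow(mat))
  n <- nrow(idx)
  emp1 <- t(vapply(seq_len(L), function(i) tabulate(idx[, i], 4L) / n,
                   numeric(4)))
  emp2 <- NULL
  if (constraint_order >= 2 && L > 1L) {
    emp2 <- lapply(seq_len(L - 1L), function(i) {
      tab <- matrix(0, 4, 4)
      for (r in seq_len(n)) tab[idx[r, i], idx[r, i + 1L]] <-
          tab[idx[r, i], idx[r, i + 1L]] + 1
      tab / n
    })
  }
  W1 <- matrix(1, L, 4)
  W2 <- if (is.null(emp2)) NULL else replicate(L - 1L, matrix(1, 4, 4),
                                               simplify = FALSE)
  dev <- Inf; iter <- 0L
  while (dev >= tol && iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(L)) {
      mm <- chain_marginals(W1, W2)
      r <- ifelse(mm$m1[i, ] > 0, emp1[i, ] / mm$m1[i, ], 0)
      W1[i, ] <- W1[i, ] * r
    }
    if (!is.null(W2)) {
      for (i in seq_len(L - 1L)) {
        mm <- chain_marginals(W1, W2)
        r <- ifelse(mm$m2[[i]] > 0, emp2[[i]] / mm$m2[[i]], 0)
        W2[[i]] <- W2[[i]] * r
      }
    }
    mm <- chain_marginals(W1, W2)
    dev <- max(abs(mm$m1 - emp1))
    if (!is.null(W2)) {
      dev <- max(dev, max(vapply(seq_len(L - 1L), function(i)
        max(abs(mm$m2[[i]] - emp2[[i]])), numeric(1))))
    }
  }
  stopifnot(length(background) == 4L, all(background > 0))
  structure(list(site_type = site_type, length = L,
                 constraint_order = constraint_order,
                 W1 = W1, W2 = W2, logZ = chain_logZ(W1, W2),
                 emp1 = emp1, emp2 = emp2,
                 background = background / sum(background),
                 converged = dev < tol, deviation = dev, iterations = iter),
            class = "splice_site_model")
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat(sprintf("splice_site_model: %s, window %d nt, order %d, %s (dev %.2g, %d iter)\n",
              x$site_type, x$length, x$constraint_order,
              if (x$converged) "converged" else "NOT converged",
              x$deviation, x$iterations))
  invisible(x)
}

# forward pass: unnormalized chain sums
chain_forward <- function(W1, W2) {
  L <- nrow(W1)
  f <- matrix(0, L, 4)
  f[1L, ] <- W1[1L, ]
  if (L > 1L) for (i in 2L:L) {
    f[i, ] <- as.numeric(f[i - 1L, ] %*% pair_mat(W2, i - 1L)) * W1[i, ]
  }
  f
}
chain_backward <- function(W1, W2) {
  L <- nrow(W1)
  b <- matrix(0, L, 4)
  b[L, ] <- 1
  if (L > 1L) for (i in (L - 1L):1L) {
    b[i, ] <- as.numeric(pair_mat(W2, i) %*% (W1[i + 1L, ] * b[i + 1L, ]))
  }
  b
}
pair_mat <- function(W2, i) if (is.null(W2)) matrix(1, 4, 4) else W2[[i]]

chain_logZ <- function(W1, W2) log(sum(chain_forward(W1, W2)[nrow(W1), ]))

# exact model marginals by forward-backward
chain_marginals <- function(W1, W2) {
  L <- nrow(W1)
  f <- chain_forward(W1, W2)
  b <- chain_backward(W1, W2)
  Z <- sum(f[L, ])
  m1 <- (f * b) / Z
  m2 <- NULL
  if (!is.null(W2)) {
    m2 <- lapply(seq_len(L - 1L), function(i) {
      outer(f[i, ], W1[i + 1L, ] * b[i + 1L, ]) * pair_mat(W2, i) / Z
    })
  }
  list(m1 = m1, m2 = m2)
}

# fitted probability of one motif (character string)
motif_prob <- function(model, motif) {
  x <- match(strsplit(toupper(motif), "")[[1]], c("A", "C", "G", "T"))
  if (length(x) != model$length || anyNA(x)) return(NA_real_)
  lp <- sum(log(model$W1[cbind(seq_len(model$length), x)]))
  if (!is.null(model$W2)) {
    for (i in seq_len(model$length - 1L)) {
      lp <- lp + log(model$W2[[i]][x[i], x[i + 1L]])
    }
  }
  exp(lp - model$logZ)
}

# log2-odds score of a motif against the 0-order background
score_motif <- function(model, motif) {
  p <- motif_prob(model, motif)
  if (is.na(p)) return(NA_real_)
  x <- match(strsplit(toupper(motif), "")[[1]], c("A", "C", "G", "T"))
  pbg <- prod(model$background[x])
  log2(p / pbg)
}

#' Mean training-set log-likelihood of a fitted model
#'
#' @param model a `splice_site_model`.
#' @param sequences motifs to evaluate (defaults make no sense here, pass
#'   the training set to compare constraint orders).
#' @return mean log-likelihood per motif (natural log).
#' @export
model_loglik <- function(model, sequences) {
  mean(vapply(sequences, function(s) log(motif_prob(model, s)), numeric(1)))
}

#' Genome background nucleotide frequencies
#'
#' @param genome a `DNAStringSet`.
#' @return length-4 numeric vector of A,C,G,T frequencies.
#' @export
genome_base_freq <- function(genome) {
  f <- colSums(Biostrings::alphabetFrequency(genome)[, c("A", "C", "G", "T"),
                                                     drop = FALSE])
  as.numeric(f / sum(f))
}

#' Score a splice site in the genome
#'
#' `site` is the intron-boundary coordinate in the 0-based half-open intron
#' convention: for a donor, the first intronic base on `+` (one past the
#' last intronic base on `-`); for an acceptor, one past the last intronic
#' base on `+` (the first intronic base on `-`).  The motif window is
#' extracted accordingly and reverse-complemented on the minus strand, so a
#' minus-strand score equals the plus-strand score of the
#' reverse-complemented window.
#'
#' @param model a `splice_site_model`.
#' @param genome a `DNAStringSet`.
#' @param chrom chromosome name.
#' @param site intron boundary coordinate (see above).
#' @param strand `"+"` or `"-"`.
#' @return log2 odds of the window under the model versus background, or
#'   `NA` when the window runs off the chromosome.
#' @export
score_splice_site <- function(model, genome, chrom, site, strand) {
  win <- splice_window(model$site_type, site, strand)
  len <- length(genome[[chrom]])
  if (win[1L] < 0L || win[2L] > len) return(NA_real_)
  s <- interval_seq(genome, chrom, win[1L], win[2L])
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  score_motif(model, s)
}

# window on the + strand, 0-based half-open, for a site coordinate
splice_window <- function(site_type, site, strand) {
  if (site_type == "donor") {
    if (strand == "+") c(site - 3L, site + 6L) else c(site - 6L, site + 3L)
  } else {
    if (strand == "+") c(site - 20L, site + 3L) else c(site - 3L, site + 20L)
  }
}

#' Extract training windows for donor or acceptor sites from an annotation
#'
#' Pulls the motif window of every unique annotated intron boundary of the
#' model, in transcription orientation.
#'
#' @param model a [gene_model()].
#' @param genome a `DNAStringSet`.
#' @param site_type `"donor"` or `"acceptor"`.
#' @return character vector of motif windows (off-chromosome sites dropped).
#' @export
splice_site_sequences <- function(model, genome, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  introns <- model_introns(model)
  introns <- unique(introns[, c("chrom", "start", "end", "strand")])
  out <- character()
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    site <- if (site_type == "donor") {
      if (it$strand == "+") it$start else it$end
    } else {
      if (it$strand == "+") it$end else it$start
    }
    win <- splice_window(site_type, site, it$strand)
    len <- length(genome[[it$chrom]])
    if (win[1L] < 0L || win[2L] > len) next
    s <- interval_seq(genome, it$chrom, win[1L], win[2L])
    if (it$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    if (grepl("[^ACGT]", s)) next
    out <- c(out, s)
  }
  out
}

# donor/acceptor site coordinates of an event region (intron convention)
# side: "intron_start" or "intron_end" of the intron the boundary belongs to
site_model_for_side <- function(side, strand) {
  if (side == "intron_start") {
    if (strand == "+") "donor" else "acceptor"
  } else {
    if (strand == "+") "acceptor" else "donor"
  }
}

#' Splice-site strength versus inclusion ratio
#'
#' For cassette exons, the exon's own acceptor and donor sites are scored;
#' for retained introns, the average of the intron's donor and acceptor
#' scores is used.  Scores are grouped into inclusion-ratio bins and the
#' lowest and highest occupied bins are compared with a Mann-Whitney test.
#'
#' @param events event data.frame with `inclusion_ratio` filled.
#' @param model_d,model_a fitted donor and acceptor `splice_site_model`s.
#' @param genome a `DNAStringSet`.
#' @param bins inclusion-ratio bin edges (default `c(0,.2,.4,.6,.8,1)`).
#' @return list with `table` (family, site, bin, n, median_score) and
#'   `tests` (family, site, low/high bin labels, p_value,
#'   median_difference = high bin minus low bin).  When fewer than two bins
#'   are occupied the comparison is reported `NA`.
#' @export
strength_vs_inclusion <- function(events, model_d, model_a, genome,
                                  bins = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  rows <- list()
  ce <- events[events$kind == "CE" & !is.na(events$inclusion_ratio), ,
               drop = FALSE]
  for (i in seq_len(nrow(ce))) {
    ev <- ce[i, ]
    acc_site <- if (ev$strand == "+") ev$p else ev$q
    don_site <- if (ev$strand == "+") ev$q else ev$p
    rows[[length(rows) + 1L]] <- data.frame(
      family = "CE", site = c("acceptor", "donor"),
      ratio = ev$inclusion_ratio,
      score = c(score_splice_site(model_a, genome, ev$chrom, acc_site,
                                  ev$strand),
                score_splice_site(model_d, genome, ev$chrom, don_site,
                                  ev$strand)),
      stringsAsFactors = FALSE)
  }
  ir <- events[events$kind == "IR" & !is.na(events$inclusion_ratio), ,
               drop = FALSE]
  for (i in seq_len(nrow(ir))) {
    ev <- ir[i, ]
    don_site <- if (ev$strand == "+") ev$p else ev$q
    acc_site <- if (ev$strand == "+") ev$q else ev$p
    sc <- mean(c(score_splice_site(model_d, genome, ev$chrom, don_site,
                                   ev$strand),
                 score_splice_site(model_a, genome, ev$chrom, acc_site,
                                   ev$strand)))
    rows[[length(rows) + 1L]] <- data.frame(
      family = "IR", site = "average", ratio = ev$inclusion_ratio, score = sc,
      stringsAsFactors = FALSE)
  }
  binned_comparison(rows, bins, "ratio")
}

#' Relative splice-site strength versus splicing ratio
#'
#' For alternative-boundary and alternative-terminal-exon events the two
#' competing sites are scored and the difference (major minus minor, major
#' being the more supported variant, ties broken toward the annotated site)
#' is binned by splicing ratio; the first and last occupied bins are
#' compared with a Mann-Whitney test.
#'
#' @param events event data.frame with `splicing_ratio` filled.
#' @param model_d,model_a fitted donor and acceptor models.
#' @param genome a `DNAStringSet`.
#' @param junctions junction data.frame used to rank major/minor variants.
#' @param bins splicing-ratio bin edges.
#' @return same structure as [strength_vs_inclusion()], with score =
#'   major site score minus minor site score.
#' @export
relative_strength_vs_splicing_ratio <- function(events, model_d, model_a,
                                                genome, junctions,
                                                bins = c(0, 0.2, 0.4, 0.6,
                                                         0.8, 1)) {
  rows <- list()
  ev_set <- events[events$kind %in% c("ALT_DONOR", "ALT_ACCEPTOR", "AFE",
                                      "ALE") &
                     !is.na(events$splicing_ratio), , drop = FALSE]
  for (i in seq_len(nrow(ev_set))) {
    ev <- ev_set[i, ]
    vs <- event_variant_sites(ev, junctions)
    if (is.null(vs)) next
    st <- site_model_for_side(vs$side, ev$strand)
    mdl <- if (st == "donor") model_d else model_a
    s_major <- score_splice_site(mdl, genome, ev$chrom, vs$major, ev$strand)
    s_minor <- score_splice_site(mdl, genome, ev$chrom, vs$minor, ev$strand)
    if (is.na(s_major) || is.na(s_minor)) next
    rows[[length(rows) + 1L]] <- data.frame(
      family = if (ev$kind %in% c("AFE", "ALE")) "ATE" else "AEB",
      site = "relative", ratio = ev$splicing_ratio,
      score = s_major - s_minor, stringsAsFactors = FALSE)
  }
  binned_comparison(rows, bins, "ratio")
}

# the two competing boundary sites of an AEB/ATE event, ranked major/minor
event_variant_sites <- function(ev, junctions) {
  if (ev$kind %in% c("AFE", "ALE")) {
    if (!is.na(ev$c)) {
      sites <- c(ev$q, ev$q2); side <- "intron_start"
      n <- c(junction_support(junctions, ev$chrom, ev$q, ev$c, ev$strand),
             junction_support(junctions, ev$chrom, ev$q2, ev$c, ev$strand))
    } else {
      sites <- c(ev$p, ev$p2); side <- "intron_end"
      n <- c(junction_support(junctions, ev$chrom, ev$b, ev$p, ev$strand),
             junction_support(junctions, ev$chrom, ev$b, ev$p2, ev$strand))
    }
  } else if (!is.na(ev$p2)) {
    sites <- c(ev$p, ev$p2); side <- "intron_end"
    n <- c(junction_support(junctions, ev$chrom, ev$b, ev$p, ev$strand),
           junction_support(junctions, ev$chrom, ev$b, ev$p2, ev$strand))
  } else if (!is.na(ev$q2)) {
    sites <- c(ev$q, ev$q2); side <- "intron_start"
    n <- c(junction_support(junctions, ev$chrom, ev$q, ev$c, ev$strand),
           junction_support(junctions, ev$chrom, ev$q2, ev$c, ev$strand))
  } else {
    return(NULL)
  }
  # ties break toward the first (annotated / major-stored) site
  ord <- if (n[2L] > n[1L]) c(2L, 1L) else c(1L, 2L)
  list(major = sites[ord[1L]], minor = sites[ord[2L]], side = side)
}

# shared binning + extreme-bin Mann-Whitney machinery
binned_comparison <- function(rows, bins, ratio_col) {
  tab0 <- data.frame(family = character(), site = character(),
                     bin = character(), n = integer(),
                     median_score = numeric(), stringsAsFactors = FALSE)
  tests0 <- data.frame(family = character(), site = character(),
                       low_bin = character(), high_bin = character(),
                       p_value = numeric(), median_difference = numeric(),
                       stringsAsFactors = FALSE)
  rows <- Filter(function(x) !is.null(x), rows)
  if (length(rows) == 0L) return(list(table = tab0, tests = tests0))
  df <- do.call(rbind, rows)
  df <- df[!is.na(df$score), , drop = FALSE]
  if (nrow(df) == 0L) return(list(table = tab0, tests = tests0))
  df$bin <- cut(pmin(df[[ratio_col]], max(bins)), bins, include.lowest = TRUE)
  tabs <- list(); tests <- list()
  for (key in unique(paste(df$family, df$site))) {
    sub <- df[paste(df$family, df$site) == key, , drop = FALSE]
    agg_n <- tapply(sub$score, sub$bin, length)
    agg_m <- tapply(sub$score, sub$bin, stats::median)
    occupied <- names(agg_n)[!is.na(agg_n) & agg_n > 0L]
    tabs[[key]] <- data.frame(family = sub$family[1L], site = sub$site[1L],
                              bin = occupied, n = as.integer(agg_n[occupied]),
                              median_score = as.numeric(agg_m[occupied]),
                              stringsAsFactors = FALSE)
    if (length(occupied) >= 2L) {
      lo <- occupied[1L]; hi <- occupied[length(occupied)]
      a <- sub$score[sub$bin == lo]; b <- sub$score[sub$bin == hi]
      tests[[key]] <- data.frame(
        family = sub$family[1L], site = sub$site[1L], low_bin = lo,
        high_bin = hi, p_value = mann_whitney(a, b),
        median_difference = stats::median(b) - stats::median(a),
        stringsAsFactors = FALSE)
    } else {
      tests[[key]] <- data.frame(
        family = sub$family[1L], site = sub$site[1L],
        low_bin = NA_character_, high_bin = NA_character_,
        p_value = NA_real_, median_difference = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, tabs); rownames(tab) <- NULL
  tst <- do.call(rbind, tests); rownames(tst) <- NULL
  list(table = tab, tests = tst)
}
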