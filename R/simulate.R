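#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: gene structure
#' statistics (exon length mean 320 bp, intron length mean 1390 bp,
#' matching genome-wide honey bee averages), uniform exonic read depth,
#' background intronic noise at a mean of `noise_factor` times exon depth
#' (0.017, the genome-wide average intron inclusion ratio), per-kind
#' planted event counts, and optional coupling of splice-site strength or
#' CpG content to the planted ratios.
#'
#' Each gene has three exons and hosts at most one planted event; planted
#' inclusion/splicing ratios are drawn from a nine-point grid across
#' `ratio_range`.  When strength or methylation coupling is on, alternative
#' boundary displacements are drawn from `coupled_displacement_pool`
#' (default 30-90 bp) so the two competing motif windows and the boundary
#' region do not overlap; otherwise `displacement_pool` (3/4/5 bp, the
#' dominant displacement gaps) is used.
#'
#' @param n_genes number of gene slots (default 200).
#' @param seed RNG seed; fixed seed gives a byte-identical file set.
#' @param exon_len_mean,exon_len_sd,intron_len_mean,intron_len_sd gene
#'   geometry distributions (bp).
#' @param depth uniform exonic read depth (default 100).
#' @param noise_factor mean intronic noise depth as a fraction of `depth`.
#' @param n_ce,n_ir,n_alt_donor,n_alt_acceptor,n_afe,n_ale planted event
#'   counts per kind.
#' @param n_novel_exon,n_novel_transcript planted novel-exon fixtures
#'   (half-known junction into an intergenic island) and intergenic
#'   two-island novel transcripts.
#' @param ratio_range range of planted inclusion/splicing ratios.
#' @param displacement_pool,coupled_displacement_pool AEB displacement
#'   choices (bp).
#' @param couple_strength `"none"`, `"planted"` (strength follows the
#'   planted ratio) or `"uniform_strong"` (all sites strong; null control).
#' @param couple_methylation `"none"` or `"planted"` (CpG content follows
#'   the planted ratio).
#' @param methylated_fraction fraction of exons flagged methylated.
#' @param cpg_depletion fraction of CpGs kept in methylated exons.
#' @param decoy_fraction fraction of genes receiving a low-confidence decoy
#'   junction (score <= 0.5, removed by filtering).
#' @param intergenic intergenic spacing (bp).
#' @param chrom chromosome name of the simulated contig.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200, seed = 1,
                              exon_len_mean = 320, exon_len_sd = 80,
                              intron_len_mean = 1390, intron_len_sd = 300,
                              depth = 100, noise_factor = 0.017,
                              n_ce = 25, n_ir = 30, n_alt_donor = 20,
                              n_alt_acceptor = 25, n_afe = 10, n_ale = 10,
                              n_novel_exon = 10, n_novel_transcript = 5,
                              ratio_range = c(0.1, 0.9),
                              displacement_pool = c(3L, 4L, 5L),
                              coupled_displacement_pool = 60:150,
                              couple_strength = c("none", "planted",
                                                  "uniform_strong"),
                              couple_methylation = c("none", "planted"),
                              methylated_fraction = 0.5,
                              cpg_depletion = 0.25,
                              decoy_fraction = 0.05,
                              intergenic = 2500, chrom = "chr1") {
  couple_strength <- match.arg(couple_strength)
  couple_methylation <- match.arg(couple_methylation)
  counts <- c(n_ce, n_ir, n_alt_donor, n_alt_acceptor, n_afe, n_ale,
              n_novel_exon, n_novel_transcript)
  if (any(counts < 0)) stop("event counts must be >= 0")
  if (sum(counts) > n_genes) {
    stop("planted event counts exceed the number of gene slots")
  }
  structure(as.list(environment()), class = "simulation_config")
}

# sample one motif from the strong or weak pool; intronic GT/AG fixed
donor_consensus <- "CAGGTAAGT"
acceptor_consensus <- "TTTTTTTTTTTTTTTTTTAGGTT"

#' Sample a donor or acceptor motif from a strength pool
#'
#' Strong motifs follow the consensus at 95% per position, weak ones at
#' 30%; the invariant GT (donor) / AG (acceptor) dinucleotide is always
#' kept.  Used by the generator to plant a reproducible strength-versus-
#' inclusion relationship.
#'
#' @param site_type `"donor"` or `"acceptor"`.
#' @param strength `"strong"` or `"weak"`.
#' @return a motif string (9 nt donor, 23 nt acceptor) in transcription
#'   orientation.
#' @export
sample_splice_motif <- function(site_type, strength = c("strong", "weak")) {
  strength <- match.arg(strength)
  motif_with_consensus(site_type, if (strength == "strong") 0.95 else 0.3)
}

# motif following the consensus with per-position probability p_cons
motif_with_consensus <- function(site_type, p_cons) {
  cons <- strsplit(if (site_type == "donor") donor_consensus else
    acceptor_consensus, "")[[1]]
  fixed <- if (site_type == "donor") 4:5 else 19:20
  out <- vapply(seq_along(cons), function(i) {
    if (i %in% fixed || stats::runif(1) < p_cons) cons[i]
    else sample(c("A", "C", "G", "T"), 1L)
  }, character(1))
  paste(out, collapse = "")
}

# random sequence with CpG dinucleotides thinned to `keep` of their
# original occurrence (keep = 1: untouched)
random_seq <- function(n, keep_cpg = 1) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (keep_cpg < 1 && n > 1L) {
    cg <- which(s[-n] == "C" & s[-1L] == "G")
    drop <- cg[stats::runif(length(cg)) > keep_cpg]
    if (length(drop) > 0L) {
      s[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
    }
  }
  s
}

# CG-enriched sequence for boundary regions: each dinucleotide slot is CG
# with probability `density`
cpg_rich_seq <- function(n, density) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  i <- 1L
  while (i < n) {
    if (stats::runif(1) < density) {
      s[i] <- "C"; s[i + 1L] <- "G"; i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  s
}

#' Generate a synthetic genome with planted alternative-splicing events
#'
#' Lays out three-exon genes (alternating strand) on one contig, plants the
#' configured numbers of IR, CE, alternative-boundary, and alternative-
#' terminal-exon events with known target ratios, writes canonical GT/AG
#' dinucleotides at every simulated intron boundary, and emits the full
#' input file set: genome FASTA, annotation GFF3 (alternative terminal
#' exons appear as second transcripts), junction TSV (supports drawn
#' binomially around the planted ratios at the configured depth), coverage
#' bedGraph (uniform exonic depth, Poisson intronic noise, planted
#' retained-intron and transcribed-island blocks), methylation TSV, and a
#' truth table.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, all files are written
#'   there (`genome.fa`, `annotation.gff3`, `junctions.tsv`,
#'   `coverage.bedGraph`, `methylation.tsv`, `truth.tsv`).
#' @return list with `genome` (`DNAStringSet`), `model` ([gene_model()]),
#'   `junctions`, `coverage`, `methylation`, `truth` (planted events with
#'   coordinates and target ratios), `novel_truth` (planted novel
#'   exons/transcripts), `exon_flags` (per-exon methylation flag), and
#'   `files` (paths, when written).
#' @export
simulate_splicing_data <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cn <- config$chrom
  depth <- config$depth

  rlen <- function(mean, sd, lo, hi) {
    as.integer(pmin(pmax(round(stats::rnorm(1, mean, sd)), lo), hi))
  }
  grid <- seq(config$ratio_range[1L], config$ratio_range[2L], length.out = 9)
  draw_ratio <- function() sample(grid, 1L)
  coupled <- config$couple_strength != "none" ||
    config$couple_methylation != "none"
  disp_pool <- if (coupled) config$coupled_displacement_pool else
    config$displacement_pool

  kinds <- c(rep("CE", config$n_ce), rep("IR", config$n_ir),
             rep("ALT_DONOR", config$n_alt_donor),
             rep("ALT_ACCEPTOR", config$n_alt_acceptor),
             rep("AFE", config$n_afe), rep("ALE", config$n_ale),
             rep("NOVEL_EXON", config$n_novel_exon),
             rep("NOVEL_TX", config$n_novel_transcript))
  kinds <- c(kinds, rep("NONE", config$n_genes - length(kinds)))
  # spread kinds across slots deterministically but mixed
  kinds <- sample(kinds)

  genes <- list(); transcripts <- list(); exons <- list()
  junc <- list(); truth <- list(); novel_truth <- list()
  cov_blocks <- list()      # (start, end, depth) uniform blocks
  noise_introns <- list()   # introns that get Poisson noise
  meth <- list(); exon_flags <- list()
  seq_edits <- list()       # (start, string) applied to the genome sequence
  motif_edits <- list()     # applied after CpG edits so motifs survive

  spacing <- as.integer(config$intergenic)
  pos <- spacing
  add_junction <- function(start, end, strand, support,
                           score = stats::runif(1, 0.75, 1)) {
    junc[[length(junc) + 1L]] <<- data.frame(
      chrom = cn, start = start, end = end, strand = strand,
      score = score, support = as.integer(support), stringsAsFactors = FALSE)
  }
  plant_intron_ends <- function(s, e, strand) {
    if (strand == "+") {
      seq_edits[[length(seq_edits) + 1L]] <<- list(s, "GT")
      seq_edits[[length(seq_edits) + 1L]] <<- list(e - 2L, "AG")
    } else {
      seq_edits[[length(seq_edits) + 1L]] <<- list(s, "CT")
      seq_edits[[length(seq_edits) + 1L]] <<- list(e - 2L, "AC")
    }
  }
  plant_planned_motif <- function(site_type, site, strand, m) {
    win <- splice_window(site_type, site, strand)
    if (strand == "-") {
      m <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    }
    motif_edits[[length(motif_edits) + 1L]] <<- list(win[1L], m)
  }
  plant_motif <- function(site_type, site, strand, strength) {
    plant_planned_motif(site_type, site, strand,
                        sample_splice_motif(site_type, strength))
  }
  strength_for <- function(kind, ratio) {
    switch(config$couple_strength,
           none = NULL,
           uniform_strong = "strong",
           planted = {
             hi <- ratio > 0.5
             if (kind == "IR") { if (hi) "weak" else "strong" }
             else if (hi) "strong" else "weak"
           })
  }

  ev_id <- 0L
  for (g in seq_along(kinds)) {
    kind <- kinds[g]
    gid <- sprintf("g%04d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"

    if (kind == "NOVEL_TX") {
      # two intergenic islands bridged by a both-novel junction
      i1 <- c(pos, pos + 250L)
      i2 <- c(pos + 1050L, pos + 1300L)
      js <- pos + 200L; je <- pos + 1100L
      cov_blocks[[length(cov_blocks) + 1L]] <- c(i1, depth)
      cov_blocks[[length(cov_blocks) + 1L]] <- c(i2, depth)
      add_junction(js, je, "+", depth)
      plant_intron_ends(js, je, "+")
      novel_truth[[length(novel_truth) + 1L]] <- data.frame(
        kind = "NOVEL_TX", chrom = cn, exon1_start = i1[1L], exon1_end = js,
        exon2_start = je, exon2_end = i2[2L], stringsAsFactors = FALSE)
      pos <- i2[2L] + spacing
      next
    }

    # three-exon gene body
    el <- vapply(1:3, function(i)
      rlen(config$exon_len_mean, config$exon_len_sd, 120L, 600L), integer(1))
    il <- vapply(1:2, function(i)
      rlen(config$intron_len_mean, config$intron_len_sd, 800L, 2500L),
      integer(1))
    e1 <- c(pos, pos + el[1L])
    i1 <- c(e1[2L], e1[2L] + il[1L])
    e2 <- c(i1[2L], i1[2L] + el[2L])
    i2 <- c(e2[2L], e2[2L] + il[2L])
    e3 <- c(i2[2L], i2[2L] + el[3L])
    gene_end <- e3[2L]
    tid <- paste0(gid, ".t1")
    ex_list <- list(e1, e2, e3)
    tx_list <- list(list(id = tid, exons = 1:3))
    ratio <- draw_ratio()
    plant_intron_ends(i1[1L], i1[2L], strand)
    plant_intron_ends(i2[1L], i2[2L], strand)
    cov_blocks[[length(cov_blocks) + 1L]] <- c(e1, depth)
    cov_blocks[[length(cov_blocks) + 1L]] <- c(e2, depth)
    cov_blocks[[length(cov_blocks) + 1L]] <- c(e3, depth)

    j1_support <- depth; j2_support <- depth
    intron_noise <- c(TRUE, TRUE)
    extra <- NULL

    if (kind == "CE") {
      n_in <- stats::rbinom(2L, depth, ratio)
      n_skip <- stats::rbinom(1L, depth, 1 - ratio)
      j1_support <- n_in[1L]; j2_support <- n_in[2L]
      add_junction(e1[2L], e3[1L], strand, n_skip)
      ev_id <- ev_id + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        event_id = sprintf("ev%04d", ev_id), kind = "CE", gene_id = gid,
        chrom = cn, strand = strand, a = e1[1L], b = e1[2L], p = e2[1L],
        q = e2[2L], p2 = NA_integer_, q2 = NA_integer_, c = e3[1L],
        d = e3[2L], target_ratio = ratio, stringsAsFactors = FALSE)
      st <- strength_for("CE", ratio)
      if (!is.null(st)) {
        acc_site <- if (strand == "+") e2[1L] else e2[2L]
        don_site <- if (strand == "+") e2[2L] else e2[1L]
        plant_motif("acceptor", acc_site, strand, st)
        plant_motif("donor", don_site, strand, st)
      }
      if (config$couple_methylation == "planted") {
        seq_edits[[length(seq_edits) + 1L]] <- list(
          e2[1L] + 3L,
          paste(random_seq(el[2L] - 26L, keep_cpg = 1 - 0.9 * ratio),
                collapse = ""))
      }
    } else if (kind == "IR") {
      ir_depth <- max(6L, as.integer(round(ratio * depth)))
      cov_blocks[[length(cov_blocks) + 1L]] <- c(i1, ir_depth)
      intron_noise[1L] <- FALSE
      ev_id <- ev_id + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        event_id = sprintf("ev%04d", ev_id), kind = "IR", gene_id = gid,
        chrom = cn, strand = strand, a = e1[1L], b = i1[1L], p = i1[1L],
        q = i1[2L], p2 = NA_integer_, q2 = NA_integer_, c = i1[2L],
        d = e2[2L], target_ratio = ratio, stringsAsFactors = FALSE)
      st <- strength_for("IR", ratio)
      if (!is.null(st)) {
        don_site <- if (strand == "+") i1[1L] else i1[2L]
        acc_site <- if (strand == "+") i1[2L] else i1[1L]
        plant_motif("donor", don_site, strand, st)
        plant_motif("acceptor", acc_site, strand, st)
      }
      if (config$couple_methylation == "planted") {
        # retained introns carry the CpG depletion footprint of
        # hyper-methylation relative to ordinary introns
        seq_edits[[length(seq_edits) + 1L]] <- list(
          i1[1L] + 25L,
          paste(random_seq(i1[2L] - i1[1L] - 50L, keep_cpg = 0.3),
                collapse = ""))
      }
    } else if (kind %in% c("ALT_DONOR", "ALT_ACCEPTOR")) {
      # which genomic side of intron 1 moves, in genome coordinates; the
      # planted ratio is the splicing ratio (minor/major): the annotated
      # junction is the major variant at full depth, the alternative one
      # draws binomially at `ratio`.  The alternative boundary extends the
      # exon into the intron or shrinks it with equal probability, so the
      # boundary-region inclusion ratio spans both halves of [0,1].
      move_start <- (kind == "ALT_DONOR") == (strand == "+")
      disp <- sample(disp_pool, 1L)
      extend <- stats::runif(1) < 0.5
      if (!extend) {
        # a shrinking boundary must stay inside the affected exon
        disp <- min(disp, el[if (move_start) 1L else 2L] - 30L)
      }
      n_alt <- max(1L, stats::rbinom(1L, depth, ratio))
      if (move_start) {
        # annotated exon end b = i1 start; b' displaced into the exon
        # (shrink) or the intron (extend)
        alt <- if (extend) i1[1L] + disp else i1[1L] - disp
        add_junction(alt, i1[2L], strand, n_alt)
        plant_intron_ends(alt, i1[2L], strand)
        q2 <- alt; p2 <- NA_integer_
      } else {
        # annotated exon start p = i1 end; p' displaced into the intron
        # (extend) or the exon (shrink)
        alt <- if (extend) i1[2L] - disp else i1[2L] + disp
        add_junction(i1[1L], alt, strand, n_alt)
        plant_intron_ends(i1[1L], alt, strand)
        p2 <- alt; q2 <- NA_integer_
      }
      ev_id <- ev_id + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        event_id = sprintf("ev%04d", ev_id), kind = kind, gene_id = gid,
        chrom = cn, strand = strand,
        a = if (move_start) NA_integer_ else e1[1L],
        b = if (move_start) NA_integer_ else e1[2L],
        p = if (move_start) e1[1L] else e2[1L],
        q = if (move_start) e1[2L] else e2[2L],
        p2 = p2, q2 = q2,
        c = if (move_start) e2[1L] else e3[1L],
        d = if (move_start) e2[2L] else e3[2L],
        target_ratio = ratio, stringsAsFactors = FALSE)
      if (config$couple_strength == "uniform_strong") {
        side_type <- site_model_for_side(
          if (move_start) "intron_start" else "intron_end", strand)
        plant_motif(side_type, if (move_start) i1[1L] else i1[2L], strand,
                    "strong")
        plant_motif(side_type, alt, strand, "strong")
      } else if (config$couple_strength == "planted") {
        # graded: the major (annotated) site weakens as the splicing ratio
        # rises, the minor site strengthens
        side_type <- site_model_for_side(
          if (move_start) "intron_start" else "intron_end", strand)
        m_major <- motif_with_consensus(side_type, 0.9 - 0.6 * ratio)
        m_minor <- motif_with_consensus(side_type, 0.3 + 0.6 * ratio)
        plant_planned_motif(side_type, if (move_start) i1[1L] else i1[2L],
                            strand, m_major)
        plant_planned_motif(side_type, alt, strand, m_minor)
      }
      if (config$couple_methylation == "planted") {
        # boundary-region CpG density follows the region inclusion ratio
        incl <- if (extend) ratio / (1 + ratio) else 1 / (1 + ratio)
        reg <- sort(c(if (move_start) i1[1L] else i1[2L], alt))
        seq_edits[[length(seq_edits) + 1L]] <- list(
          reg[1L], paste(cpg_rich_seq(reg[2L] - reg[1L], 0.6 * incl),
                         collapse = ""))
      }
    } else if (kind %in% c("AFE", "ALE")) {
      s_ratio <- ratio
      n_minor <- stats::rbinom(1L, depth, s_ratio)
      if ((kind == "AFE") == (strand == "+")) {
        # alternative exon inside intron 1, sharing the intron-1 end site
        alt_e <- c(i1[1L] + 400L, i1[1L] + 400L + 150L)
        alt_intron <- c(alt_e[2L], i1[2L])
        add_junction(alt_intron[1L], alt_intron[2L], strand, n_minor)
        plant_intron_ends(alt_intron[1L], alt_intron[2L], strand)
        cov_blocks[[length(cov_blocks) + 1L]] <- c(alt_e, depth)
        tx_list[[2L]] <- list(id = paste0(gid, ".t2"), exons = c(4L, 2L, 3L))
        ex_list[[4L]] <- alt_e
        shared_c <- i1[2L]
        maj_e <- e1
      } else {
        alt_e <- c(i2[2L] - 400L - 150L, i2[2L] - 400L)
        alt_intron <- c(i2[1L], alt_e[1L])
        add_junction(alt_intron[1L], alt_intron[2L], strand, n_minor)
        plant_intron_ends(alt_intron[1L], alt_intron[2L], strand)
        cov_blocks[[length(cov_blocks) + 1L]] <- c(alt_e, depth)
        tx_list[[2L]] <- list(id = paste0(gid, ".t2"), exons = c(1L, 2L, 4L))
        ex_list[[4L]] <- alt_e
        shared_c <- NA_integer_
        maj_e <- e3
      }
      ev_id <- ev_id + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        event_id = sprintf("ev%04d", ev_id), kind = kind, gene_id = gid,
        chrom = cn, strand = strand,
        a = NA_integer_,
        b = if (is.na(shared_c)) i2[1L] else NA_integer_,
        p = maj_e[1L], q = maj_e[2L], p2 = alt_e[1L], q2 = alt_e[2L],
        c = shared_c, d = NA_integer_,
        target_ratio = s_ratio, stringsAsFactors = FALSE)
      if (config$couple_strength %in% c("planted", "uniform_strong")) {
        side <- if (!is.na(shared_c)) "intron_start" else "intron_end"
        side_type <- site_model_for_side(side, strand)
        maj_site <- if (!is.na(shared_c)) maj_e[2L] else maj_e[1L]
        alt_site <- if (!is.na(shared_c)) alt_e[2L] else alt_e[1L]
        if (config$couple_strength == "uniform_strong") {
          plant_motif(side_type, maj_site, strand, "strong")
          plant_motif(side_type, alt_site, strand, "strong")
        } else {
          plant_planned_motif(side_type, maj_site, strand,
                              motif_with_consensus(side_type,
                                                   0.9 - 0.6 * s_ratio))
          plant_planned_motif(side_type, alt_site, strand,
                              motif_with_consensus(side_type,
                                                   0.3 + 0.6 * s_ratio))
        }
      }
    } else if (kind == "NOVEL_EXON") {
      isl <- c(gene_end + 400L, gene_end + 700L)
      je <- isl[1L] + 50L
      add_junction(e3[2L], je, strand, depth)
      plant_intron_ends(e3[2L], je, strand)
      cov_blocks[[length(cov_blocks) + 1L]] <- c(isl, depth)
      novel_truth[[length(novel_truth) + 1L]] <- data.frame(
        kind = "NOVEL_EXON", chrom = cn, exon1_start = je,
        exon1_end = isl[2L], exon2_start = NA_integer_,
        exon2_end = NA_integer_, stringsAsFactors = FALSE)
      gene_end <- isl[2L]
    }

    # annotated intron junctions (inclusion junctions for CE genes)
    add_junction(i1[1L], i1[2L], strand, j1_support)
    add_junction(i2[1L], i2[2L], strand, j2_support)
    if (intron_noise[1L]) noise_introns[[length(noise_introns) + 1L]] <- i1
    if (intron_noise[2L]) noise_introns[[length(noise_introns) + 1L]] <- i2

    # decoy junction filtered out by the score threshold
    if (stats::runif(1) < config$decoy_fraction) {
      add_junction(e1[2L] + 7L, e1[2L] + 57L, strand, 3L,
                   score = stats::runif(1, 0, 0.5))
    }

    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, chrom = cn,
      start = min(vapply(ex_list, `[`, integer(1), 1L)),
      end = max(vapply(ex_list, `[`, integer(1), 2L)),
      strand = strand, provenance = "annotated", stringsAsFactors = FALSE)
    for (tx in tx_list) {
      transcripts[[length(transcripts) + 1L]] <- data.frame(
        transcript_id = tx$id, gene_id = gid, provenance = "annotated",
        stringsAsFactors = FALSE)
      for (k in tx$exons) {
        exons[[length(exons) + 1L]] <- data.frame(
          transcript_id = tx$id, gene_id = gid, chrom = cn,
          start = ex_list[[k]][1L], end = ex_list[[k]][2L], strand = strand,
          provenance = "annotated", stringsAsFactors = FALSE)
      }
    }
    # per-exon methylation flags: depletion + bisulfite records.  When CpG
    # content is coupled to the planted ratio, flag-based depletion is
    # suppressed on event genes so it cannot overwrite the planted signal.
    skip_depletion <- config$couple_methylation == "planted" &&
      kind %in% c("CE", "ALT_DONOR", "ALT_ACCEPTOR")
    for (k in seq_along(ex_list)) {
      flagged <- stats::runif(1) < config$methylated_fraction
      exon_flags[[length(exon_flags) + 1L]] <- data.frame(
        gene_id = gid, start = ex_list[[k]][1L], end = ex_list[[k]][2L],
        methylated = flagged, stringsAsFactors = FALSE)
      if (flagged && !skip_depletion) {
        seq_edits[[length(seq_edits) + 1L]] <- list(
          ex_list[[k]][1L] + 3L,
          paste(random_seq(ex_list[[k]][2L] - ex_list[[k]][1L] - 26L,
                           keep_cpg = config$cpg_depletion), collapse = ""))
      }
    }
    pos <- gene_end + spacing
  }

  total_len <- pos
  base <- random_seq(total_len)
  apply_edits <- function(base, edits) {
    for (ed in edits) {
      s <- strsplit(ed[[2L]], "")[[1]]
      base[(ed[[1L]] + 1L):(ed[[1L]] + length(s))] <- s
    }
    base
  }
  base <- apply_edits(base, seq_edits)
  base <- apply_edits(base, motif_edits)
  genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(genome) <- cn

  model <- gene_model(do.call(rbind, genes),
                      do.call(rbind, transcripts),
                      do.call(rbind, exons))
  junctions <- merge_junctions(do.call(rbind, junc))

  cov <- numeric(total_len)
  lambda <- config$noise_factor * depth
  for (it in noise_introns) {
    n <- it[2L] - it[1L]
    cov[(it[1L] + 1L):it[2L]] <- stats::rpois(n, lambda)
  }
  # uniform blocks (exons, planted retained introns, islands) overwrite noise
  for (b in cov_blocks) cov[(b[1L] + 1L):b[2L]] <- b[3L]
  coverage <- coverage_track(stats::setNames(list(cov), cn))

  # bisulfite records at CpG positions of flagged/unflagged exons
  flags <- do.call(rbind, exon_flags)
  for (i in seq_len(nrow(flags))) {
    s <- paste(base[(flags$start[i] + 1L):flags$end[i]], collapse = "")
    cg <- Biostrings::start(Biostrings::matchPattern("CG",
                                                     Biostrings::DNAString(s)))
    cg <- utils::head(cg, 15L)
    if (length(cg) == 0L) next
    methylated <- if (flags$methylated[i]) {
      1L + stats::rbinom(length(cg), 9L, 0.7)
    } else rep(0L, length(cg))
    meth[[length(meth) + 1L]] <- data.frame(
      chrom = cn, pos = flags$start[i] + cg - 1L, strand = "+",
      context = "CG", methylated = methylated, total = 10L,
      stringsAsFactors = FALSE)
  }
  methylation <- if (length(meth)) do.call(rbind, meth) else
    empty_methylation()
  methylation <- methylation[order(methylation$chrom, methylation$pos,
                                   methylation$strand), , drop = FALSE]
  rownames(methylation) <- NULL

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(event_id = character(), kind = character(),
               gene_id = character(), chrom = character(),
               strand = character(), a = integer(), b = integer(),
               p = integer(), q = integer(), p2 = integer(), q2 = integer(),
               c = integer(), d = integer(), target_ratio = numeric(),
               stringsAsFactors = FALSE)
  novel_df <- if (length(novel_truth)) do.call(rbind, novel_truth) else NULL
  rownames(truth_df) <- NULL

  out <- list(genome = genome, model = model, junctions = junctions,
              coverage = coverage, methylation = methylation,
              truth = truth_df, novel_truth = novel_df, exon_flags = flags,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(genome = file.path(out_dir, "genome.fa"),
                  gff3 = file.path(out_dir, "annotation.gff3"),
                  junctions = file.path(out_dir, "junctions.tsv"),
                  coverage = file.path(out_dir, "coverage.bedGraph"),
                  methylation = file.path(out_dir, "methylation.tsv"),
                  truth = file.path(out_dir, "truth.tsv"))
    write_genome(genome, files$genome)
    write_gff3(model, files$gff3)
    write_junctions(junctions, files$junctions)
    write_coverage(coverage, files$coverage)
    write_methylation(methylation, files$methylation)
    write_truth(truth_df, files$truth)
    out$files <- files
  }
  out
}

# truth table TSV: coordinates packed into one colon-separated field
write_truth <- function(truth, path) {
  lines <- "#event_id\tkind\tgene\tchrom\tcoords\ttarget_ratio"
  if (nrow(truth) > 0L) {
    coords <- apply(truth[, c("a", "b", "p", "q", "p2", "q2", "c", "d")], 1L,
                    function(v) paste(ifelse(is.na(v), ".", v), collapse = ":"))
    lines <- c(lines, paste(truth$event_id, truth$kind, truth$gene_id,
                            truth$chrom, coords,
                            format_num(truth$target_ratio), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
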