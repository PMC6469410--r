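#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' For combined sample sizes up to 20 the null distribution is enumerated
#' exactly over all group assignments (ties handled with midranks, so
#' identical groups give p = 1).  Larger samples use the normal
#' approximation with tie correction.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return two-sided p-value.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  n1 <- length(a); n <- n1 + length(b)
  if (n <= 20L) {
    pooled <- c(a, b)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n1)])
    mu <- n1 * (n + 1) / 2
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    eps <- sqrt(.Machine$double.eps)
    mean(abs(w_all - mu) >= abs(w_obs - mu) - eps)
  } else {
    stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                       correct = TRUE)$p.value
  }
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with its default:
#' junctions must score strictly above `min_score` (0.5); a retained intron
#' needs every base strictly above `ir_min_depth` (5x) and an inclusion
#' ratio of at least three times `ir_baseline` (0.017, a genome-wide
#' average intron inclusion ratio); alternative boundaries are accepted at
#' displacements strictly below `aeb_window` (200 bp).
#'
#' @param gff3,junctions,coverage,genome,methylation,orthologs input paths
#'   (`methylation` and `orthologs` optional, `NULL` to skip).
#' @param min_score junction confidence threshold (strict).
#' @param ir_min_depth IR per-base depth threshold (strict).
#' @param ir_baseline genome-wide baseline intron inclusion ratio.
#' @param aeb_window AEB displacement bound in bp (exclusive).
#' @param island_min_depth,island_min_len,island_max_gap transcribed-island
#'   parameters (see [find_transcribed_islands()]).
#' @param bins inclusion/splicing-ratio bin edges, strictly increasing
#'   within \[0,1\].
#' @param out_dir output directory for the report bundle.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(gff3, junctions, coverage, genome,
                            methylation = NULL, orthologs = NULL,
                            min_score = 0.5, ir_min_depth = 5,
                            ir_baseline = 0.017, aeb_window = 200,
                            island_min_depth = 5, island_min_len = 50,
                            island_max_gap = 10,
                            bins = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                            out_dir = NULL) {
  stopifnot(min_score >= 0, ir_min_depth > 0, ir_baseline > 0,
            aeb_window > 0, island_min_depth > 0)
  if (any(diff(bins) <= 0) || min(bins) < 0 || max(bins) > 1) {
    stop("bin edges must be strictly increasing within [0,1]")
  }
  structure(list(gff3 = gff3, junctions = junctions, coverage = coverage,
                 genome = genome, methylation = methylation,
                 orthologs = orthologs, min_score = min_score,
                 ir_min_depth = ir_min_depth, ir_baseline = ir_baseline,
                 aeb_window = aeb_window,
                 island_min_depth = island_min_depth,
                 island_min_len = island_min_len,
                 island_max_gap = island_max_gap, bins = bins,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full splicing analysis pipeline
#'
#' Mirrors the analysis order: read inputs, filter junctions, find
#' transcribed islands, augment the gene model with novel exons and
#' intergenic transcripts, detect and quantify all AS event kinds, compute
#' displacement spectra, train donor/acceptor strength models on the
#' annotation and run the strength and methylation comparisons, and join
#' the conservation table.  Deterministic given identical inputs.  When
#' `config$out_dir` is set, writes `events.tsv`, `augmented.gff3`,
#' `summary.json` (a manifest with all parameters and headline tables).
#'
#' @param config a [pipeline_config()].
#' @return list with `model` (augmented), `events`, `counts`
#'   (per-kind event/exon/gene counts), `spectrum`, `strength`,
#'   `relative_strength`, `methylation` (when inputs allow),
#'   `conservation` (when a table is given), and `params`.
#' @export
run_pipeline <- function(config) {
  genome <- read_genome(config$genome)
  model <- read_gff3(config$gff3)
  junctions <- read_junctions(config$junctions)
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  coverage <- read_coverage(config$coverage, chrom_lengths)
  bad <- setdiff(unique(c(model$exons$chrom, junctions$chrom)), names(genome))
  if (length(bad) > 0L) {
    stop("chromosome names not in genome: ", paste(bad, collapse = ", "))
  }

  part <- filter_junctions(junctions, model, config$min_score)
  islands <- find_transcribed_islands(coverage, model,
                                      config$island_min_depth,
                                      config$island_min_len,
                                      config$island_max_gap)
  model_aug <- augment_model(model, part, islands, genome)
  events <- detect_as(model_aug, junctions, coverage,
                      min_score = config$min_score,
                      baseline = config$ir_baseline,
                      min_depth = config$ir_min_depth,
                      max_displacement = config$aeb_window)
  counts <- event_counts(events, model_aug)
  spectrum <- displacement_spectrum(events)

  don_seqs <- splice_site_sequences(model_aug, genome, "donor")
  acc_seqs <- splice_site_sequences(model_aug, genome, "acceptor")
  bg <- genome_base_freq(genome)
  strength <- NULL; relative_strength <- NULL
  model_d <- model_a <- NULL
  if (length(don_seqs) >= 10L && length(acc_seqs) >= 10L) {
    model_d <- train_splice_model(don_seqs, "donor", background = bg)
    model_a <- train_splice_model(acc_seqs, "acceptor", background = bg)
    retained <- rbind(part$known,
                      part$half_known[, names(part$known), drop = FALSE])
    strength <- strength_vs_inclusion(events, model_d, model_a, genome,
                                      config$bins)
    relative_strength <- relative_strength_vs_splicing_ratio(
      events, model_d, model_a, genome, retained, config$bins)
  }

  methylation <- methylation_vs_inclusion(events, genome, config$bins,
                                          model = model_aug)
  if (!is.null(config$methylation)) {
    calls <- read_methylation(config$methylation)
    methylation$status <- methylation_status_summary(events, genome, calls)
  }
  conservation <- NULL
  if (!is.null(config$orthologs)) {
    conservation <- conservation_summary(events, read_orthologs(config$orthologs))
  }

  out <- list(model = model_aug, events = events, counts = counts,
              spectrum = spectrum, strength = strength,
              relative_strength = relative_strength,
              methylation = methylation, conservation = conservation,
              params = unclass(config))
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' Per-kind event counts
#'
#' The per-kind table mirrors the usual summary layout: number of events,
#' number of exons involved (for retained introns the two flanking exons
#' count as involved), and the number (and fraction) of genes undergoing
#' each kind of AS.
#'
#' @param events event data.frame.
#' @param model [gene_model()] supplying the gene universe for fractions.
#' @return data.frame with columns `kind`, `n_events`, `exons_involved`,
#'   `n_genes`, `gene_fraction`.
#' @export
event_counts <- function(events, model) {
  kinds <- c("IR", "CE", "ALT_DONOR", "ALT_ACCEPTOR", "AFE", "ALE")
  n_genes_total <- max(nrow(model$genes), 1L)
  out <- lapply(kinds, function(k) {
    sub <- events[events$kind == k, , drop = FALSE]
    exons <- if (k == "IR") 2L * nrow(sub) else nrow(sub)
    data.frame(kind = k, n_events = nrow(sub), exons_involved = exons,
               n_genes = length(unique(sub$gene_id)),
               gene_fraction = length(unique(sub$gene_id)) / n_genes_total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_events(result$events, file.path(out_dir, "events.tsv"))
  write_gff3(result$model, file.path(out_dir, "augmented.gff3"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("beesplice")),
    params = result$params[!vapply(result$params, is.null, logical(1)) &
                             names(result$params) != "out_dir"],
    counts = result$counts,
    spectrum = result$spectrum[c("aeb_mod3_fraction", "ce_mod3_fraction")],
    strength_tests = if (!is.null(result$strength)) result$strength$tests,
    relative_strength_tests = if (!is.null(result$relative_strength))
      result$relative_strength$tests,
    methylation_tests = if (!is.null(result$methylation))
      result$methylation$tests,
    conservation = if (!is.null(result$conservation))
      as.list(result$conservation$summary))
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  jsonlite::write_json(manifest, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
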