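# Hand-built fixtures shared across test files.  All coordinates are
# 0-based half-open unless a file format dictates otherwise.

# a three-exon plus-strand gene on a 10 kb chromosome:
#   exon1 100-200, intron1 200-1200, exon2 1200-1400, intron2 1400-2400,
#   exon3 2400-2600
toy_model <- function(strand = "+") {
  gene_model(
    genes = data.frame(gene_id = "gA", chrom = "chr1", start = 100L,
                       end = 2600L, strand = strand,
                       provenance = "annotated", stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = "gA.t1", gene_id = "gA",
                             provenance = "annotated",
                             stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = "gA.t1", gene_id = "gA",
                       chrom = "chr1", start = c(100L, 1200L, 2400L),
                       end = c(200L, 1400L, 2600L), strand = strand,
                       provenance = "annotated", stringsAsFactors = FALSE))
}

make_junctions <- function(start, end, strand = "+", score = 0.9,
                           support = 10L, chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, score = score, support = as.integer(support),
             stringsAsFactors = FALSE)
}

flat_coverage <- function(len = 10000L, depth = 0, chrom = "chr1") {
  coverage_track(stats::setNames(list(rep(as.numeric(depth), len)), chrom))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_genome <- function(len = 10000L, chrom = "chr1") {
  g <- Biostrings::DNAStringSet(random_dna(len))
  names(g) <- chrom
  g
}

# small, fast simulation used by several files
small_sim <- function(seed = 7, out_dir = NULL, ...) {
  args <- list(n_genes = 60, seed = seed, n_ce = 8, n_ir = 8,
               n_alt_donor = 6, n_alt_acceptor = 6, n_afe = 4, n_ale = 4,
               n_novel_exon = 4, n_novel_transcript = 2)
  over <- list(...)
  args[names(over)] <- over
  simulate_splicing_data(do.call(simulation_config, args), out_dir = out_dir)
}

# reverse-complement an entire simulated dataset: genome, model, junctions,
# coverage.  A feature [s, e) maps to [L - e, L - s) and strands flip.
flip_dataset <- function(sim) {
  L <- length(sim$genome[[1]])
  cn <- names(sim$genome)
  flip_iv <- function(s, e) list(start = L - e, end = L - s)
  flip_strand <- function(s) ifelse(s == "+", "-", ifelse(s == "-", "+", s))

  genome <- Biostrings::DNAStringSet(
    Biostrings::reverseComplement(sim$genome[[1]]))
  names(genome) <- cn

  ex <- sim$model$exons
  iv <- flip_iv(ex$start, ex$end)
  ex$start <- iv$start; ex$end <- iv$end; ex$strand <- flip_strand(ex$strand)
  g <- sim$model$genes
  iv <- flip_iv(g$start, g$end)
  g$start <- iv$start; g$end <- iv$end; g$strand <- flip_strand(g$strand)
  model <- gene_model(g, sim$model$transcripts, ex)

  j <- sim$junctions
  iv <- flip_iv(j$start, j$end)
  j$start <- iv$start; j$end <- iv$end; j$strand <- flip_strand(j$strand)
  j <- j[order(j$chrom, j$start, j$end), , drop = FALSE]
  rownames(j) <- NULL

  coverage <- coverage_track(stats::setNames(list(rev(sim$coverage[[cn]])),
                                             cn))
  list(genome = genome, model = model, junctions = j, coverage = coverage,
       L = L)
}

# map detected events of the flipped dataset back to original coordinates
unflip_events <- function(ev, L) {
  sw <- function(x, y) {
    tmp <- L - ev[[x]]
    ev[[x]] <<- L - ev[[y]]
    ev[[y]] <<- tmp
  }
  sw("a", "b"); sw("p", "q"); sw("p2", "q2"); sw("c", "d")
  # after mirroring, upstream/downstream exons swap roles
  tmp <- ev[, c("a", "b")]
  ev[, c("a", "b")] <- ev[, c("c", "d")]
  ev[, c("c", "d")] <- tmp
  ev$strand <- ifelse(ev$strand == "+", "-", "+")
  ev
}

event_key <- function(ev) {
  # kind + location signature robust to which columns a kind fills
  apply(ev[, c("kind", "chrom", "strand", "p", "q", "p2", "q2")], 1L,
        function(r) paste(ifelse(is.na(r), ".", trimws(r)), collapse = "|"))
}
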