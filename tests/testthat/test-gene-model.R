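test_that("derived introns are the gaps between consecutive exons", {
  m <- toy_model()
  introns <- model_introns(m)
  expect_equal(introns$start, c(200L, 1400L))
  expect_equal(introns$end, c(1200L, 2400L))
  expect_equal(introns$a, c(100L, 1200L))
  expect_equal(introns$d, c(1400L, 2600L))
  expect_equal(nrow(model_introns(gene_model())), 0L)
})

test_that("overlapping exons within a transcript are rejected", {
  expect_error(gene_model(
    genes = data.frame(gene_id = "g", chrom = "c", start = 0L, end = 100L,
                       strand = "+", provenance = "annotated"),
    transcripts = data.frame(transcript_id = "t", gene_id = "g",
                             provenance = "annotated"),
    exons = data.frame(transcript_id = "t", gene_id = "g", chrom = "c",
                       start = c(0L, 30L), end = c(50L, 80L), strand = "+",
                       provenance = "annotated")),
    "overlapping exons")
})

test_that("junction filtering drops score <= 0.5 (strict) and partitions by boundary match", {
  m <- toy_model()
  j <- rbind(
    make_junctions(200, 1200, score = 0.5),    # exactly at threshold: dropped
    make_junctions(200, 1200, score = 0.51),   # known intron
    make_junctions(200, 2400, score = 0.9),    # skip junction: both known
    make_junctions(200, 1100, score = 0.9),    # half known (novel end)
    make_junctions(150, 1200, score = 0.9),    # half known (novel start)
    make_junctions(5000, 6000, score = 0.9))   # both novel
  part <- filter_junctions(j, m)
  expect_equal(nrow(part$known) + nrow(part$half_known) +
                 nrow(part$both_novel), 5L)
  expect_equal(sort(part$known$end), c(1200L, 2400L))
  expect_equal(sort(part$half_known$novel_side), c("end", "start"))
  expect_equal(part$both_novel$start, 5000L)
})

test_that("junction partition equals brute-force boundary classification", {
  sim <- small_sim(seed = 13)
  set.seed(99)
  n <- 1000L
  L <- length(sim$genome[[1]])
  j <- data.frame(chrom = "chr1",
                  start = as.integer(sample(L - 6000L, n)),
                  strand = sample(c("+", "-"), n, TRUE),
                  score = runif(n), support = 5L, stringsAsFactors = FALSE)
  j$end <- j$start + as.integer(sample(100:5000, n, TRUE))
  # add real boundaries so all three classes occur
  j <- rbind(j, sim$junctions)
  part <- filter_junctions(j, sim$model)
  ex <- sim$model$exons
  starts <- paste(ex$chrom, ex$strand, ex$end)
  ends <- paste(ex$chrom, ex$strand, ex$start)
  keep <- j[j$score > 0.5, ]
  sk <- paste(keep$chrom, keep$strand, keep$start) %in% starts
  ek <- paste(keep$chrom, keep$strand, keep$end) %in% ends
  expect_equal(nrow(part$known), sum(sk & ek))
  expect_equal(nrow(part$half_known), sum(xor(sk, ek)))
  expect_equal(nrow(part$both_novel), sum(!sk & !ek))
})

test_that("transcribed islands: empty coverage, one planted block, run-length oracle", {
  m <- toy_model()
  expect_equal(nrow(find_transcribed_islands(flat_coverage(), m)), 0L)

  cov <- flat_coverage()
  cov[["chr1"]][5001:5300] <- 20
  isl <- find_transcribed_islands(cov, m)
  expect_equal(isl$start, 5000L)
  expect_equal(isl$end, 5300L)

  # exon-overlapping block is discarded
  cov2 <- flat_coverage()
  cov2[["chr1"]][151:400] <- 20
  expect_equal(nrow(find_transcribed_islands(cov2, m)), 0L)

  # random coverage versus a direct per-base scan with gap merging
  set.seed(4)
  v <- as.numeric(rpois(4000, 4))
  cov3 <- coverage_track(list(chrZ = v))
  empty <- gene_model()
  isl3 <- find_transcribed_islands(cov3, empty, min_depth = 5,
                                   min_len = 20, max_gap = 3)
  ok <- v >= 5
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths
  blocks <- cbind(starts[runs$values], ends[runs$values])
  if (nrow(blocks) > 1L) {
    merged <- blocks[1, , drop = FALSE]
    for (i in 2:nrow(blocks)) {
      if (blocks[i, 1] - merged[nrow(merged), 2] <= 3) {
        merged[nrow(merged), 2] <- blocks[i, 2]
      } else merged <- rbind(merged, blocks[i, ])
    }
    blocks <- merged
  }
  blocks <- blocks[blocks[, 2] - blocks[, 1] >= 20, , drop = FALSE]
  expect_equal(cbind(isl3$start, isl3$end), unname(blocks))
})

test_that("augmentation adds planted novel exons and intergenic transcripts", {
  sim <- small_sim(seed = 17)
  part <- filter_junctions(sim$junctions, sim$model)
  isl <- find_transcribed_islands(sim$coverage, sim$model)
  aug <- augment_model(sim$model, part, isl, sim$genome)
  truth <- sim$novel_truth

  ne <- truth[truth$kind == "NOVEL_EXON", ]
  got <- aug$exons[aug$exons$provenance == "novel", ]
  hits <- sum(ne$exon1_start %in% got$start)
  expect_gte(hits, nrow(ne) - 1L)    # junction-side boundary exact

  nt <- truth[truth$kind == "NOVEL_TX", ]
  novel_genes <- aug$genes[aug$genes$provenance == "novel", ]
  expect_equal(nrow(novel_genes), nrow(nt))

  # annotated features untouched
  expect_equal(aug$exons[aug$exons$provenance == "annotated",
                         c("start", "end")],
               sim$model$exons[, c("start", "end")], ignore_attr = TRUE)
})

test_that("augmentation is idempotent", {
  sim <- small_sim(seed = 17)
  part <- filter_junctions(sim$junctions, sim$model)
  isl <- find_transcribed_islands(sim$coverage, sim$model)
  aug1 <- augment_model(sim$model, part, isl, sim$genome)
  part2 <- filter_junctions(sim$junctions, aug1)
  isl2 <- find_transcribed_islands(sim$coverage, aug1)
  aug2 <- augment_model(aug1, part2, isl2, sim$genome)
  expect_equal(nrow(aug2$exons), nrow(aug1$exons))
  expect_equal(nrow(aug2$genes), nrow(aug1$genes))
})
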