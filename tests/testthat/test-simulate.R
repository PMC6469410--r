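test_that("a fixed seed yields a byte-identical file set", {
  cfg <- simulation_config(n_genes = 15, seed = 41, n_ce = 3, n_ir = 3,
                           n_alt_donor = 2, n_alt_acceptor = 2, n_afe = 1,
                           n_ale = 1, n_novel_exon = 1,
                           n_novel_transcript = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_splicing_data(cfg, d1)
  simulate_splicing_data(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("a zero-event configuration produces no CE/AEB/ATE and no IR", {
  sim <- small_sim(seed = 2, n_ce = 0, n_ir = 0, n_alt_donor = 0,
                   n_alt_acceptor = 0, n_afe = 0, n_ale = 0,
                   n_novel_exon = 0, n_novel_transcript = 0, n_genes = 40)
  # junctions exactly match the annotated introns after filtering
  part <- filter_junctions(sim$junctions, sim$model)
  expect_equal(nrow(part$half_known), 0L)
  expect_equal(nrow(part$both_novel), 0L)
  ev <- detect_as(sim$model, sim$junctions, sim$coverage)
  expect_equal(sum(ev$kind %in% c("CE", "ALT_DONOR", "ALT_ACCEPTOR",
                                  "AFE", "ALE")), 0L)
  # intronic noise at 0.017x of 100x depth never clears the >5x floor
  expect_equal(sum(ev$kind == "IR"), 0L)
})

test_that("canonical GT/AG dinucleotides sit at every annotated intron boundary", {
  sim <- small_sim(seed = 19)
  introns <- model_introns(sim$model)
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    don <- beesplice:::interval_seq(sim$genome, it$chrom, it$start,
                                    it$start + 2L)
    acc <- beesplice:::interval_seq(sim$genome, it$chrom, it$end - 2L,
                                    it$end)
    if (it$strand == "+") {
      expect_equal(paste0(don, acc), "GTAG")
    } else {
      expect_equal(paste0(don, acc), "CTAC")
    }
  }
})

test_that("recomputed metrics converge to the planted ratios at high depth", {
  sim <- small_sim(seed = 29, depth = 1000, n_ce = 10, n_ir = 10,
                   n_alt_donor = 6, n_alt_acceptor = 6, n_afe = 5,
                   n_ale = 5, n_novel_exon = 0, n_novel_transcript = 0,
                   n_genes = 50)
  ev <- detect_as(sim$model, sim$junctions, sim$coverage)
  m <- merge(sim$truth, ev, by = c("gene_id", "kind"))
  expect_equal(nrow(m), nrow(sim$truth))
  recomputed <- ifelse(m$kind %in% c("CE", "IR"),
                       m$inclusion_ratio, m$splicing_ratio)
  expect_lt(max(abs(recomputed - m$target_ratio)), 0.05)
  for (k in unique(m$kind)) {
    err <- abs(recomputed - m$target_ratio)[m$kind == k]
    expect_lt(mean(err), 0.02, label = paste("mean ratio error for", k))
  }
})

test_that("CE ratios on the planted grid are recovered within binomial error", {
  sim <- small_sim(seed = 31, n_genes = 110, n_ce = 50, n_ir = 0,
                   n_alt_donor = 0, n_alt_acceptor = 0, n_afe = 0,
                   n_ale = 0, n_novel_exon = 0, n_novel_transcript = 0)
  ev <- detect_as(sim$model, sim$junctions, sim$coverage)
  ce <- ev[ev$kind == "CE", ]
  expect_equal(nrow(ce), 50L)
  m <- merge(sim$truth, ce, by = "gene_id")
  expect_equal(nrow(m), 50L)
  expect_lt(mean(abs(m$inclusion_ratio - m$target_ratio)), 0.05)
})

test_that("CpG depletion makes flagged exons score below unflagged ones", {
  sim <- small_sim(seed = 5, n_genes = 70, n_ce = 0, n_ir = 0,
                   n_alt_donor = 0, n_alt_acceptor = 0, n_afe = 0, n_ale = 0,
                   n_novel_exon = 0, n_novel_transcript = 0)
  fl <- sim$exon_flags
  expect_gte(nrow(fl), 200L)
  oe <- vapply(seq_len(nrow(fl)), function(i)
    cpg_oe(sim$genome, "chr1", fl$start[i], fl$end[i])$oe, numeric(1))
  expect_lt(mean(oe[fl$methylated]), mean(oe[!fl$methylated]))
  # flagged exons carry methylated calls, unflagged only unmethylated ones
  expect_gt(sum(sim$methylation$methylated), 0L)
  st <- vapply(seq_len(nrow(fl)), function(i)
    region_methylation_status("chr1", fl$start[i], fl$end[i],
                              sim$methylation), character(1))
  expect_true(all(st[fl$methylated & st != "no_data"] == "methylated"))
  expect_true(all(st[!fl$methylated & st != "no_data"] == "unmethylated"))
})

test_that("strength planting is reproducible and controls score separation", {
  set.seed(1)
  strong <- replicate(50, sample_splice_motif("donor", "strong"))
  weak <- replicate(50, sample_splice_motif("donor", "weak"))
  md <- train_splice_model(c(strong, weak), "donor")
  s_strong <- vapply(strong, function(x) beesplice:::score_motif(md, x),
                     numeric(1))
  s_weak <- vapply(weak, function(x) beesplice:::score_motif(md, x),
                   numeric(1))
  expect_gt(median(s_strong), median(s_weak))
  expect_lt(mann_whitney(s_strong, s_weak), 0.01)
  # all-strong planting leaves nothing to distinguish
  set.seed(2)
  g1 <- replicate(30, sample_splice_motif("donor", "strong"))
  g2 <- replicate(30, sample_splice_motif("donor", "strong"))
  mu <- train_splice_model(c(g1, g2), "donor")
  p <- mann_whitney(vapply(g1, function(x) beesplice:::score_motif(mu, x),
                           numeric(1)),
                    vapply(g2, function(x) beesplice:::score_motif(mu, x),
                           numeric(1)))
  expect_gt(p, 0.05)
})
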