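test_that("a junction joining non-adjacent exon boundaries yields a cassette exon", {
  m <- toy_model()
  skip <- make_junctions(200, 2400)         # exon1 end -> exon3 start
  ce <- detect_ce(m, skip)
  expect_equal(nrow(ce), 1L)
  expect_equal(ce$p, 1200L)
  expect_equal(ce$q, 1400L)
  expect_equal(ce$b, 200L)
  expect_equal(ce$c, 2400L)

  adj <- make_junctions(200, 1200)          # adjacent exons: no CE
  expect_equal(nrow(detect_ce(m, adj)), 0L)
})

test_that("CE inclusion ratio follows the junction-support formula", {
  m <- toy_model()
  ce <- detect_ce(m, make_junctions(200, 2400))
  j <- rbind(make_junctions(200, 1200, support = 10),
             make_junctions(1400, 2400, support = 10),
             make_junctions(200, 2400, support = 10))
  expect_equal(compute_ce_ratio(ce, j), 0.5)

  # no skip support -> ratio 1
  j2 <- rbind(make_junctions(200, 1200, support = 5),
              make_junctions(1400, 2400, support = 7))
  expect_equal(compute_ce_ratio(ce, j2), 1)

  # all three zero -> NA
  j3 <- make_junctions(200, 2400, support = 0)
  expect_true(is.na(compute_ce_ratio(ce, j3)))

  # random support triples equal the formula evaluated directly
  set.seed(8)
  for (i in 1:200) {
    sup <- sample(0:100, 3L, replace = TRUE)
    jj <- rbind(make_junctions(200, 1200, support = sup[1]),
                make_junctions(1400, 2400, support = sup[2]),
                make_junctions(200, 2400, support = sup[3]))
    inc <- (sup[1] + sup[2]) / 2
    want <- if (inc + sup[3] == 0) NA_real_ else inc / (inc + sup[3])
    expect_identical(compute_ce_ratio(ce, jj), want)
  }
})

test_that("IR inclusion ratio equals the coverage-mean formula, unclamped", {
  m <- toy_model()
  cov <- flat_coverage(depth = 50)
  ir_ev <- beesplice:::event_row("IR", "gA", "chr1", "+", a = 100, b = 200,
                                 p = 200, q = 1200, c = 1200, d = 1400)
  expect_equal(compute_ir_ratio(ir_ev, cov), 1)

  cov2 <- flat_coverage()
  cov2[["chr1"]][101:200] <- 20     # Cov(a,p)
  cov2[["chr1"]][1201:1400] <- 20   # Cov(q,d)
  cov2[["chr1"]][201:1200] <- 10    # Cov(p,q)
  expect_equal(compute_ir_ratio(ir_ev, cov2), 0.5)

  # random tracks versus direct per-base means; ratio may exceed 1
  set.seed(12)
  for (i in 1:50) {
    v <- as.numeric(rpois(1400, 8))
    covr <- coverage_track(list(chr1 = v))
    want <- 2 * mean(v[201:1200]) / (mean(v[101:200]) + mean(v[1201:1400]))
    expect_equal(compute_ir_ratio(ir_ev, covr), want, tolerance = 1e-12)
  }
})

test_that("IR detection applies both depth and baseline-ratio criteria exactly", {
  m <- toy_model()
  # depth 4 everywhere in the intron: fails the strict >5 criterion
  cov <- flat_coverage(depth = 100)
  cov[["chr1"]][201:1200] <- 4
  cov[["chr1"]][1401:2400] <- 0
  expect_equal(nrow(detect_ir(m, cov)), 0L)

  # min depth exactly 5 still fails (strict inequality)
  cov[["chr1"]][201:1200] <- 5
  expect_equal(nrow(detect_ir(m, cov)), 0L)

  # ratio exactly 3 x 0.017 = 0.051 passes; flanks 200x, intron 10.2x
  cov2 <- flat_coverage(depth = 200)
  cov2[["chr1"]][201:1200] <- 10.2
  cov2[["chr1"]][1401:2400] <- 0
  ir <- detect_ir(m, cov2)
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$inclusion_ratio, 0.051)

  # high retained depth: ratio 2.0, detected with intron coordinates
  cov3 <- flat_coverage(depth = 100)
  cov3[["chr1"]][1401:2400] <- 0
  cov3[["chr1"]][201:1200] <- 100
  ir3 <- detect_ir(m, cov3)
  expect_equal(ir3$p, 200L)
  expect_equal(ir3$inclusion_ratio, 2 * 100 / (100 + 100) * 1)
})

test_that("alternative boundaries respect the 200 bp window and side assignment", {
  m <- toy_model()
  # novel donor 3 nt into the exon on + strand: ALT_DONOR, displacement 3
  part <- filter_junctions(make_junctions(197, 1200), m)
  ev <- detect_aeb(m, part$half_known)
  expect_equal(ev$kind, "ALT_DONOR")
  expect_equal(ev$displacement, 3L)
  expect_equal(ev$q2, 197L)

  # same geometry on the minus strand is an alternative acceptor
  mm <- toy_model(strand = "-")
  part_m <- filter_junctions(make_junctions(197, 1200, strand = "-"), mm)
  ev_m <- detect_aeb(mm, part_m$half_known)
  expect_equal(ev_m$kind, "ALT_ACCEPTOR")

  # displacement exactly 200 is rejected (strict < 200)
  part200 <- filter_junctions(make_junctions(200, 1400), m)
  expect_equal(part200$half_known$novel_side, "end")
  expect_equal(nrow(detect_aeb(m, part200$half_known)), 0L)
  # one less is accepted
  part199 <- filter_junctions(make_junctions(200, 1399), m)
  ev199 <- detect_aeb(m, part199$half_known)
  expect_equal(ev199$displacement, 199L)
  expect_equal(ev199$kind, "ALT_ACCEPTOR")

  # novel end crossing the opposite exon boundary is not an AEB
  part_cross <- filter_junctions(make_junctions(50, 1200), m)
  expect_equal(nrow(detect_aeb(m, part_cross$half_known)), 0L)
})

test_that("AEB splicing and inclusion ratios follow the min/max and region formulas", {
  m <- toy_model()
  part <- filter_junctions(make_junctions(1400, 2390), m)  # alt acceptor 2390 for intron 1400-2400
  ev <- detect_aeb(m, part$half_known)
  expect_equal(ev$kind, "ALT_ACCEPTOR")

  j <- rbind(make_junctions(1400, 2400, support = 5),
             make_junctions(1400, 2390, support = 10))
  r <- compute_aeb_ratios(ev, j)
  expect_equal(r$splicing_ratio, 0.5)
  # region [2390, 2400): retained by the junction ending at 2390
  expect_equal(r$inclusion_ratio, 10 / 15)

  # tie gives splicing ratio 1
  j_tie <- rbind(make_junctions(1400, 2400, support = 7),
                 make_junctions(1400, 2390, support = 7))
  expect_equal(compute_aeb_ratios(ev, j_tie)$splicing_ratio, 1)

  # both zero -> NA
  j0 <- make_junctions(1400, 2400, support = 0)
  expect_true(is.na(compute_aeb_ratios(ev, j0)$splicing_ratio))

  # random pairs equal the direct formulas
  set.seed(5)
  for (i in 1:200) {
    sup <- sample(0:60, 2L, replace = TRUE)
    jj <- rbind(make_junctions(1400, 2400, support = sup[1]),
                make_junctions(1400, 2390, support = sup[2]))
    rr <- compute_aeb_ratios(ev, jj)
    if (max(sup) == 0) {
      expect_true(is.na(rr$splicing_ratio))
    } else {
      expect_equal(rr$splicing_ratio, min(sup) / max(sup))
      expect_equal(rr$inclusion_ratio, sup[2] / sum(sup))
    }
  }
})

test_that("alternative terminal exons require a shared constitutive site", {
  m <- toy_model()
  # second transcript with a different first exon splicing to exon2 start
  m$transcripts <- rbind(m$transcripts, data.frame(
    transcript_id = "gA.t2", gene_id = "gA", provenance = "annotated"))
  m$exons <- rbind(m$exons, data.frame(
    transcript_id = "gA.t2", gene_id = "gA", chrom = "chr1",
    start = c(500L, 1200L, 2400L), end = c(640L, 1400L, 2600L),
    strand = "+", provenance = "annotated"))
  m <- beesplice:::validate_gene_model(m)
  j <- rbind(make_junctions(200, 1200, support = 20),
             make_junctions(640, 1200, support = 5))
  ate <- detect_ate(m, j)
  afe <- ate[ate$kind == "AFE", ]
  expect_equal(nrow(afe), 1L)
  expect_equal(afe$c, 1200L)
  expect_equal(compute_aeb_ratios(afe, j)$splicing_ratio, 0.25)

  # first exons splicing to different acceptors: no AFE
  m2 <- toy_model()
  m2$transcripts <- rbind(m2$transcripts, data.frame(
    transcript_id = "gA.t2", gene_id = "gA", provenance = "annotated"))
  m2$exons <- rbind(m2$exons, data.frame(
    transcript_id = "gA.t2", gene_id = "gA", chrom = "chr1",
    start = c(500L, 1250L, 2400L), end = c(640L, 1400L, 2600L),
    strand = "+", provenance = "annotated"))
  m2 <- beesplice:::validate_gene_model(m2)
  ate2 <- detect_ate(m2, j)
  expect_equal(nrow(ate2[ate2$kind == "AFE", ]), 0L)

  # single-exon transcripts are skipped outright
  m3 <- gene_model(
    genes = data.frame(gene_id = "g", chrom = "chr1", start = 0L, end = 100L,
                       strand = "+", provenance = "annotated"),
    transcripts = data.frame(transcript_id = "t", gene_id = "g",
                             provenance = "annotated"),
    exons = data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
                       start = 0L, end = 100L, strand = "+",
                       provenance = "annotated"))
  expect_equal(nrow(detect_ate(m3, j)), 0L)
})

test_that("displacement spectrum reports mod-3 fractions", {
  ev3 <- do.call(rbind, lapply(c(3L, 3L, 6L), function(d)
    beesplice:::event_row("ALT_DONOR", "g", "chr1", "+", p = 0, q = 10,
                          q2 = 10 - d, c = 50, d = 60,
                          displacement = d)))
  sp <- displacement_spectrum(ev3)
  expect_equal(sp$aeb_mod3_fraction, 1)

  ev_mix <- do.call(rbind, lapply(c(3L, 4L), function(d)
    beesplice:::event_row("ALT_ACCEPTOR", "g", "chr1", "+", p = 0, q = 10,
                          p2 = d, c = 50, d = 60, displacement = d)))
  sp2 <- displacement_spectrum(ev_mix)
  expect_equal(sp2$aeb_mod3_fraction, 0.5)
  expect_equal(sp2$histogram$count, c(1L, 1L))

  empty <- displacement_spectrum(beesplice:::empty_events())
  expect_equal(nrow(empty$histogram), 0L)
  expect_true(is.na(empty$aeb_mod3_fraction))

  # CE length mod-3 fraction
  ce <- rbind(beesplice:::event_row("CE", "g", "chr1", "+", a = 0, b = 10,
                                    p = 20, q = 119, c = 150, d = 160),
              beesplice:::event_row("CE", "g", "chr1", "+", a = 0, b = 10,
                                    p = 20, q = 120, c = 150, d = 160))
  expect_equal(displacement_spectrum(ce)$ce_mod3_fraction, 0.5)
})

test_that("planted events are recovered with correct kind and coordinates", {
  sim <- small_sim(seed = 7)
  ev <- detect_as(sim$model, sim$junctions, sim$coverage)
  tr <- sim$truth
  expect_equal(as.vector(table(ev$kind)[sort(unique(tr$kind))]),
               as.vector(table(tr$kind)[sort(unique(tr$kind))]))
  m <- merge(tr, ev, by = c("gene_id", "kind"))
  expect_equal(nrow(m), nrow(tr))
  # event region coordinates match the truth (terminal-exon pairs may have
  # major/minor swapped, so compare as unordered pairs)
  pq_truth <- pmin(m$p.x, m$p2.x, na.rm = TRUE)
  pq_det <- pmin(m$p.y, m$p2.y, na.rm = TRUE)
  expect_equal(pq_det, pq_truth)
})

test_that("detection is strand-reversal invariant", {
  sim <- small_sim(seed = 23, n_novel_exon = 0, n_novel_transcript = 0)
  ev <- detect_as(sim$model, sim$junctions, sim$coverage)
  fl <- flip_dataset(sim)
  ev_f <- detect_as(fl$model, fl$junctions, fl$coverage)
  back <- unflip_events(ev_f, fl$L)
  expect_setequal(event_key(back), event_key(ev))
  # metrics carried across the flip
  key_o <- event_key(ev); key_b <- event_key(back)
  ord_o <- order(key_o); ord_b <- order(key_b)
  expect_equal(back$inclusion_ratio[ord_b], ev$inclusion_ratio[ord_o])
  expect_equal(back$splicing_ratio[ord_b], ev$splicing_ratio[ord_o])
})
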