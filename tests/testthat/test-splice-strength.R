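bases <- c("A", "C", "G", "T")

rand_motifs <- function(n, L, prob = rep(0.25, 4)) {
  vapply(seq_len(n), function(i)
    paste(sample(bases, L, TRUE, prob = prob), collapse = ""), character(1))
}

test_that("first-order fit equals the closed-form independence model", {
  set.seed(3)
  pwm <- matrix(runif(36, 0.05, 1), 9, 4)
  pwm <- pwm / rowSums(pwm)
  seqs <- vapply(1:400, function(i) paste(vapply(1:9, function(j)
    sample(bases, 1, prob = pwm[j, ]), character(1)), collapse = ""),
    character(1))
  m <- train_splice_model(seqs, "donor", constraint_order = 1)
  expect_true(m$converged)
  # fitted marginals equal empirical marginals
  mm <- beesplice:::chain_marginals(m$W1, m$W2)
  expect_lt(max(abs(mm$m1 - m$emp1)), 1e-4)
  # per-motif probability equals the product of empirical marginals
  for (i in 1:50) {
    mot <- rand_motifs(1, 9)
    x <- match(strsplit(mot, "")[[1]], bases)
    expect_equal(beesplice:::motif_prob(m, mot),
                 prod(m$emp1[cbind(1:9, x)]), tolerance = 1e-6)
  }
})

test_that("uniform training data gives near-zero log-odds everywhere", {
  set.seed(4)
  seqs <- rand_motifs(4000, 9)
  m <- train_splice_model(seqs, "donor", constraint_order = 1)
  sc <- vapply(rand_motifs(30, 9), function(x)
    beesplice:::score_motif(m, x), numeric(1))
  expect_lt(max(abs(sc)), 0.6)  # sampling noise only
})

test_that("a single repeated motif receives the maximal score", {
  mot <- "CAGGTAAGT"
  m <- train_splice_model(rep(mot, 120), "donor", constraint_order = 1)
  s_ref <- beesplice:::score_motif(m, mot)
  others <- rand_motifs(50, 9)
  for (o in others) {
    expect_gte(s_ref, beesplice:::score_motif(m, o))
  }
})

test_that("consensus of a strongly biased set outscores every single mismatch", {
  set.seed(6)
  seqs <- replicate(500, sample_splice_motif("donor", "strong"))
  m <- train_splice_model(seqs, "donor", constraint_order = 1)
  cons <- "CAGGTAAGT"
  s_cons <- beesplice:::score_motif(m, cons)
  for (i in 1:9) for (b in bases) {
    if (substr(cons, i, i) == b) next
    mut <- cons
    substr(mut, i, i) <- b
    expect_gt(s_cons, beesplice:::score_motif(m, mut))
  }
})

test_that("pairwise constraints match and likelihood is non-decreasing in order", {
  set.seed(7)
  # Markov-generated motifs so adjacent pairs carry signal
  trans <- matrix(c(.6, .2, .1, .1,
                    .1, .6, .2, .1,
                    .1, .1, .6, .2,
                    .2, .1, .1, .6), 4, 4, byrow = TRUE)
  gen <- function() {
    x <- integer(9); x[1] <- sample(1:4, 1)
    for (i in 2:9) x[i] <- sample(1:4, 1, prob = trans[x[i - 1], ])
    paste(bases[x], collapse = "")
  }
  seqs <- replicate(400, gen())
  m1 <- train_splice_model(seqs, "donor", constraint_order = 1)
  m2 <- train_splice_model(seqs, "donor", constraint_order = 2)
  expect_true(m2$converged)
  mm <- beesplice:::chain_marginals(m2$W1, m2$W2)
  expect_lt(max(abs(mm$m1 - m2$emp1)), 1e-4)
  pair_dev <- max(vapply(1:8, function(i)
    max(abs(mm$m2[[i]] - m2$emp2[[i]])), numeric(1)))
  expect_lt(pair_dev, 1e-4)
  expect_gte(model_loglik(m2, seqs), model_loglik(m1, seqs) - 1e-9)
  # the fitted distribution is normalized: marginals each sum to one
  expect_equal(rowSums(mm$m1), rep(1, 9), tolerance = 1e-9)
})

test_that("acceptor windows (23-mer) train by dynamic programming, not enumeration", {
  set.seed(8)
  seqs <- replicate(200, sample_splice_motif("acceptor", "strong"))
  t0 <- Sys.time()
  m <- train_splice_model(seqs, "acceptor", constraint_order = 2)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 30)
  expect_true(m$converged)
  expect_equal(m$length, 23L)
})

test_that("training rejects malformed input", {
  expect_error(train_splice_model(c("ACGT"), "donor"), "length")
  expect_error(train_splice_model(rep("CAGGTANGT", 10), "donor"), "non-ACGT")
})

test_that("genome scoring is deterministic, strand-correct, and NA off the end", {
  set.seed(9)
  seqs <- replicate(200, sample_splice_motif("donor", "strong"))
  m <- train_splice_model(seqs, "donor")
  g <- toy_genome(500)
  s1 <- score_splice_site(m, g, "chr1", 100L, "+")
  expect_identical(s1, score_splice_site(m, g, "chr1", 100L, "+"))
  # minus-strand score equals plus-strand score of the revcomp window
  rc <- Biostrings::DNAStringSet(Biostrings::reverseComplement(g[[1]]))
  names(rc) <- "chr1"
  s_minus <- score_splice_site(m, g, "chr1", 100L, "-")
  s_mirror <- score_splice_site(m, rc, "chr1", 500L - 100L, "+")
  expect_equal(s_minus, s_mirror)
  expect_true(is.na(score_splice_site(m, g, "chr1", 1L, "+")))
  expect_true(is.na(score_splice_site(m, g, "chr1", 499L, "+")))
})

test_that("a motif at background frequency scores zero log-odds", {
  # model whose fitted distribution IS the background
  seqs <- apply(expand.grid(rep(list(bases), 2))[rep(1:16, 10), ], 1,
                paste, collapse = "")
  # use donor geometry via a uniform set instead: every base equally likely
  set.seed(10)
  m <- train_splice_model(rand_motifs(8000, 9), "donor",
                          constraint_order = 1)
  sc <- beesplice:::score_motif(m, "ACGTACGTA")
  expect_lt(abs(sc), 0.5)
})

test_that("strength-vs-inclusion handles a single occupied bin without error", {
  ev <- beesplice:::event_row("CE", "g", "chr1", "+", a = 50, b = 100,
                              p = 200, q = 260, c = 380, d = 420)
  ev$inclusion_ratio <- 0.9
  set.seed(11)
  md <- train_splice_model(replicate(120, sample_splice_motif("donor",
                                                              "strong")),
                           "donor")
  ma <- train_splice_model(replicate(120, sample_splice_motif("acceptor",
                                                              "strong")),
                           "acceptor")
  g <- toy_genome(1000)
  out <- strength_vs_inclusion(ev, md, ma, g)
  expect_true(all(is.na(out$tests$p_value)))
  expect_gte(nrow(out$table), 1L)
})
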