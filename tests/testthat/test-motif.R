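test_that("pwm construction yields coherent probabilities and score bounds", {
  counts <- matrix(c(97, 1, 1, 1,
                     1, 97, 1, 1,
                     1, 1, 97, 1,
                     1, 1, 1, 97), 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm(counts, id = "acgt")
  expect_equal(colSums(p$prob), rep(1, 4), tolerance = 1e-12)
  expect_identical(pwm_consensus(p), "ACGT")
  # the consensus scores the maximum achievable score exactly
  hit <- scan_sequence("ACGT", p, threshold_fraction = 1)
  expect_equal(hit$score, p$max_score, tolerance = 1e-12)
  expect_equal(hit$score_fraction, 1, tolerance = 1e-12)
  # reverse complement round-trips
  expect_equal(pwm_revcomp(pwm_revcomp(p))$prob, p$prob, tolerance = 1e-15)
  expect_error(pwm(counts[1:3, ]), "4 rows")
})

test_that("palindromic matches merge across strands without double counting", {
  counts <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(1:4, 1:4)] <- 97  # consensus ACGT; revcomp is also ACGT
  p <- pwm(counts, id = "acgt")
  m <- scan_sequence("ACGTACGT", p, threshold_fraction = 0.80)
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(0L, 4L))
  expect_equal(m$end, c(4L, 8L))
  raw <- scan_sequence("ACGTACGT", p, threshold_fraction = 0.80, merge = FALSE)
  expect_equal(nrow(raw), 4)  # both strands at both offsets before merging
  expect_true(all(raw$end - raw$start == 4L))
})

test_that("masked and invalid sequence content is handled", {
  p <- random_pwm(5, seed = 28)
  expect_equal(nrow(scan_sequence("", p)), 0)
  expect_equal(nrow(scan_sequence("NNNNNNNNNN", p)), 0)
  cons <- pwm_consensus(p)
  # a soft-masked (lower-case) planted site is skipped
  expect_equal(nrow(scan_sequence(tolower(cons), p)), 0)
  expect_gte(nrow(scan_sequence(cons, p)), 1)
  expect_error(scan_sequence("ACGU", p), "invalid sequence character")
})

test_that("scanning agrees exactly with a naive every-offset oracle", {
  set.seed(29)
  for (i in 1:15) {
    p <- random_pwm(sample(5:10, 1), id = paste0("m", i))
    seq <- random_dna(300)
    # plant one consensus to guarantee hits
    pos <- sample(200, 1)
    substr(seq, pos, pos + p$length - 1) <- pwm_consensus(p)
    got <- scan_sequence(seq, p, threshold_fraction = 0.80, merge = FALSE)
    oracle <- naive_scan(seq, p, threshold_fraction = 0.80)
    expect_identical(nrow(got), nrow(oracle))
    got <- dplyr::arrange(got, start, strand)
    expect_equal(got$start, oracle$start)
    expect_identical(got$strand, oracle$strand)
    expect_equal(got$score, oracle$score, tolerance = 1e-9)
  }
})

test_that("reverse-complementing the sequence mirrors coordinates", {
  set.seed(30)
  p <- random_pwm(7, seed = 31)
  seq <- random_dna(400)
  pos <- sample(300, 1)
  substr(seq, pos, pos + 6) <- pwm_consensus(p)
  n <- nchar(seq)
  rc <- paste0(rev(chartr("ACGT", "TGCA", strsplit(seq, "")[[1]])),
               collapse = "")
  fwd <- scan_sequence(seq, p, merge = FALSE)
  rev_ <- scan_sequence(rc, p, merge = FALSE)
  expect_equal(nrow(fwd), nrow(rev_))
  mirrored <- sort(n - fwd$end)
  expect_equal(sort(rev_$start), mirrored)
  expect_equal(sum(fwd$strand == "+"), sum(rev_$strand == "-"))
})

test_that("merging is idempotent and counts are additive over N-spacers", {
  set.seed(32)
  p <- random_pwm(6, seed = 33)
  seq1 <- paste0(random_dna(50), pwm_consensus(p), random_dna(50))
  seq2 <- paste0(random_dna(40), pwm_consensus(p), random_dna(40))
  m <- scan_sequence(seq1, p)
  expect_identical(merge_matches(m), m)

  c1 <- count_matches(c(a = seq1), p)$count
  c2 <- count_matches(c(b = seq2), p)$count
  spacer <- strrep("N", p$length)
  cc <- count_matches(c(ab = paste0(seq1, spacer, seq2)), p)$count
  expect_equal(cc, c1 + c2)
})

test_that("count_matches equals the merged interval count from scan_sequence", {
  set.seed(34)
  p <- random_pwm(6, seed = 35)
  seqs <- setNames(replicate(10, {
    s <- random_dna(200)
    if (runif(1) < 0.7) {
      pos <- sample(150, 1)
      substr(s, pos, pos + p$length - 1) <- pwm_consensus(p)
    }
    s
  }), sprintf("s%02d", 1:10))
  counts <- count_matches(seqs, p)
  direct <- vapply(names(seqs), function(id) {
    nrow(scan_sequence(seqs[[id]], p, seq_id = id))
  }, 1L)
  expect_equal(counts$count, unname(direct))
})

test_that("window scores agree with an external PWM scorer", {
  skip_if_not_installed("Biostrings")
  set.seed(36)
  p <- random_pwm(8, seed = 37)
  seq <- random_dna(200)
  got <- scan_sequence(seq, p, threshold_fraction = 0.01, merge = FALSE)
  fwd <- got[got$strand == "+", ]
  ext <- Biostrings::PWMscoreStartingAt(p$logodds, Biostrings::DNAString(seq),
                                        starting.at = fwd$start + 1L)
  expect_equal(fwd$score, unname(ext), tolerance = 1e-9)
})

test_that("motif enrichment detects a planted foreground excess", {
  set.seed(38)
  n_fg <- 100; n_bg <- 500
  lens <- round(runif(n_fg + n_bg, 250, 750))
  ids <- sprintf("s%03d", seq_along(lens))
  counts <- tibble::tibble(
    seq_id = ids, motif_id = "m1",
    count = rpois(n_fg + n_bg, lambda = c(rep(3, n_fg), rep(1, n_bg))))
  res <- motif_enrichment(counts, foreground = ids[1:n_fg],
                          lengths = setNames(lens, ids))
  expect_gt(res$z, 0)
  expect_lt(res$p, 0.05)
  expect_identical(res$model, "gam_logistic")
})

test_that("motif enrichment falls back to plain logistic for equal lengths", {
  set.seed(39)
  ids <- sprintf("s%03d", 1:300)
  counts <- tibble::tibble(
    seq_id = ids, motif_id = "m1",
    count = rpois(300, lambda = c(rep(3, 50), rep(1, 250))))
  res <- motif_enrichment(counts, foreground = ids[1:50],
                          lengths = setNames(rep(500, 300), ids))
  expect_identical(res$model, "glm_logistic")
  expect_gt(res$z, 0)
  # sign agrees with a direct logistic fit without any smooth
  fit <- glm(y ~ count, family = binomial(),
             data = data.frame(y = c(rep(1, 50), rep(0, 250)),
                               count = counts$count))
  expect_equal(sign(res$z), sign(coef(summary(fit))["count", "z value"]))
})

test_that("a motif absent everywhere is degenerate, and nulls are calibrated", {
  ids <- sprintf("s%03d", 1:100)
  counts <- tibble::tibble(seq_id = ids, motif_id = "dead", count = 0L)
  res <- motif_enrichment(counts, foreground = ids[1:20],
                          lengths = setNames(rep(500, 100), ids))
  expect_true(res$degenerate)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)

  set.seed(40)
  rejections <- vapply(1:100, function(i) {
    lens <- round(runif(240, 250, 750))
    ids <- sprintf("q%03d", 1:240)
    counts <- tibble::tibble(seq_id = ids, motif_id = "m",
                             count = rpois(240, lens / 500))
    r <- motif_enrichment(counts, foreground = ids[1:40],
                          lengths = setNames(lens, ids))
    r$p < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.11)
})
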