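test_that("detection call behaves at its boundaries", {
  expect_identical(as.numeric(detect_above_background(1:5, 1:5)), 1)
  expect_true(attr(detect_above_background(1:5, 1:5), "degenerate"))

  # 11 probe pairs, every PM > MM: most extreme exact signed-rank outcome
  pm <- 10 + (1:11) / 100
  mm <- rep(10, 11)
  expect_equal(as.numeric(detect_above_background(pm, mm)), 1 / 2^11,
               tolerance = 1e-12)

  expect_error(detect_above_background(1:3, 1:4), "equal length")
})

test_that("detection call ignores a common additive shift", {
  set.seed(11)
  pm <- rnorm(11, 8)
  mm <- rnorm(11, 7.5)
  expect_equal(as.numeric(detect_above_background(pm, mm)),
               as.numeric(detect_above_background(pm + 3.7, mm + 3.7)))
})

test_that("null PM/MM intensities reject near the nominal level", {
  probes <- simulate_probe_pairs(800, n_pairs = 11, signal = 0, seed = 21)
  p <- vapply(seq_len(800), function(i) {
    as.numeric(detect_above_background(probes$pm[i, ], probes$mm[i, ]))
  }, 1.0)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.07)
})

test_that("detection frequency counts group samples correctly", {
  vals <- matrix(rnorm(20), 2, 10,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:10)))
  det <- matrix(FALSE, 2, 10, dimnames = dimnames(vals))
  det["g1", ] <- TRUE
  det["g2", 1] <- TRUE
  b <- make_bundle(vals, groups = rep(c("PP", "PN"), each = 5),
                   detected = det)
  freq <- detection_frequency(b, c("PP", "PN"))
  expect_equal(freq$frequency[freq$gene_id == "g1"], 1.0)
  expect_equal(freq$frequency[freq$gene_id == "g2"], 0.1)
  # monotone: adding a detected sample cannot lower the frequency
  det2 <- det
  det2["g2", 2] <- TRUE
  b2 <- make_bundle(vals, groups = rep(c("PP", "PN"), each = 5),
                    detected = det2)
  freq2 <- detection_frequency(b2, c("PP", "PN"))
  expect_gte(freq2$frequency[freq2$gene_id == "g2"],
             freq$frequency[freq$gene_id == "g2"])
  expect_error(detection_frequency(b, "nope"), "no samples")
})

test_that("skin-expressed filter includes the 10% boundary", {
  vals <- matrix(0, 3, 10,
                 dimnames = list(c("ga", "gb", "gc"), paste0("s", 1:10)))
  det <- matrix(FALSE, 3, 10, dimnames = dimnames(vals))
  det["ga", 1] <- TRUE      # exactly 10%
  det["gb", 1:5] <- TRUE
  b <- make_bundle(vals, groups = rep(c("PP", "PN"), each = 5),
                   detected = det)
  kept <- skin_expressed_filter(b, min_fraction = 0.10)
  expect_true("ga" %in% kept)     # boundary inclusive
  expect_true("gb" %in% kept)
  expect_false("gc" %in% kept)    # never detected
  expect_setequal(skin_expressed_filter(b, min_fraction = 0),
                  c("ga", "gb", "gc"))
})

test_that("qc_trim trims floor(fraction*n) per tail with set semantics", {
  set.seed(2)
  metrics <- tibble::tibble(sample_id = sprintf("s%02d", 1:40),
                            bg = rnorm(40), scale = rnorm(40))
  spec1 <- tibble::tibble(metric = "bg", tail = "both", fraction = 0.025)
  kept <- qc_trim(metrics, spec1)
  expect_length(kept, 38)
  expect_false(metrics$sample_id[which.min(metrics$bg)] %in% kept)
  expect_false(metrics$sample_id[which.max(metrics$bg)] %in% kept)

  expect_length(qc_trim(metrics, tibble::tibble(metric = "bg", tail = "both",
                                                fraction = 0)), 40)

  # a sample flagged by two metrics is removed once (union semantics)
  m2 <- metrics
  m2$scale[which.min(m2$bg)] <- min(m2$scale) - 10
  spec2 <- tibble::tibble(metric = c("bg", "scale"),
                          tail = c("low", "low"), fraction = c(0.025, 0.025))
  expect_length(qc_trim(m2, spec2), 39)

  # retained set independent of row order
  shuffled <- m2[sample(nrow(m2)), ]
  expect_setequal(qc_trim(m2, spec2), qc_trim(shuffled, spec2))

  expect_error(qc_trim(metrics, tibble::tibble(metric = "bg", tail = "both",
                                               fraction = 0.6)), "0.5")
  expect_error(qc_trim(metrics, tibble::tibble(metric = "nope", tail = "low",
                                               fraction = 0.1)), "unknown")
})

test_that("representative selection matches a brute-force distance sort", {
  set.seed(3)
  vals <- matrix(rnorm(100 * 10), 100, 10,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 sprintf("s%02d", 1:10)))
  b <- make_bundle(vals, groups = rep("kc", 10))
  got <- select_representatives(b, "kc", k = 5)
  centroid <- rowMeans(vals)
  d <- apply(vals, 2, function(x) sqrt(sum((x - centroid)^2)))
  expect_identical(got, names(sort(d))[1:5])
  # group smaller than k comes back whole
  expect_length(select_representatives(b, "kc", k = 50), 10)
  expect_error(select_representatives(b, "kc", k = 0), "positive")
})

test_that("a sample sitting on the centroid ranks first", {
  vals <- cbind(a = c(1, 2), b = c(3, 4), c = c(2, 3))  # c is the centroid
  rownames(vals) <- c("g1", "g2")
  b <- make_bundle(vals, groups = rep("kc", 3))
  expect_identical(select_representatives(b, "kc", k = 3)[1], "c")
})

test_that("representative probe set preference follows suffix then level", {
  cands <- tibble::tibble(
    probe_set_id = c("200001_x_at", "200002_at"),
    suffix_class = c("_x", "none"),
    median_pp = c(12, 5), median_pn = c(12, 5))
  expect_identical(choose_representative_probeset(cands), "200002_at")

  tie <- tibble::tibble(
    probe_set_id = c("b_at", "a_at"),
    suffix_class = "none",
    median_pp = c(5.0, 6.0), median_pn = c(5.0, 4.0))
  expect_identical(choose_representative_probeset(tie), "a_at")

  single <- tibble::tibble(probe_set_id = "x_s_at", suffix_class = "_s",
                           median_pp = 1, median_pn = 1)
  expect_identical(choose_representative_probeset(single), "x_s_at")
})

test_that("reference normalization maps the reference median to 1 and inverts", {
  set.seed(4)
  vals <- matrix(rnorm(50, 8), 5, 10,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:10)))
  b <- make_bundle(vals, groups = rep(c("kc", "normal_skin"), each = 5))
  rel <- normalize_to_reference(b)
  ref_med <- attr(rel, "reference_median")
  skin_cols <- b$samples$sample_id[b$samples$group == "normal_skin"]
  expect_equal(apply(rel[, skin_cols], 1, median), rep(1, 5),
               ignore_attr = TRUE)
  # one log2 unit above the reference median doubles relative expression
  expect_equal(unname(2^(ref_med["g1"] + 1 - ref_med["g1"])), 2.0)
  # round trip: log2(rel) + reference median recovers the input
  expect_equal(log2(rel) + ref_med, vals, tolerance = 1e-12,
               ignore_attr = TRUE)
})
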