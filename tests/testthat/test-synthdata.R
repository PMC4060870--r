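test_that("cohort generation is deterministic and plants the configured DEGs", {
  cfg <- synth_config(seed = 1, n_genes = 1000, frac_deg_up = 0.05)
  a <- generate_patient_cohort(cfg)
  b <- generate_patient_cohort(cfg)
  expect_identical(a$bundle$values, b$bundle$values)
  expect_identical(a$truth, b$truth)
  expect_length(a$truth$deg_up, 50)

  c2 <- generate_patient_cohort(synth_config(seed = 2, n_genes = 1000))
  expect_false(identical(a$bundle$values, c2$bundle$values))
  expect_identical(dim(a$bundle$values), dim(c2$bundle$values))
})

test_that("planted genes carry the planted paired log2 shift, null genes none", {
  cfg <- synth_config(seed = 5, planted_log2fc = 1, noise_sd = 0.3,
                      n_patients = 60)
  co <- generate_patient_cohort(cfg)
  b <- co$bundle
  pp <- b$values[, b$samples$group == "PP"]
  pn <- b$values[, b$samples$group == "PN"]
  d <- pp - pn  # columns pair by construction order
  up_d <- d[co$truth$deg_up, ]
  se <- sd(up_d) / sqrt(length(up_d))
  expect_lt(abs(mean(up_d) - 1), 3 * se)

  null_genes <- setdiff(rownames(d), c(co$truth$deg_up, co$truth$deg_down))
  null_d <- d[null_genes, ]
  expect_lt(abs(mean(null_d)), 3 * sd(null_d) / sqrt(length(null_d)))
})

test_that("null paired differences pass a location test in almost all seeds", {
  pass <- vapply(1:20, function(s) {
    co <- generate_patient_cohort(small_config(seed = s))
    b <- co$bundle
    d <- b$values[, b$samples$group == "PP"] -
      b$values[, b$samples$group == "PN"]
    nulls <- setdiff(rownames(d), c(co$truth$deg_up, co$truth$deg_down))
    x <- as.vector(d[sample(nulls, 50), ])
    wilcox.test(x, mu = 0)$p.value > 0.01
  }, TRUE)
  expect_gte(mean(pass), 0.95)
})

test_that("detection flags follow the logistic link on expression", {
  cfg <- small_config(seed = 3)
  co <- generate_patient_cohort(cfg)
  b <- co$bundle
  expected <- mean(plogis(cfg$detection_slope *
                            (b$values - cfg$detection_midpoint)))
  observed <- mean(b$detected)
  se <- sqrt(expected * (1 - expected) / length(b$detected))
  expect_lt(abs(observed - expected), 4 * se)
  # detection p-values are consistent with the flags
  expect_identical(unname(b$detected), unname(b$detection_p < 0.05))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_patients = 0), "positive count")
  expect_error(synth_config(frac_deg_up = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(pwm_length = 300, seq_length = 300), "smaller")
})

test_that("compendium markers clear the planted margin and map back", {
  cfg <- synth_config(seed = 4, marker_log2_margin = 2, noise_sd = 0.2)
  cmp <- generate_celltype_compendium(cfg)
  b <- cmp$bundle
  mm <- cmp$truth$marker_map
  types <- setdiff(unique(b$samples$group), "normal_skin")
  med <- vapply(types, function(t) {
    cols <- b$samples$sample_id[b$samples$group == t]
    apply(b$values[names(mm), cols, drop = FALSE], 1, median)
  }, numeric(length(mm)))
  own <- med[cbind(seq_along(mm), match(mm, types))]
  other_max <- vapply(seq_along(mm), function(i) {
    max(med[i, -match(mm[i], types)])
  }, 1.0)
  expect_gte(mean(own - other_max >= 2), 0.99)
})

test_that("compendium respects degenerate marker settings and seed changes", {
  cfg0 <- small_config(frac_marker_genes = 0)
  cmp0 <- generate_celltype_compendium(cfg0)
  expect_length(cmp0$truth$marker_map, 0)

  a <- generate_celltype_compendium(small_config(seed = 1))
  b <- generate_celltype_compendium(small_config(seed = 9))
  expect_false(identical(a$bundle$values, b$bundle$values))
  expect_identical(dim(a$bundle$values), dim(b$bundle$values))

  expect_error(
    generate_celltype_compendium(small_config(samples_per_celltype = 1)),
    ">= 2")
})

test_that("genome fixture draws the stated background base composition", {
  cfg <- synth_config(seed = 6, n_sequences = 100, seq_length = 10000,
                      planted_motif_rate = 0)
  g <- generate_genome_fixture(cfg)
  expect_equal(nrow(g$truth$planted_matches), 0)
  chars <- strsplit(paste0(toupper(g$sequences), collapse = ""), "")[[1]]
  chars <- chars[chars != "N"]
  n <- length(chars)
  freqs <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  for (base in names(freqs)) {
    p <- freqs[[base]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(chars == base) - p), 4 * se)
  }
})

test_that("planted motif occurrences are recovered by the scanner", {
  cfg <- small_config(seed = 7, planted_motif_rate = 1)
  g <- generate_genome_fixture(cfg)
  pm <- g$truth$planted_matches
  expect_gt(nrow(pm), 10)
  hits <- vapply(sample(seq_len(nrow(pm)), 20), function(i) {
    row <- pm[i, ]
    m <- scan_sequence(g$sequences[[row$seq_id]], g$pwms[[row$motif_id]],
                       threshold_fraction = 0.80, seq_id = row$seq_id)
    any(m$start < row$end & m$end > row$start)  # interval overlap
  }, TRUE)
  expect_true(all(hits))
})

test_that("variant panel has block LD structure and verified causal alleles", {
  cfg <- small_config(seed = 8, planted_motif_rate = 1)
  g <- generate_genome_fixture(cfg, foreground_genes = sprintf("g%04d", 1:10))
  v <- generate_variants(cfg, g)
  expect_gt(nrow(v$variants), 10)

  # within-block r^2 high, between-block near zero
  blocks <- split(v$variants$variant_id, v$variants$block)
  blocks <- blocks[lengths(blocks) >= 2]
  within <- unlist(lapply(blocks, function(ids) {
    cor(t(v$genotypes[ids, , drop = FALSE]))[lower.tri(diag(length(ids)))]^2
  }))
  expect_gt(median(within), 0.95)
  b1 <- blocks[[1]][1]
  b2 <- blocks[[2]][1]
  expect_lt(cor(v$genotypes[b1, ], v$genotypes[b2, ])^2, 0.3)

  # causal SNPs flip the planted match across the 0.80 threshold
  for (i in seq_len(nrow(v$truth$causal_snps))) {
    cs <- v$truth$causal_snps[i, ]
    var <- v$variants[v$variants$variant_id == cs$variant_id, ]
    p <- g$pwms[[cs$motif_id]]
    seq <- g$sequences[[var$seq_id]]
    w <- celldissect:::extract_window(seq, var$pos, p$length)
    rf <- celldissect:::best_fraction(
      celldissect:::window_with_base(w, var$ref), p)
    af <- celldissect:::best_fraction(
      celldissect:::window_with_base(w, var$alt), p)
    if (cs$effect_class == "abrogate") {
      expect_gte(rf, 0.80)
      expect_lt(af, 0.80)
    } else {
      expect_lt(rf, 0.80)
      expect_gte(af, 0.80)
    }
  }
})

test_that("an empty variant panel writes a valid header-only VCF", {
  cfg <- small_config(seed = 9, n_snps = 0)
  g <- generate_genome_fixture(cfg)
  v <- generate_variants(cfg, g)
  expect_equal(nrow(v$variants), 0)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v$variants, path)
  lines <- readLines(path)
  expect_true(all(grepl("^#", lines)))
  expect_equal(nrow(read_vcf(path)), 0)
})
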