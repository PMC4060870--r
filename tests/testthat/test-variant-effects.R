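test_that("ld_partners handles identities, independence and monomorphism", {
  g <- rbind(
    lead = c(0, 0, 1, 1, 2, 2),
    twin = c(0, 0, 1, 1, 2, 2),
    indep = c(0, 1, 0, 1, 0, 1),
    mono = rep(1, 6))
  colnames(g) <- sprintf("i%d", 1:6)
  expect_warning(ld <- ld_partners(g, "lead"), "monomorphic")
  expect_equal(ld$r2[ld$variant_id == "lead"], 1)
  expect_true("twin" %in% ld$variant_id)
  expect_equal(ld$r2[ld$variant_id == "twin"], 1)
  expect_false("indep" %in% ld$variant_id)
  expect_false("mono" %in% ld$variant_id)
  expect_identical(ld$variant_id[1], "lead")

  # the printed hand case: dosages (0,0,1,1) vs (0,1,0,1) have r^2 = 0
  g2 <- rbind(lead = c(0, 0, 1, 1), other = c(0, 1, 0, 1))
  colnames(g2) <- sprintf("i%d", 1:4)
  expect_equal(unname(cor(g2["lead", ], g2["other", ])^2), 0)
  expect_false("other" %in% ld_partners(g2, "lead")$variant_id)

  expect_error(ld_partners(g, "absent"), "not in")
})

test_that("ld_partners matches a brute-force correlation oracle", {
  set.seed(41)
  for (i in 1:50) {
    nv <- sample(5:15, 1)
    ni <- sample(10:40, 1)
    g <- matrix(rbinom(nv * ni, 2, runif(1, 0.2, 0.8)), nv, ni,
                dimnames = list(sprintf("v%02d", 1:nv),
                                sprintf("i%02d", 1:ni)))
    sds <- apply(g, 1, sd)
    if (sds[1] == 0) next
    keep <- sds > 0
    lead <- rownames(g)[1]
    oracle <- vapply(rownames(g)[keep], function(v) {
      cor(g[lead, ], g[v, ])^2
    }, 1.0)
    got <- suppressWarnings(ld_partners(g, lead, r2_threshold = 0))
    expect_equal(sort(got$variant_id),
                 sort(names(oracle)[oracle > 0 | names(oracle) == lead]))
    common <- intersect(got$variant_id, names(oracle))
    expect_equal(got$r2[match(common, got$variant_id)],
                 unname(oracle[common]), tolerance = 1e-12)
  }
})

test_that("candidate genes cover overlap plus immediate neighbours", {
  ann <- tibble::tibble(
    seq_id = "chr1",
    start = c(100, 500, 900),
    end = c(200, 800, 1000),
    gene_id = c("A", "C", "B"))
  # position between A and C (1-based 301 -> 0-based 300)
  expect_setequal(candidate_genes_for_locus(301, ann, "chr1"), c("A", "C"))
  # position inside C: C plus flanking A and B
  expect_setequal(candidate_genes_for_locus(601, ann, "chr1"),
                  c("A", "B", "C"))
  # upstream of every gene: only the first gene
  expect_setequal(candidate_genes_for_locus(50, ann, "chr1"), "A")
  expect_error(candidate_genes_for_locus(50, ann, "chrX"), "no annotation")
})

test_that("allele effects classify planted causal SNPs from the fixture", {
  cfg <- small_config(seed = 42, planted_motif_rate = 1)
  g <- generate_genome_fixture(cfg, foreground_genes = sprintf("g%04d", 1:10))
  v <- generate_variants(cfg, g)
  expect_gte(nrow(v$truth$causal_snps), 1)
  for (i in seq_len(nrow(v$truth$causal_snps))) {
    cs <- v$truth$causal_snps[i, ]
    var <- v$variants[v$variants$variant_id == cs$variant_id, ]
    eff <- allele_specific_matches(g$sequences, var,
                                   g$pwms[cs$motif_id])
    expected <- if (cs$effect_class == "abrogate") "abrogates" else "engenders"
    expect_identical(eff$effect, expected)
    if (cs$effect_class == "abrogate") {
      # the affected window overlaps the planted occurrence
      pm <- g$truth$planted_matches
      pm <- pm[pm$seq_id == var$seq_id & pm$motif_id == cs$motif_id, ]
      expect_true(any(eff$offset < pm$end & eff$offset + 100 > pm$start))
    }
  }
})

test_that("a degenerate ref == alt variant is never an effect", {
  set.seed(43)
  p <- random_pwm(6, seed = 44, id = "m1")
  seq <- paste0(random_dna(30), pwm_consensus(p), random_dna(30))
  var <- tibble::tibble(variant_id = "rsX", seq_id = "s1", pos = 33,
                        ref = substr(seq, 33, 33), alt = substr(seq, 33, 33),
                        risk_allele = "alt")
  eff <- allele_specific_matches(c(s1 = seq), var, list(p))
  expect_true(all(eff$effect %in% c("retained", "none")))
})

test_that("swapping allele labels and risk orientation flips the effect class", {
  p <- random_pwm(6, seed = 45, id = "m1")
  cons <- pwm_consensus(p)
  seq <- paste0(strrep("A", 20), cons, strrep("A", 20))
  pos <- 23  # inside the planted consensus
  ref <- substr(seq, pos, pos)
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  alt <- alts[which.min(p$logodds[alts, 3])]
  v1 <- tibble::tibble(variant_id = "r1", seq_id = "s", pos = pos,
                       ref = ref, alt = alt, risk_allele = "alt")
  e1 <- allele_specific_matches(c(s = seq), v1, list(p))
  expect_identical(e1$effect, "abrogates")
  # same physical alleles with labels and risk orientation swapped
  swapped_ref <- alt
  swapped_alt <- ref
  v2 <- tibble::tibble(variant_id = "r2", seq_id = "s", pos = pos,
                       ref = swapped_ref, alt = swapped_alt,
                       risk_allele = "alt")
  e2 <- suppressWarnings(allele_specific_matches(c(s = seq), v2, list(p)))
  expect_identical(e2$effect, "engenders")

  # windows crossing the boundary raise a truncated-window error
  v3 <- tibble::tibble(variant_id = "r3", seq_id = "s", pos = 2,
                       ref = "A", alt = "C", risk_allele = "alt")
  expect_error(allele_specific_matches(c(s = seq), v3, list(p)), "truncated")
})

test_that("prioritization orders changing effects by enrichment strength", {
  effects <- tibble::tibble(
    variant_id = c("r1", "r2", "r3", "r4"),
    motif_id = c("m1", "m2", "m3", "m1"),
    ref_score_fraction = c(0.9, 0.5, 0.9, 0.9),
    alt_score_fraction = c(0.5, 0.9, 0.9, 0.5),
    risk_allele = "alt",
    effect = c("abrogates", "engenders", "retained", "abrogates"),
    strand = "+", offset = 0L)
  enr <- tibble::tibble(motif_id = c("m1", "m2", "m3"),
                        z = c(3.1, 7.8, 1.0),
                        p = c(1e-3, 1e-14, 0.3),
                        q = c(2e-3, 3e-14, 0.3))
  ranked <- prioritize_snp_motif_pairs(effects, enr)
  expect_identical(ranked$motif_id[1], "m2")
  expect_equal(ranked$z[1:2], c(7.8, 3.1))
  expect_false("retained" %in% ranked$effect)
  expect_identical(ranked$rank, seq_len(nrow(ranked)))

  all_retained <- dplyr::mutate(effects, effect = "retained")
  expect_equal(nrow(prioritize_snp_motif_pairs(all_retained, enr)), 0)
  expect_error(prioritize_snp_motif_pairs(effects, enr[1:2, ]), "m3")
})

test_that("VCF coordinates round-trip through write and read", {
  skip_if_not_installed("vcfR")
  set.seed(46)
  n <- 200
  variants <- tibble::tibble(
    variant_id = sprintf("rs%04d", 1:n),
    seq_id = sample(sprintf("seq_%02d", 1:5), n, replace = TRUE),
    pos = sample.int(5000, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = NA_character_,
    risk_allele = sample(c("ref", "alt"), n, replace = TRUE))
  variants$alt <- unname(vapply(variants$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, ""))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(variants, path)
  back <- read_vcf(path)
  ord <- match(variants$variant_id, back$variant_id)
  expect_identical(back$pos[ord], variants$pos)
  expect_identical(back$ref[ord], variants$ref)
  expect_identical(back$alt[ord], variants$alt)
  expect_identical(back$risk_allele[ord], variants$risk_allele)
})
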