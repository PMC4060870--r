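#' Simulate LD-structured biallelic variants over the genome fixture
#'
#' Places `n_snps` single-nucleotide variants on the fixture sequences,
#' grouped into LD blocks of `ld_block_size`. Within a block every SNP's two
#' haplotype alleles copy a shared founder indicator, flipped independently
#' per site with probability `haplotype_flip_prob`, so within-block dosage
#' r-squared is near 1 while between-block r-squared is near 0. Two causal
#' SNPs are planted inside block 1 together with the designated lead SNP:
#' an *abrogate* SNP whose alternate allele destroys a planted causal-motif
#' match (reference window fraction >= threshold, alternate < threshold) and
#' an *engender* SNP whose alternate allele completes a deliberately broken
#' occurrence (reference < threshold, alternate >= threshold). Both are
#' verified with the package scanner at generation time; risk alleles of
#' causal SNPs are their alternate alleles.
#'
#' @param config A [synth_config()].
#' @param genome Output of [generate_genome_fixture()].
#' @param threshold_fraction Match threshold for causal verification
#'   (default 0.80).
#' @return List with `variants` (tibble: `variant_id`, `seq_id`, `pos`
#'   1-based, `ref`, `alt`, `risk_allele`, `block`), `genotypes` (integer
#'   dosage matrix, variants x individuals), and `truth` (list:
#'   `causal_snps` tibble with `variant_id`, `motif_id`, `effect_class`;
#'   `lead_snp`).
#' @export
generate_variants <- function(config, genome, threshold_fraction = 0.80) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  withr::local_seed(sub_seed(config$seed, 37L))

  sequences <- genome$sequences
  seq_ids <- names(sequences)
  lens <- nchar(sequences)
  L <- config$pwm_length
  pwms <- genome$pwms
  cpwm <- pwms[[genome$truth$causal_motif]]

  causal <- list()
  rows <- list()

  # abrogate causal SNP: flip a high-information column of a planted match
  pm <- if (config$n_snps > 0) genome$truth$planted_matches else
    genome$truth$planted_matches[0, ]
  pm <- pm[pm$motif_id == genome$truth$causal_motif &
             pm$seq_id %in% genome$truth$foreground, , drop = FALSE]
  if (nrow(pm) > 0) {
    for (i in sample.int(nrow(pm))) {
      hit <- pm[i, ]
      res <- find_allele_flip(sequences[[hit$seq_id]], hit$start, cpwm,
                              threshold_fraction, mode = "abrogate")
      if (!is.null(res)) {
        rows[[length(rows) + 1L]] <- tibble(
          seq_id = hit$seq_id, pos = res$pos, ref = res$ref, alt = res$alt,
          risk_allele = "alt", block = 1L)
        causal[[length(causal) + 1L]] <- tibble(
          motif_id = genome$truth$causal_motif, effect_class = "abrogate")
        break
      }
    }
  }

  # engender causal SNP: restore the consensus base of a broken occurrence
  bm <- if (config$n_snps > 0) genome$truth$broken_matches else
    genome$truth$broken_matches[0, ]
  if (nrow(bm) > 0) {
    for (i in seq_len(nrow(bm))) {
      b <- bm[i, ]
      pos <- b$start + b$broken_col  # 1-based position of the broken base
      seq <- sequences[[b$seq_id]]
      window <- extract_window(seq, pos, L)
      if (is.null(window)) next
      ref_frac <- best_fraction(window$seq, cpwm)
      alt_chars <- window_with_base(window, b$consensus_base)
      alt_frac <- best_fraction(alt_chars, cpwm)
      if (!is.na(ref_frac) && !is.na(alt_frac) &&
          ref_frac < threshold_fraction && alt_frac >= threshold_fraction) {
        rows[[length(rows) + 1L]] <- tibble(
          seq_id = b$seq_id, pos = pos, ref = b$broken_base,
          alt = b$consensus_base, risk_allele = "alt", block = 1L)
        causal[[length(causal) + 1L]] <- tibble(
          motif_id = genome$truth$causal_motif, effect_class = "engender")
        break
      }
    }
  }

  # decoy SNPs at random positions, reference allele = the sequence base
  n_decoys <- max(0L, config$n_snps - length(rows))
  guard <- 0L
  while (length(rows) - length(causal) < n_decoys && guard < 50L * n_decoys) {
    guard <- guard + 1L
    si <- sample.int(length(sequences), 1L)
    if (lens[si] <= 2L * L + 2L) next
    pos <- sample((L + 1L):(lens[si] - L), 1L)
    refb <- toupper(substr(sequences[[si]], pos, pos))
    if (!refb %in% c("A", "C", "G", "T")) next
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    rows[[length(rows) + 1L]] <- tibble(
      seq_id = seq_ids[si], pos = pos, ref = refb, alt = altb,
      risk_allele = sample(c("ref", "alt"), 1L), block = NA_integer_)
  }

  if (length(rows) == 0) {
    variants <- tibble(variant_id = character(), seq_id = character(),
                       pos = integer(), ref = character(), alt = character(),
                       risk_allele = character(), block = integer())
    genotypes <- matrix(integer(0), 0, config$n_individuals,
                        dimnames = list(NULL,
                          sprintf("ind_%03d", seq_len(config$n_individuals))))
    return(list(variants = variants, genotypes = genotypes,
                truth = list(causal_snps = tibble(variant_id = character(),
                                                  motif_id = character(),
                                                  effect_class = character()),
                             lead_snp = NA_character_)))
  }

  variants <- bind_rows(rows)
  if (any(variants$pos < 1 | variants$pos > lens[variants$seq_id])) {
    abort("generation error: SNP position outside its sequence.")
  }
  variants$variant_id <- sprintf("rs%04d", seq_len(nrow(variants)))
  # fill decoy blocks: block 1 first (with the causal SNPs), then the rest
  open <- which(is.na(variants$block))
  slots <- rep(seq_len(ceiling(nrow(variants) / config$ld_block_size)),
               each = config$ld_block_size)[seq_len(nrow(variants))]
  n_in_1 <- sum(variants$block == 1L, na.rm = TRUE)
  variants$block[open] <- slots[(n_in_1 + 1L):(n_in_1 + length(open))]

  # lead SNP: a non-causal member of block 1 (falls back to the first SNP)
  causal_ids <- variants$variant_id[seq_along(causal)]
  block1 <- variants$variant_id[variants$block == 1L]
  lead <- setdiff(block1, causal_ids)
  lead_snp <- if (length(lead) > 0) lead[1] else variants$variant_id[1]

  genotypes <- draw_block_genotypes(variants$block, config)
  rownames(genotypes) <- variants$variant_id

  causal_tbl <- if (length(causal)) {
    mutate(bind_rows(causal), variant_id = causal_ids, .before = 1)
  } else {
    tibble(variant_id = character(), motif_id = character(),
           effect_class = character())
  }
  list(variants = select(variants, "variant_id", dplyr::everything()),
       genotypes = genotypes,
       truth = list(causal_snps = causal_tbl, lead_snp = lead_snp))
}

# internal: dosage matrix with block-copy haplotypes
draw_block_genotypes <- function(blocks, config) {
  n_ind <- config$n_individuals
  geno <- matrix(0L, length(blocks), n_ind,
                 dimnames = list(NULL, sprintf("ind_%03d", seq_len(n_ind))))
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    p <- runif(1, 0.2, 0.5)
    h1 <- rbinom(n_ind, 1, p)
    h2 <- rbinom(n_ind, 1, p)
    for (v in idx) {
      f1 <- rbinom(n_ind, 1, config$haplotype_flip_prob)
      f2 <- rbinom(n_ind, 1, config$haplotype_flip_prob)
      geno[v, ] <- as.integer(abs(h1 - f1) + abs(h2 - f2))
    }
  }
  geno
}

# internal: the (2L-1)-wide window centred on pos, or NULL at a boundary
extract_window <- function(seq, pos, L) {
  lo <- pos - L + 1L
  hi <- pos + L - 1L
  if (lo < 1L || hi > nchar(seq)) return(NULL)
  list(seq = substr(seq, lo, hi), centre = L)
}

# internal: window sequence with the centre base replaced
window_with_base <- function(window, base) {
  chars <- strsplit(window$seq, "")[[1]]
  chars[window$centre] <- base
  paste0(chars, collapse = "")
}

# internal: search a planted window for a position/allele whose substitution
# abrogates (or engenders) the match at the given threshold
find_allele_flip <- function(seq, start, pwm, threshold_fraction, mode) {
  L <- pwm$length
  bases <- c("A", "C", "G", "T")
  for (col in order(-apply(pwm$logodds, 2, function(x) max(x) - sort(x, TRUE)[2]))) {
    pos <- start + col  # 1-based position within the sequence
    window <- extract_window(seq, pos, L)
    if (is.null(window)) next
    ref_frac <- best_fraction(window$seq, pwm)
    if (is.na(ref_frac)) next
    refb <- toupper(substr(seq, pos, pos))
    for (altb in setdiff(bases, refb)) {
      alt_frac <- best_fraction(window_with_base(window, altb), pwm)
      if (is.na(alt_frac)) next
      if (mode == "abrogate" && ref_frac >= threshold_fraction &&
          alt_frac < threshold_fraction) {
        return(list(pos = pos, ref = refb, alt = altb))
      }
      if (mode == "engender" && ref_frac < threshold_fraction &&
          alt_frac >= threshold_fraction) {
        return(list(pos = pos, ref = refb, alt = altb))
      }
    }
  }
  NULL
}
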