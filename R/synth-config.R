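#' Configuration for the synthetic-data generators
#'
#' One object drives every generator so that a single integer seed determines
#' the complete synthetic study: the paired patient cohort, the ten-cell-type
#' compendium, the intergenic sequence set with planted motif occurrences, and
#' the LD-structured variant panel. Defaults encode the study conditions the
#' pipeline is designed around: 60 patients across 3 study batches, 5% of
#' genes planted up and 5% down at a 2-fold shift with 0.3 log2-unit noise,
#' a 10-type compendium with 50 samples per type and a 2 log2-unit marker
#' margin, sequences with background base frequencies 0.30/0.20/0.20/0.30
#' (A/C/G/T) and per-kb motif planting, and 5-SNP LD blocks.
#'
#' @param seed Integer; every generator derives all randomness from it.
#' @param n_patients,n_studies Cohort size and number of study batches.
#' @param n_genes Number of genes simulated throughout.
#' @param frac_deg_up,frac_deg_down Fractions of genes planted as increased /
#'   decreased in lesional (PP) relative to uninvolved (PN) skin.
#' @param planted_log2fc Planted paired log2 fold-change magnitude.
#' @param noise_sd Per-sample noise standard deviation, log2 units.
#' @param n_celltypes,samples_per_celltype Compendium dimensions.
#' @param frac_marker_genes Fraction of genes planted as cell-type markers.
#' @param frac_off_genes Fraction of genes with near-zero baseline
#'   expression (log2 baseline uniform on 0-1), emulating transcripts the
#'   platform never detects; excluded from marker and module planting.
#' @param marker_log2_margin Minimum median log2 gap between a marker's own
#'   cell type and every other type.
#' @param detection_slope,detection_midpoint Logistic link from log2
#'   expression to detection probability:
#'   `plogis(detection_slope * (expr - detection_midpoint))`.
#' @param module_size,module_loading Size of the planted co-expression module
#'   and the loading of its latent factor (log2 units per factor SD).
#' @param n_sequences,seq_length Number of intergenic sequences and their
#'   mean length in bases (lengths vary uniformly within 0.5-1.5x).
#' @param n_pwms,pwm_length Motif dictionary size and motif width.
#' @param planted_motif_rate Planted consensus occurrences per kb.
#' @param fg_motif_boost Multiplier on `planted_motif_rate` for the causal
#'   motif within foreground (co-expression-module-adjacent) sequences.
#' @param ld_block_size,n_snps,n_individuals Variant panel dimensions.
#' @param haplotype_flip_prob Per-site probability that a haplotype departs
#'   from its block founder allele (controls within-block r^2).
#' @param n_probe_pairs Probe pairs per gene for the optional PM/MM table.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_patients = 60L, n_studies = 3L, n_genes = 1000L,
                         frac_deg_up = 0.05, frac_deg_down = 0.05,
                         planted_log2fc = 1, noise_sd = 0.3,
                         n_celltypes = 10L, samples_per_celltype = 50L,
                         frac_marker_genes = 0.10, frac_off_genes = 0.05,
                         marker_log2_margin = 2,
                         detection_slope = 1.5, detection_midpoint = 6,
                         module_size = 30L, module_loading = 0.8,
                         n_sequences = 300L, seq_length = 500L,
                         n_pwms = 21L, pwm_length = 8L,
                         planted_motif_rate = 0.5, fg_motif_boost = 4,
                         ld_block_size = 5L, n_snps = 60L,
                         n_individuals = 100L,
                         haplotype_flip_prob = 0.005,
                         n_probe_pairs = 11L) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients), n_studies = as.integer(n_studies),
    n_genes = as.integer(n_genes),
    frac_deg_up = frac_deg_up, frac_deg_down = frac_deg_down,
    planted_log2fc = planted_log2fc, noise_sd = noise_sd,
    n_celltypes = as.integer(n_celltypes),
    samples_per_celltype = as.integer(samples_per_celltype),
    frac_marker_genes = frac_marker_genes,
    frac_off_genes = frac_off_genes,
    marker_log2_margin = marker_log2_margin,
    detection_slope = detection_slope,
    detection_midpoint = detection_midpoint,
    module_size = as.integer(module_size), module_loading = module_loading,
    n_sequences = as.integer(n_sequences), seq_length = as.integer(seq_length),
    n_pwms = as.integer(n_pwms), pwm_length = as.integer(pwm_length),
    planted_motif_rate = planted_motif_rate, fg_motif_boost = fg_motif_boost,
    ld_block_size = as.integer(ld_block_size), n_snps = as.integer(n_snps),
    n_individuals = as.integer(n_individuals),
    haplotype_flip_prob = haplotype_flip_prob,
    n_probe_pairs = as.integer(n_probe_pairs)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  props <- c("frac_deg_up", "frac_deg_down", "frac_marker_genes",
             "frac_off_genes", "haplotype_flip_prob")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(paste0("configuration error: `", p, "` must be in [0, 1]."))
    }
  }
  counts <- c("n_patients", "n_studies", "n_genes", "n_celltypes",
              "samples_per_celltype", "n_sequences", "seq_length",
              "n_pwms", "pwm_length", "n_individuals", "n_probe_pairs",
              "ld_block_size")
  for (p in counts) {
    if (is.na(cfg[[p]]) || cfg[[p]] <= 0) {
      abort(paste0("configuration error: `", p, "` must be a positive count."))
    }
  }
  if (cfg$n_snps < 0) abort("configuration error: `n_snps` must be >= 0.")
  if (cfg$pwm_length >= cfg$seq_length) {
    abort("configuration error: `pwm_length` must be smaller than `seq_length`.")
  }
  if (cfg$noise_sd < 0) abort("configuration error: `noise_sd` must be >= 0.")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> seed", x$seed, "\n")
  cat("  cohort:", x$n_patients, "patients /", x$n_studies, "studies /",
      x$n_genes, "genes\n")
  cat("  compendium:", x$n_celltypes, "cell types x",
      x$samples_per_celltype, "samples\n")
  cat("  genome:", x$n_sequences, "sequences ~", x$seq_length, "bp,",
      x$n_pwms, "PWMs of width", x$pwm_length, "\n")
  cat("  variants:", x$n_snps, "SNPs in blocks of", x$ld_block_size, "over",
      x$n_individuals, "individuals\n")
  invisible(x)
}

# canonical background nucleotide frequencies (intergenic A/C/G/T)
DEFAULT_BACKGROUND <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)

# cell-type labels used by the compendium generator
celltype_names <- function(n) {
  base <- c("keratinocyte", "fibroblast", "t_cell_cd4", "t_cell_cd8",
            "b_cell", "nk_cell", "monocyte", "macrophage",
            "dendritic_cell", "neutrophil")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("celltype_%02d", seq_len(n - length(base)) + length(base)))
}
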