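#' SNPs in linkage disequilibrium with a lead variant
#'
#' r-squared is the squared Pearson correlation of genotype dosage vectors
#' (composite LD; phased input should be collapsed to 0/1/2 dosages first).
#' Partners must exceed the threshold strictly; the lead is always included
#' with r-squared 1. Monomorphic variants have no defined correlation and
#' are excluded with a warning.
#'
#' @param genotypes Dosage matrix, variants x individuals, rownames =
#'   variant ids.
#' @param lead Lead variant id.
#' @param r2_threshold Strict lower bound on partner r-squared
#'   (default 0.90).
#' @return An `ld_set` tibble: `variant_id`, `r2`, descending, lead first;
#'   attributes `lead` and `r2_threshold`.
#' @export
ld_partners <- function(genotypes, lead, r2_threshold = 0.90) {
  stopifnot(is.matrix(genotypes))
  if (!lead %in% rownames(genotypes)) {
    abort(paste0("lead variant '", lead, "' not in the genotype matrix."))
  }
  if (ncol(genotypes) < 2) abort("need at least 2 individuals.")
  lead_vec <- genotypes[lead, ]
  if (sd(lead_vec) == 0) abort("lead variant is monomorphic; r^2 undefined.")
  sds <- apply(genotypes, 1, sd)
  if (any(sds == 0)) {
    warn(paste0("excluding monomorphic variant(s): ",
                paste(rownames(genotypes)[sds == 0], collapse = ", ")))
  }
  keep <- sds > 0
  r2 <- suppressWarnings(cor(t(genotypes[keep, , drop = FALSE]), lead_vec)[, 1]^2)
  r2[rownames(genotypes)[keep] == lead] <- 1
  ids <- rownames(genotypes)[keep]
  sel <- r2 > r2_threshold | ids == lead
  out <- tibble(variant_id = ids[sel], r2 = unname(r2[sel]))
  out <- arrange(out, desc(.data$r2), .data$variant_id)
  out <- bind_rows(out[out$variant_id == lead, ],
                   out[out$variant_id != lead, ])
  attr(out, "lead") <- lead
  attr(out, "r2_threshold") <- r2_threshold
  class(out) <- c("ld_set", class(out))
  out
}

#' Candidate genes for a locus position
#'
#' The candidate set is every gene overlapping the position, plus the
#' nearest gene ending before it and the nearest gene starting after it
#' (0-based, half-open gene intervals; position is 1-based, VCF style).
#'
#' @param position 1-based position.
#' @param annotation Tibble with columns `seq_id`, `start`, `end`,
#'   `gene_id` (0-based half-open intervals).
#' @param seq_id Sequence the position lies on.
#' @return Character vector of gene ids.
#' @export
candidate_genes_for_locus <- function(position, annotation, seq_id) {
  ann <- annotation[annotation$seq_id == seq_id, , drop = FALSE]
  if (nrow(ann) == 0) {
    abort(paste0("no annotation for sequence '", seq_id, "'."))
  }
  pos0 <- position - 1L
  if (pos0 < 0) abort("position is off the start of the sequence.")
  overlapping <- ann$gene_id[ann$start <= pos0 & pos0 < ann$end]
  before <- ann[ann$end <= pos0, , drop = FALSE]
  upstream <- if (nrow(before) > 0) {
    before$gene_id[order(-before$end, before$gene_id)][1]
  } else character(0)
  after <- ann[ann$start > pos0, , drop = FALSE]
  downstream <- if (nrow(after) > 0) {
    after$gene_id[order(after$start, after$gene_id)][1]
  } else character(0)
  unique(c(overlapping, upstream, downstream))
}

#' Allele-specific motif matches at a variant
#'
#' For each PWM, builds the local sequence window (position +/- motif width
#' minus one) under the reference and alternate alleles, finds each
#' allele's best-scoring window over both strands, and classifies the
#' variant's effect on the motif in *risk-allele orientation*: `abrogates`
#' when the non-risk allele has a match (score fraction >= threshold) and
#' the risk allele does not; `engenders` for the converse; `retained` when
#' both alleles match; `none` when neither does. A degenerate variant with
#' `ref == alt` can only be `retained` or `none`. Windows crossing a
#' sequence boundary raise a truncated-window error.
#'
#' @param sequences Named character vector of sequences.
#' @param variant One-row tibble (or list) with `variant_id`, `seq_id`,
#'   `pos` (1-based), `ref`, `alt`, and optionally `risk_allele`
#'   (`"ref"`/`"alt"`, default `"alt"`).
#' @param pwms List of [pwm()] objects.
#' @param threshold_fraction Match threshold (default 0.80).
#' @inheritParams scan_sequence
#' @return Tibble: `variant_id`, `motif_id`, `ref_score_fraction`,
#'   `alt_score_fraction`, `risk_allele`, `effect`, `strand`, `offset`
#'   (0-based window start of the better allele's best window, relative to
#'   the sequence).
#' @export
allele_specific_matches <- function(sequences, variant, pwms,
                                    threshold_fraction = 0.80,
                                    score_scale = c("logodds", "prob")) {
  score_scale <- match.arg(score_scale)
  v <- as.list(variant)
  risk <- v$risk_allele %||% "alt"
  if (is.na(risk)) risk <- "alt"
  seq <- sequences[[v$seq_id]]
  if (is.null(seq)) abort(paste0("unknown sequence: ", v$seq_id))
  if (nchar(v$ref) != 1 || nchar(v$alt) != 1) {
    abort("only single-base substitutions are supported.")
  }
  seq_base <- toupper(substr(seq, v$pos, v$pos))
  if (seq_base != toupper(v$ref)) {
    warn(paste0("reference allele of ", v$variant_id,
                " does not match the sequence base."))
  }
  bind_rows(lapply(pwms, function(p) {
    L <- p$length
    window <- extract_window(seq, v$pos, L)
    if (is.null(window)) {
      abort(paste0("truncated window: variant ", v$variant_id,
                   " is within ", L - 1, " bases of a sequence boundary."))
    }
    ref_seq <- window_with_base(window, v$ref)
    alt_seq <- window_with_base(window, v$alt)
    ref_best <- best_fraction(ref_seq, p, score_scale, details = TRUE)
    alt_best <- best_fraction(alt_seq, p, score_scale, details = TRUE)
    rf <- ref_best$fraction
    af <- alt_best$fraction
    ref_match <- !is.na(rf) && rf >= threshold_fraction
    alt_match <- !is.na(af) && af >= threshold_fraction
    risk_match <- if (risk == "alt") alt_match else ref_match
    nonrisk_match <- if (risk == "alt") ref_match else alt_match
    effect <- if (risk_match && nonrisk_match) "retained"
      else if (!risk_match && !nonrisk_match) "none"
      else if (nonrisk_match && !risk_match) "abrogates"
      else "engenders"
    best <- if (isTRUE(af > rf) || is.na(rf)) alt_best else ref_best
    win_start <- v$pos - L  # 0-based start of the local window
    tibble(variant_id = v$variant_id, motif_id = p$id,
           ref_score_fraction = rf, alt_score_fraction = af,
           risk_allele = risk, effect = effect,
           strand = best$strand,
           offset = if (is.na(best$offset)) NA_integer_ else
             as.integer(win_start + best$offset))
  }))
}

#' Rank SNP-motif pairs by co-expression-guided motif enrichment
#'
#' Keeps only effects that change a match (`abrogates` / `engenders`) and
#' orders them by the motif's enrichment z among sequences adjacent to the
#' target gene's co-expression partners — strongest enrichment first, ties
#' by smaller p then motif id. Each entry carries the motif's q-value and a
#' significance flag.
#'
#' @param effects Tibble from [allele_specific_matches()] (possibly
#'   row-bound over variants).
#' @param enrichment A `motif_enrichment` tibble covering every motif in
#'   `effects`.
#' @param alpha Significance threshold on q (default 0.05).
#' @return Tibble of ranked effects with `z`, `p`, `q`, `significant`,
#'   `rank`.
#' @export
prioritize_snp_motif_pairs <- function(effects, enrichment, alpha = 0.05) {
  missing <- setdiff(unique(effects$motif_id), enrichment$motif_id)
  if (length(missing) > 0) {
    abort(paste0("no enrichment result for motif(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- effects |>
    filter(.data$effect %in% c("abrogates", "engenders")) |>
    left_join(select(enrichment, "motif_id", "z", "p", "q"),
              by = "motif_id") |>
    arrange(desc(.data$z), .data$p, .data$motif_id) |>
    mutate(significant = .data$q < alpha, rank = row_number())
  out
}
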