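#' Paired lesional-versus-uninvolved differential expression statistics
#'
#' For each gene, computes the per-patient fold-change
#' `fc = 2^(PP - PN)` on log2 values, its median over patients, per-study
#' median fold-changes, and a p-value from either a two-sample Wilcoxon
#' rank-sum test of PP versus PN values (`test_mode = "rank_sum"`, the
#' default) or a Wilcoxon signed-rank test of the paired differences
#' (`test_mode = "signed_rank"`).
#'
#' @param bundle An [expression_bundle()] whose PP/PN samples pair by
#'   `patient_id` — every patient must have exactly one of each.
#' @param genes Optional gene-id subset (e.g. the skin-expressed set).
#' @param test_mode `"rank_sum"` or `"signed_rank"`.
#' @return Tibble with columns `gene_id`, `median_fc`, `p`,
#'   `n_patients_fc_above_1`, and one `median_fc_<study>` column per study.
#'   The per-patient log2 fold-change matrix is attached as attribute
#'   `patient_log2fc` (genes x patients).
#' @export
paired_de_stats <- function(bundle, genes = NULL,
                            test_mode = c("rank_sum", "signed_rank")) {
  stopifnot(inherits(bundle, "expression_bundle"))
  test_mode <- match.arg(test_mode)
  s <- bundle$samples
  counts <- table(s$patient_id, s$group)
  bad <- rownames(counts)[counts[, "PP"] != 1 | counts[, "PN"] != 1]
  if (length(bad) > 0) {
    abort(paste0("unpaired patient(s): ", paste(bad, collapse = ", ")))
  }
  patients <- sort(unique(s$patient_id))
  pp_ids <- s$sample_id[match(paste0(patients, ".PP"),
                              paste0(s$patient_id, ".", s$group))]
  pn_ids <- s$sample_id[match(paste0(patients, ".PN"),
                              paste0(s$patient_id, ".", s$group))]
  study <- s$study_id[match(pp_ids, s$sample_id)]

  genes <- genes %||% rownames(bundle$values)
  vals_pp <- bundle$values[genes, pp_ids, drop = FALSE]
  vals_pn <- bundle$values[genes, pn_ids, drop = FALSE]
  d <- vals_pp - vals_pn
  colnames(d) <- patients

  p <- vapply(seq_along(genes), function(i) {
    if (test_mode == "rank_sum") {
      if (all(vals_pp[i, ] == vals_pn[i, ])) return(1)
      suppressWarnings(wilcox.test(vals_pp[i, ], vals_pn[i, ])$p.value)
    } else {
      di <- d[i, ][d[i, ] != 0]
      if (length(di) == 0) return(1)
      suppressWarnings(wilcox.test(di, mu = 0)$p.value)
    }
  }, 1.0)

  out <- tibble(
    gene_id = genes,
    median_fc = unname(2^apply(d, 1, median)),
    p = p,
    n_patients_fc_above_1 = unname(rowSums(d > 0))
  )
  for (st in sort(unique(study))) {
    out[[paste0("median_fc_", st)]] <-
      unname(2^apply(d[, study == st, drop = FALSE], 1, median))
  }
  attr(out, "patient_log2fc") <- d
  out
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    abort("`pvals` must be numeric in [0, 1] with no NAs.")
  }
  p.adjust(pvals, method = "BH")
}

#' Call differentially expressed genes with cross-study consistency
#'
#' A gene is called up when `q < max_q`, its median fold-change exceeds
#' `fc_up`, and its median fold-change within *every* study exceeds 1
#' (strictly); down is the mirror image with `fc_down` and study medians
#' below 1. Everything else is `none`. Inequalities at the fold-change
#' boundaries are strict.
#'
#' @param stats Output of [paired_de_stats()].
#' @param fc_up,fc_down Linear fold-change thresholds (defaults 1.50, 0.67).
#' @param max_q FDR threshold (default 0.05).
#' @return A `deg_table` tibble: the input plus `q` and
#'   `direction` (`"up"`, `"down"`, `"none"`), carrying the
#'   `patient_log2fc` attribute through.
#' @export
call_degs <- function(stats, fc_up = 1.50, fc_down = 0.67, max_q = 0.05) {
  study_cols <- grep("^median_fc_", names(stats), value = TRUE)
  if (length(study_cols) == 0) {
    abort("`stats` must carry per-study median fold-change columns.")
  }
  q <- bh_fdr(stats$p)
  sm <- as.matrix(stats[, study_cols])
  all_up <- rowSums(sm > 1) == ncol(sm)
  all_down <- rowSums(sm < 1) == ncol(sm)
  direction <- rep("none", nrow(stats))
  direction[q < max_q & stats$median_fc > fc_up & all_up] <- "up"
  direction[q < max_q & stats$median_fc < fc_down & all_down] <- "down"
  out <- mutate(stats, q = q, direction = direction,
                .after = "p")
  attr(out, "patient_log2fc") <- attr(stats, "patient_log2fc")
  class(out) <- c("deg_table", class(out))
  out
}

#' Genes responding in every single patient
#'
#' The universal up-set contains up-called DEGs whose per-patient
#' fold-change strictly exceeds 1 for *every* patient; the down-set is the
#' mirror image. A patient at fold-change exactly 1 excludes the gene.
#'
#' @param degs A `deg_table` from [call_degs()] (or [paired_de_stats()]
#'   output passed through it).
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
universal_response_genes <- function(degs, direction = c("up", "down")) {
  direction <- match.arg(direction)
  d <- attr(degs, "patient_log2fc")
  if (is.null(d)) {
    abort("`degs` must carry the `patient_log2fc` attribute from paired_de_stats().")
  }
  called <- degs$gene_id[degs$direction == direction]
  d <- d[called, , drop = FALSE]
  if (direction == "up") {
    called[rowSums(d > 0) == ncol(d)]
  } else {
    called[rowSums(d < 0) == ncol(d)]
  }
}
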