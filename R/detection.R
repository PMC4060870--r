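#' Detection call from paired perfect-match/mismatch probes
#'
#' Tests whether perfect-match (PM) intensities exceed their paired mismatch
#' (MM) intensities with a one-sided Wilcoxon signed-rank test; a small
#' p-value is evidence that the probe set is detected above background. The
#' exact null distribution is used for n <= 25 probe pairs (tied or zero
#' differences fall back to the normal approximation, as usual for this
#' test). Adding a common constant to both PM and MM leaves the result
#' unchanged.
#'
#' @param pm,mm Equal-length numeric vectors of probe intensities.
#' @return A single p-value in (0, 1]; attribute `degenerate` is `TRUE` when
#'   every PM equals its MM (no evidence either way, p = 1).
#' @export
detect_above_background <- function(pm, mm) {
  if (!is.numeric(pm) || !is.numeric(mm) || length(pm) != length(mm) ||
      length(pm) < 1) {
    abort("`pm` and `mm` must be numeric vectors of equal length >= 1.")
  }
  d <- pm - mm
  d <- d[d != 0]
  if (length(d) == 0) {
    return(structure(1, degenerate = TRUE))
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    wilcox.test(d, alternative = "greater", mu = 0, exact = exact)$p.value
  )
  structure(unname(p), degenerate = FALSE)
}

#' Per-gene detection frequency within a sample group
#'
#' The proportion of a group's samples in which each gene was called
#' detected above background.
#'
#' @param bundle An [expression_bundle()].
#' @param group Group label(s) present in `bundle$samples$group`.
#' @return Tibble with columns `gene_id`, `group`, `n_samples`, `frequency`.
#' @export
detection_frequency <- function(bundle, group) {
  stopifnot(inherits(bundle, "expression_bundle"))
  ids <- group_samples(bundle, group)
  det <- bundle$detected[, ids, drop = FALSE]
  tibble(gene_id = rownames(det),
         group = paste(group, collapse = "+"),
         n_samples = length(ids),
         frequency = unname(rowMeans(det)))
}

#' Genes expressed in skin: detection in at least a fraction of biopsies
#'
#' Filters to genes detected in at least `min_fraction` of all PP and PN
#' biopsies combined (boundary inclusive).
#'
#' @param bundle An [expression_bundle()] with PP and PN samples.
#' @param min_fraction Minimum detection fraction (default 0.10).
#' @return Character vector of gene ids.
#' @export
skin_expressed_filter <- function(bundle, min_fraction = 0.10) {
  freq <- detection_frequency(bundle, c("PP", "PN"))
  freq$gene_id[freq$frequency >= min_fraction]
}
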