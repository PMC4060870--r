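#' Percentile trimming of samples by QC metrics
#'
#' For each metric in the spec, removes the `floor(fraction * n)` most
#' extreme samples from the requested tail(s) — e.g. fraction 0.025 with
#' `tail = "both"` drops the 2.5% lowest and 2.5% highest. Removal sets from
#' successive metrics are unioned, so a sample flagged twice is removed once.
#' Ordering within a metric breaks ties by sample id, making the retained
#' set independent of input row order.
#'
#' @param metrics Tibble with a `sample_id` column and one numeric column
#'   per QC metric.
#' @param spec Tibble with columns `metric`, `tail` (`"both"`, `"low"` or
#'   `"high"`) and `fraction` (in `[0, 0.5]`).
#' @return Character vector of retained sample ids, in input order.
#' @export
qc_trim <- function(metrics, spec) {
  metrics <- as_tibble(metrics)
  spec <- as_tibble(spec)
  stopifnot("sample_id" %in% names(metrics),
            all(c("metric", "tail", "fraction") %in% names(spec)))
  if (any(!spec$metric %in% names(metrics))) {
    abort(paste0("unknown QC metric(s): ",
                 paste(setdiff(spec$metric, names(metrics)), collapse = ", ")))
  }
  if (any(spec$fraction < 0 | spec$fraction > 0.5)) {
    abort("`fraction` must be in [0, 0.5].")
  }
  n <- nrow(metrics)
  removed <- character(0)
  for (i in seq_len(nrow(spec))) {
    k <- floor(spec$fraction[i] * n)
    if (k == 0) next
    ord <- metrics$sample_id[order(metrics[[spec$metric[i]]],
                                   metrics$sample_id)]
    tail_i <- spec$tail[i]
    if (tail_i %in% c("both", "low")) removed <- c(removed, head(ord, k))
    if (tail_i %in% c("both", "high")) removed <- c(removed, tail(ord, k))
  }
  metrics$sample_id[!metrics$sample_id %in% removed]
}

#' Representative samples closest to the group centroid
#'
#' The centroid is the per-gene mean over the group's samples; the `k`
#' samples with smallest Euclidean distance to it are returned in ascending
#' distance order (ties broken by sample id). Groups of at most `k` samples
#' are returned whole.
#'
#' @param bundle An [expression_bundle()].
#' @param group Group label.
#' @param k Number of representatives (default 50).
#' @return Character vector of sample ids, ascending distance.
#' @export
select_representatives <- function(bundle, group, k = 50) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (k <= 0) abort("`k` must be positive.")
  ids <- group_samples(bundle, group)
  vals <- bundle$values[, ids, drop = FALSE]
  centroid <- rowMeans(vals)
  d <- sqrt(colSums((vals - centroid)^2))
  ord <- order(d, ids)
  head(ids[ord], min(k, length(ids)))
}

#' Choose one representative probe set per gene
#'
#' Prefers probe sets expected to hybridize specifically: suffix class
#' `none` beats `_s`, which beats `_x`. Within the best available class, the
#' probe set maximizing the mean of its median PP and median PN expression
#' wins; remaining ties resolve to the lexicographically smallest probe-set
#' id.
#'
#' @param candidates Tibble with columns `probe_set_id`, `suffix_class`
#'   (`"none"`, `"_s"`, `"_x"`), `median_pp`, `median_pn`.
#' @return The chosen `probe_set_id`.
#' @export
choose_representative_probeset <- function(candidates) {
  candidates <- as_tibble(candidates)
  stopifnot(nrow(candidates) >= 1,
            all(c("probe_set_id", "suffix_class", "median_pp",
                  "median_pn") %in% names(candidates)))
  pref <- c(none = 1L, `_s` = 2L, `_x` = 3L)
  cls <- pref[candidates$suffix_class]
  if (any(is.na(cls))) abort("`suffix_class` must be one of none, _s, _x.")
  best <- candidates[cls == min(cls), , drop = FALSE]
  avg <- (best$median_pp + best$median_pn) / 2
  best <- best[avg == max(avg), , drop = FALSE]
  sort(best$probe_set_id)[1]
}

#' Normalize expression to a reference tissue
#'
#' Converts log2 expression to linear expression relative to each gene's
#' median in the reference group: `2^(log2expr - reference median)`. A
#' sample sitting at the reference median maps to 1.0.
#'
#' @param bundle An [expression_bundle()].
#' @param reference_group Reference group label (default `"normal_skin"`).
#' @return Numeric matrix of relative expression, same shape as
#'   `bundle$values`, with the per-gene reference medians attached as
#'   attribute `reference_median`.
#' @export
normalize_to_reference <- function(bundle, reference_group = "normal_skin") {
  stopifnot(inherits(bundle, "expression_bundle"))
  ids <- group_samples(bundle, reference_group)
  ref_median <- apply(bundle$values[, ids, drop = FALSE], 1, median)
  rel <- 2^(bundle$values - ref_median)
  attr(rel, "reference_median") <- ref_median
  rel
}
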