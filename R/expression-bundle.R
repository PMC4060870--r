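#' Expression bundle container
#'
#' Bundles a gene-by-sample matrix of log2 expression values with per-sample
#' detection calls and the sample/gene metadata every downstream stage needs.
#' Expression values stay as a plain numeric matrix (genes in rows, samples in
#' columns); metadata are tibbles so results chain with dplyr verbs.
#'
#' @param values Numeric matrix of log2 expression, genes x samples, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param samples Tibble with columns `sample_id`, `group` (e.g. `"PP"`,
#'   `"PN"`, a cell-type name or `"normal_skin"`), and optionally
#'   `patient_id`, `study_id`.
#' @param genes Tibble with columns `gene_id` and optionally `probe_set_id`,
#'   `suffix_class` (one of `"none"`, `"_s"`, `"_x"`).
#' @param detected Logical matrix, same shape as `values`: was the gene called
#'   detected above background in that sample? Defaults to all `TRUE`.
#' @param detection_p Optional numeric matrix of detection p-values, same
#'   shape as `values`. When present, `detected` must equal
#'   `detection_p < detection_alpha`.
#' @param detection_alpha Significance level linking `detection_p` to
#'   `detected` (default 0.05).
#'
#' @return An object of class `expression_bundle`.
#' @export
expression_bundle <- function(values, samples, genes = NULL, detected = NULL,
                              detection_p = NULL, detection_alpha = 0.05) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene ids as rownames and sample ids as colnames.")
  }
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("`samples` needs at least columns `sample_id` and `group`.")
  }
  if (!identical(sort(samples$sample_id), sort(colnames(values)))) {
    abort("`samples$sample_id` must match the column names of `values`.")
  }
  samples <- samples[match(colnames(values), samples$sample_id), ]
  if (is.null(genes)) genes <- tibble(gene_id = rownames(values))
  genes <- as_tibble(genes)
  if (!"gene_id" %in% names(genes) ||
      !identical(sort(genes$gene_id), sort(rownames(values)))) {
    abort("`genes$gene_id` must match the row names of `values`.")
  }
  genes <- genes[match(rownames(values), genes$gene_id), ]
  if (is.null(detected)) {
    if (!is.null(detection_p)) {
      detected <- detection_p < detection_alpha
    } else {
      detected <- matrix(TRUE, nrow(values), ncol(values),
                         dimnames = dimnames(values))
    }
  }
  stopifnot(identical(dim(detected), dim(values)))
  if (!is.null(detection_p)) {
    stopifnot(identical(dim(detection_p), dim(values)))
    if (!identical(unname(detected), unname(detection_p < detection_alpha))) {
      abort("`detected` must equal `detection_p < detection_alpha`.")
    }
  }
  structure(
    list(values = values, detected = detected, detection_p = detection_p,
         samples = samples, genes = genes, detection_alpha = detection_alpha),
    class = "expression_bundle"
  )
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat("<expression_bundle> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  grp <- table(x$samples$group)
  cat("  groups: ", paste0(names(grp), " (", grp, ")", collapse = ", "), "\n",
      sep = "")
  cat("  detected: ", round(100 * mean(x$detected), 1), "% of cells\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_bundle <- function(x) dim(x$values)

# internal: sample ids belonging to a metadata group
group_samples <- function(bundle, group) {
  ids <- bundle$samples$sample_id[bundle$samples$group %in% group]
  if (length(ids) == 0) {
    abort(paste0("no samples in group '", paste(group, collapse = ","), "'"))
  }
  ids
}
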