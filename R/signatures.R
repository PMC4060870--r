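#' Build a weighted cell-type signature from the compendium
#'
#' For each candidate gene, the specificity margin is its median log2
#' expression in the target cell type minus the highest median among the
#' other types. The `k` genes with the largest positive margin (among genes
#' detected in at least `detection_threshold` of the type's samples) form
#' the signature, weighted proportionally to their margin (floored at `eps`)
#' and normalized to sum 1, so the most type-specific genes carry the most
#' weight.
#'
#' @param bundle The compendium [expression_bundle()].
#' @param cell_type Target cell type.
#' @param k Signature size (default 250).
#' @param detection_threshold Minimum detection frequency in the target type
#'   (default 0.10).
#' @param reference_group Reference tissue group excluded from margins.
#' @param allow_fewer If `TRUE`, silently use all available genes when fewer
#'   than `k` have positive margin; if `FALSE` (default) raise a shortfall
#'   error naming the available count.
#' @param genes Optional candidate gene restriction (e.g. the
#'   skin-expressed set the scores will be computed over).
#' @param eps Weight floor (default 1e-6).
#' @return A `signature_set` tibble: `cell_type`, `gene_id`, `margin`,
#'   `weight` (descending margin; weights sum to 1).
#' @export
build_signature <- function(bundle, cell_type, k = 250,
                            detection_threshold = 0.10,
                            reference_group = "normal_skin",
                            allow_fewer = FALSE, genes = NULL, eps = 1e-6) {
  stopifnot(inherits(bundle, "expression_bundle"))
  types <- setdiff(unique(bundle$samples$group), reference_group)
  if (length(types) < 2) abort("compendium needs at least 2 cell types.")
  if (!cell_type %in% types) abort(paste0("unknown cell type: ", cell_type))

  med <- vapply(types, function(t) {
    apply(bundle$values[, group_samples(bundle, t), drop = FALSE], 1, median)
  }, numeric(nrow(bundle$values)))
  own <- med[, cell_type]
  other <- apply(med[, setdiff(types, cell_type), drop = FALSE], 1, max)
  margin <- own - other
  det <- rowMeans(bundle$detected[, group_samples(bundle, cell_type),
                                  drop = FALSE])
  eligible <- margin > 0 & det >= detection_threshold
  if (!is.null(genes)) {
    eligible <- eligible & rownames(bundle$values) %in% genes
  }
  n_avail <- sum(eligible)
  if (n_avail < k && !allow_fewer) {
    abort(paste0("signature shortfall: only ", n_avail,
                 " genes with positive specificity margin (k = ", k, ")."))
  }
  k_eff <- min(k, n_avail)
  if (k_eff == 0) abort("no genes with positive specificity margin.")
  ord <- order(-margin, rownames(bundle$values))
  ord <- ord[eligible[ord]][seq_len(k_eff)]
  w <- pmax(margin[ord], eps)
  out <- tibble(cell_type = cell_type,
                gene_id = rownames(bundle$values)[ord],
                margin = margin[ord],
                weight = w / sum(w))
  class(out) <- c("signature_set", class(out))
  out
}

#' Score one patient against a cell-type signature
#'
#' The score is the weighted mean of the patient's log2 fold-changes over
#' the signature genes (`scale = "linear"` instead averages the linear
#' ratios). Zero means no coordinated shift; the score is linear in log2
#' fold-change, so squaring every fold-change doubles it. Significance
#' comes from a two-sided Wilcoxon rank-sum test of the signature genes'
#' fold-changes against all other genes' fold-changes for that patient.
#'
#' @param signature A `signature_set` from [build_signature()].
#' @param fc Named numeric vector: the patient's linear PP/PN fold-changes
#'   over the skin-expressed genes (must contain every signature gene).
#' @param alpha Significance level for the direction call (default 0.05).
#' @param scale `"log2"` (default) or `"linear"`.
#' @return Tibble with one row: `cell_type`, `score`, `p`, `direction`
#'   (`"high"`, `"low"`, `"ns"`).
#' @export
score_patient <- function(signature, fc, alpha = 0.05,
                          scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  missing <- setdiff(signature$gene_id, names(fc))
  if (length(missing) > 0) {
    abort(paste0("fold-change vector is missing signature gene(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  x <- if (scale == "log2") log2(fc) else fc
  centre <- if (scale == "log2") 0 else 1
  in_sig <- x[signature$gene_id]
  out_sig <- x[setdiff(names(x), signature$gene_id)]
  score <- sum(signature$weight * in_sig)
  p <- if (length(out_sig) == 0) 1 else
    suppressWarnings(wilcox.test(in_sig, out_sig)$p.value)
  direction <- if (p < alpha && score > centre) "high"
    else if (p < alpha && score < centre) "low" else "ns"
  tibble(cell_type = signature$cell_type[1], score = score, p = p,
         direction = direction)
}

#' Score every patient against every signature
#'
#' @param signatures List of `signature_set`s.
#' @param fc_matrix Genes x patients matrix of linear fold-changes.
#' @inheritParams score_patient
#' @return A `signature_scores` tibble: `patient_id`, `cell_type`, `score`,
#'   `p`, `direction`.
#' @export
score_patients <- function(signatures, fc_matrix, alpha = 0.05,
                           scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  out <- bind_rows(lapply(colnames(fc_matrix), function(pt) {
    fc <- fc_matrix[, pt]
    bind_rows(lapply(signatures, function(sig) {
      mutate(score_patient(sig, fc, alpha, scale), patient_id = pt,
             .before = 1)
    }))
  }))
  class(out) <- c("signature_scores", class(out))
  out
}

#' Hierarchical clustering with deterministic distances
#'
#' Thin, deterministic wrapper around [stats::hclust()]: Euclidean distance
#' or Spearman correlation distance (1 - rank correlation, invariant to
#' monotone transforms of rows), complete or average linkage. A constant
#' row under the Spearman metric has no defined correlation and raises an
#' error naming the row.
#'
#' @param mat Numeric matrix; rows are clustered.
#' @param metric `"euclidean"` or `"spearman_distance"`.
#' @param linkage `"complete"` or `"average"`.
#' @return List of class `hc_result`: `hclust` (the stats object),
#'   `order` (row labels in dendrogram order), `metric`, `linkage`.
#' @export
hierarchical_cluster <- function(mat,
                                 metric = c("euclidean", "spearman_distance"),
                                 linkage = c("complete", "average")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  if (nrow(mat) < 2) abort("need at least 2 rows to cluster.")
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("row_%d", seq_len(nrow(mat)))
  if (metric == "euclidean") {
    d <- dist(mat)
  } else {
    sds <- apply(mat, 1, sd)
    if (any(sds == 0)) {
      abort(paste0("constant row(s) under spearman_distance: ",
                   paste(rownames(mat)[sds == 0], collapse = ", ")))
    }
    d <- stats::as.dist(1 - cor(t(mat), method = "spearman"))
  }
  h <- hclust(d, method = linkage)
  structure(list(hclust = h, order = rownames(mat)[h$order],
                 metric = metric, linkage = linkage),
            class = "hc_result")
}

#' Export a clustering as Newick text
#'
#' @param x An `hc_result` from [hierarchical_cluster()].
#' @return Newick string (with branch lengths from merge heights).
#' @export
cluster_newick <- function(x) {
  stopifnot(inherits(x, "hc_result"))
  ape::write.tree(ape::as.phylo(x$hclust))
}
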