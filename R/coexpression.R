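#' Rank genes by Spearman co-expression with a target gene
#'
#' Computes the Spearman correlation of every eligible gene with the target
#' across a cell type's samples, drops the target itself and genes with
#' non-positive correlation, and returns the rest in descending order
#' (ties broken by gene id). Rank-based, so invariant to monotone
#' transforms of the expression scale.
#'
#' @param expr Genes x samples matrix for the cell type of interest.
#' @param target Target gene id (a rowname of `expr`).
#' @param eligible Gene ids eligible for ranking (e.g. genes expressed in
#'   both skin and this cell type). Default: all rows.
#' @return Tibble with columns `gene_id`, `r_s`, descending.
#' @export
coexpression_ranking <- function(expr, target, eligible = NULL) {
  stopifnot(is.matrix(expr), target %in% rownames(expr))
  if (ncol(expr) < 3) abort("need at least 3 samples.")
  tvec <- expr[target, ]
  if (sd(tvec) == 0) {
    abort(paste0("target gene '", target,
                 "' is constant across samples; correlation undefined."))
  }
  eligible <- setdiff(eligible %||% rownames(expr), target)
  eligible <- intersect(rownames(expr), eligible)
  r <- suppressWarnings(
    cor(t(expr[eligible, , drop = FALSE]), tvec, method = "spearman")[, 1]
  )
  out <- tibble(gene_id = eligible, r_s = unname(r))
  out <- out[!is.na(out$r_s) & out$r_s > 0, ]
  arrange(out, desc(.data$r_s), .data$gene_id)
}

#' Knee cutoff on a descending correlation curve
#'
#' Normalizes the curve of descending correlations to the unit square —
#' x is the rank fraction `i/m`, y is `r_i^power / r_1^power` — and returns
#' the rank minimizing Euclidean distance to the origin (the "bend" of the
#' curve). Raising to `power` (default 7) sharpens the bend without changing
#' the order. Ties resolve to the smallest rank.
#'
#' @param r_values Numeric vector of correlations, sorted descending,
#'   all > 0.
#' @param power Exponent applied before normalization (default 7).
#' @return Integer cutoff rank (1 for a single value).
#' @export
knee_cutoff <- function(r_values, power = 7) {
  m <- length(r_values)
  if (m == 0) abort("`r_values` must be non-empty.")
  if (any(r_values <= 0)) abort("`r_values` must all be positive.")
  if (is.unsorted(-r_values)) abort("`r_values` must be sorted descending.")
  if (m == 1) return(1L)
  x <- seq_len(m) / m
  y <- r_values^power / r_values[1]^power
  which.min(x^2 + y^2)
}

#' Local co-expression network with knee-based size cutoff
#'
#' Composes [coexpression_ranking()] and [knee_cutoff()]: the network is the
#' top `N` co-expression partners of the target, with `N` set by the knee of
#' the descending correlation curve.
#'
#' @inheritParams coexpression_ranking
#' @inheritParams knee_cutoff
#' @return A `coexpression_network` list: `target`, `partners` (tibble
#'   `gene_id`, `r_s`, truncated at the cutoff), `ranking` (full positive
#'   ranking), `cutoff_n`, `power`, `empty` flag.
#' @export
build_network <- function(expr, target, eligible = NULL, power = 7) {
  ranking <- coexpression_ranking(expr, target, eligible)
  if (nrow(ranking) == 0) {
    res <- list(target = target, partners = ranking, ranking = ranking,
                cutoff_n = 0L, power = power, empty = TRUE)
    class(res) <- "coexpression_network"
    return(res)
  }
  n <- knee_cutoff(ranking$r_s, power)
  res <- list(target = target, partners = ranking[seq_len(n), ],
              ranking = ranking, cutoff_n = as.integer(n), power = power,
              empty = FALSE)
  class(res) <- "coexpression_network"
  res
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("<coexpression_network> target ", x$target, ": ", x$cutoff_n,
      " partners (of ", nrow(x$ranking), " positively correlated; power ",
      x$power, ")", if (x$empty) " [empty]", "\n", sep = "")
  invisible(x)
}
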