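#' Fisher's exact test for cell-type assignment enrichment
#'
#' Tests whether a gene set is enriched for genes assigned to a given cell
#' type relative to a background set, via the 2 x 2 table
#' (in set vs not) x (assigned to type vs not). The reported odds ratio is
#' the sample cross-product ratio (invariant to transposing the table); the
#' p-value is the two-sided exact hypergeometric probability.
#'
#' @param set Character vector of gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of gene ids.
#' @param assignments An `assignment_table` from [assign_cell_types()].
#' @param cell_type Cell type of interest.
#' @return Tibble with one row: `cell_type`, `odds_ratio`, `p`,
#'   `set_assigned`, `set_total`, `bg_assigned`, `bg_total`.
#' @export
fisher_assignment_enrichment <- function(set, background, assignments,
                                         cell_type) {
  if (length(set) == 0) abort("`set` must be non-empty.")
  if (!all(set %in% background)) abort("`set` must be a subset of `background`.")
  assigned <- assignments$gene_id[assignments$assigned == cell_type]
  if (length(assigned) == 0) {
    abort(paste0("cell type '", cell_type,
                 "' has no assigned genes in the background."))
  }
  rest <- setdiff(background, set)
  a <- sum(set %in% assigned)
  b <- length(set) - a
  c_ <- sum(rest %in% assigned)
  d <- length(rest) - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  p <- fisher.test(tab)$p.value
  or <- (a * d) / (b * c_)
  tibble(cell_type = cell_type, odds_ratio = or, p = p,
         set_assigned = a, set_total = length(set),
         bg_assigned = c_ + a, bg_total = length(background))
}

#' Area-type gene-set enrichment statistic over a ranked list
#'
#' Walks down a ranked gene list accumulating the fraction of the gene set
#' encountered; the statistic is the mean vertical deviation between this
#' cumulative-overlap curve and the diagonal (the random expectation).
#' Positive area means the set concentrates at the top of the ranking;
#' reversing the ranking exactly negates the area. Equivalently a normalized
#' Mann-Whitney location shift, so the p-value is a two-sided Wilcoxon
#' rank-sum test of the set members' ranks against the non-members' ranks.
#'
#' @param ranked Character vector: the universe, best rank first, no
#'   duplicates.
#' @param set Character vector, subset of `ranked`.
#' @return A `gsea_result` list: `area`, `p`, `set_size`, `universe_size`,
#'   `curve` (cumulative overlap fractions), `degenerate` (empty set or
#'   set = universe: area 0, p 1).
#' @export
gsea_area <- function(ranked, set) {
  if (anyDuplicated(ranked)) abort("`ranked` must not contain duplicates.")
  if (!all(set %in% ranked)) abort("`set` must be a subset of `ranked`.")
  m <- length(ranked)
  member <- ranked %in% set
  k <- sum(member)
  if (k == 0 || k == m) {
    res <- list(area = 0, p = 1, set_size = k, universe_size = m,
                curve = if (k == 0) rep(0, m) else seq_len(m) / m,
                degenerate = TRUE)
    class(res) <- "gsea_result"
    return(res)
  }
  curve <- cumsum(member) / k
  area <- mean(curve - seq_len(m) / m)
  p <- suppressWarnings(
    wilcox.test(which(member), which(!member))$p.value
  )
  res <- list(area = area, p = p, set_size = k, universe_size = m,
              curve = curve, degenerate = FALSE)
  class(res) <- "gsea_result"
  res
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("<gsea_result> area ", signif(x$area, 4), ", p ", signif(x$p, 4),
      " (set ", x$set_size, " of ", x$universe_size, ")",
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Bootstrap empirical null for a gene-set statistic
#'
#' Draws `n_boot` random gene sets of the observed size (without
#' replacement) from the universe, recomputes the statistic on each, and
#' locates the observed value in this empirical null with add-one p-values:
#' `p_high = (1 + #\{null >= observed\}) / (n_boot + 1)` (and `p_low` with
#' `<=`), so a bootstrap p-value is never zero.
#'
#' @param universe Character vector of gene ids to sample from.
#' @param set_size Size of each random set.
#' @param statistic Function taking a character vector of gene ids and
#'   returning one number.
#' @param observed The observed statistic value.
#' @param n_boot Number of bootstrap draws (default 10000).
#' @param seed Integer seed; the same seed reproduces the null exactly.
#' @return A `bootstrap_result` list: `observed`, `null_samples`, `p_low`,
#'   `p_high`, `n_boot`, `seed`.
#' @export
bootstrap_null <- function(universe, set_size, statistic, observed,
                           n_boot = 10000, seed = 1L) {
  if (set_size > length(universe)) {
    abort("`set_size` cannot exceed the universe size.")
  }
  withr::local_seed(sub_seed(seed, 41L))
  null_samples <- vapply(seq_len(n_boot), function(b) {
    draw <- sample(universe, set_size)
    val <- tryCatch(statistic(draw), error = function(e) {
      abort(paste0("statistic failed on draw ", b, ": ",
                   conditionMessage(e)))
    })
    as.numeric(val)
  }, 1.0)
  res <- list(
    observed = observed, null_samples = null_samples,
    p_low = (1 + sum(null_samples <= observed)) / (n_boot + 1),
    p_high = (1 + sum(null_samples >= observed)) / (n_boot + 1),
    n_boot = n_boot, seed = seed
  )
  class(res) <- "bootstrap_result"
  res
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> observed ", signif(x$observed, 4),
      ", p_high ", signif(x$p_high, 4), ", p_low ", signif(x$p_low, 4),
      " (", x$n_boot, " draws, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
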