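#' Per-gene expression and detection profiles across cell types
#'
#' Computes, for every gene and cell type, the median relative expression
#' (normalized to the reference tissue) and the detection frequency — the
#' inputs to candidate-cell-type assignment.
#'
#' @param bundle A compendium [expression_bundle()] whose groups are cell
#'   types plus a reference group.
#' @param reference_group Reference tissue group (default `"normal_skin"`),
#'   excluded from the cell-type profiles.
#' @return Tibble with columns `gene_id`, `cell_type`, `median_rel_expr`,
#'   `detection`.
#' @export
celltype_profiles <- function(bundle, reference_group = "normal_skin") {
  stopifnot(inherits(bundle, "expression_bundle"))
  rel <- normalize_to_reference(bundle, reference_group)
  types <- setdiff(unique(bundle$samples$group), reference_group)
  bind_rows(lapply(types, function(t) {
    ids <- group_samples(bundle, t)
    tibble(gene_id = rownames(rel),
           cell_type = t,
           median_rel_expr = apply(rel[, ids, drop = FALSE], 1, median),
           detection = rowMeans(bundle$detected[, ids, drop = FALSE]))
  }))
}

#' Assign each gene a candidate cell type
#'
#' A gene's candidate cell type is the one with the highest median relative
#' expression among *eligible* types — those where the gene is detected in
#' at least `min_detection` of samples. With no eligible type the gene is
#' `UNASSIGNED`. Ties resolve to the higher detection frequency, then
#' lexicographically by cell-type name. `eligibility = "after"` instead
#' takes the overall argmax first and unassigns it if under-detected.
#' Because the rule uses only medians and detection, it is invariant to any
#' monotone rescaling applied uniformly to all types.
#'
#' @param profiles Tibble from [celltype_profiles()] (columns `gene_id`,
#'   `cell_type`, `median_rel_expr`, `detection`).
#' @param min_detection Minimum detection frequency (default 0.10,
#'   inclusive).
#' @param eligibility `"before"` (restrict to eligible types, then argmax;
#'   default) or `"after"` (argmax first, drop if under-detected).
#' @return An `assignment_table` tibble: `gene_id`, `assigned` (cell type or
#'   `"UNASSIGNED"`), `assigned_median`, `assigned_detection`.
#' @export
assign_cell_types <- function(profiles, min_detection = 0.10,
                              eligibility = c("before", "after")) {
  eligibility <- match.arg(eligibility)
  profiles <- as_tibble(profiles)
  if (length(unique(profiles$cell_type)) < 2) {
    abort("need at least 2 cell types to assign.")
  }
  pick <- function(df) {
    df <- df[order(-df$median_rel_expr, -df$detection, df$cell_type), ]
    df[1, ]
  }
  out <- profiles |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      if (eligibility == "before") {
        elig <- df[df$detection >= min_detection, , drop = FALSE]
        if (nrow(elig) == 0) {
          return(tibble(assigned = "UNASSIGNED",
                        assigned_median = NA_real_,
                        assigned_detection = NA_real_))
        }
        top <- pick(elig)
      } else {
        top <- pick(df)
        if (top$detection < min_detection) {
          return(tibble(assigned = "UNASSIGNED",
                        assigned_median = NA_real_,
                        assigned_detection = NA_real_))
        }
      }
      tibble(assigned = top$cell_type,
             assigned_median = top$median_rel_expr,
             assigned_detection = top$detection)
    }) |>
    ungroup()
  class(out) <- c("assignment_table", class(out))
  out
}

#' Specificity of a gene's cell-type assignment
#'
#' For each assigned gene, compares its expression in the assigned cell
#' type's samples against each of the other types' samples with a two-sided
#' Wilcoxon rank-sum test and keeps the *largest* of those p-values: the
#' assignment is specific only if even the closest competitor differs.
#' q-values are Benjamini-Hochberg over the tested genes.
#'
#' @param bundle The compendium [expression_bundle()].
#' @param assignments An `assignment_table` from [assign_cell_types()].
#' @param genes Optional gene subset (default: all assigned genes).
#' @param reference_group Reference tissue group to exclude.
#' @param alpha FDR threshold for the `specific` flag (default 0.05).
#' @return Tibble `gene_id`, `assigned`, `max_p`, `q`, `specific`.
#' @export
specificity_max_p <- function(bundle, assignments, genes = NULL,
                              reference_group = "normal_skin",
                              alpha = 0.05) {
  stopifnot(inherits(bundle, "expression_bundle"))
  asn <- assignments[assignments$assigned != "UNASSIGNED", ]
  if (!is.null(genes)) asn <- asn[asn$gene_id %in% genes, ]
  types <- setdiff(unique(bundle$samples$group), reference_group)
  type_cols <- lapply(setNames(types, types),
                      function(t) group_samples(bundle, t))
  if (any(lengths(type_cols) < 2)) {
    abort("every cell type needs at least 2 samples.")
  }
  max_p <- vapply(seq_len(nrow(asn)), function(i) {
    g <- asn$gene_id[i]
    own <- bundle$values[g, type_cols[[asn$assigned[i]]]]
    others <- setdiff(types, asn$assigned[i])
    max(vapply(others, function(t) {
      suppressWarnings(
        wilcox.test(own, bundle$values[g, type_cols[[t]]])$p.value)
    }, 1.0))
  }, 1.0)
  q <- bh_fdr(max_p)
  tibble(gene_id = asn$gene_id, assigned = asn$assigned,
         max_p = max_p, q = q, specific = q < alpha)
}
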