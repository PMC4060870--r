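#' Simulate a multi-cell-type expression compendium
#'
#' Generates log2 expression for `n_celltypes` cell types plus a
#' `normal_skin` reference group, `samples_per_celltype` samples each. A
#' fraction of genes is planted as cell-type markers: a marker's mean in its
#' own type exceeds every other type (and the skin reference) by
#' `marker_log2_margin + 0.5` log2 units, so the observed cross-type median
#' gap clears the margin with high probability. One planted co-expression
#' module (size `module_size`, the first marker of the last cell type as its
#' hub) is driven by a latent factor within that cell type's samples, giving
#' downstream co-expression analysis a recoverable ground truth. Detection is
#' drawn from the same logistic link as the cohort, so weakly expressed genes
#' can be undetected everywhere.
#'
#' @param config A [synth_config()].
#' @return A list with `bundle` (an [expression_bundle()]; groups are cell
#'   type names plus `"normal_skin"`) and `truth` (list with `marker_map`, a
#'   named character vector gene -> planted type; `module_genes`;
#'   `target_gene`; `module_celltype`).
#' @export
generate_celltype_compendium <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  if (config$n_celltypes < 2) {
    abort("configuration error: `n_celltypes` must be >= 2.")
  }
  if (config$samples_per_celltype < 2) {
    abort("configuration error: `samples_per_celltype` must be >= 2.")
  }
  withr::local_seed(sub_seed(config$seed, 23L))

  ng <- config$n_genes
  types <- celltype_names(config$n_celltypes)
  groups <- c(types, "normal_skin")
  nper <- config$samples_per_celltype
  ns <- nper * length(groups)
  genes <- sprintf("g%04d", seq_len(ng))

  baseline <- runif(ng, 4, 10)
  off <- runif(ng) < config$frac_off_genes
  baseline[off] <- runif(sum(off), 0, 1)

  n_markers <- round(config$frac_marker_genes * ng)
  marker_genes <- sort(sample(genes[!off], min(n_markers, sum(!off))))
  marker_type <- rep_len(types, length(marker_genes))
  marker_map <- setNames(marker_type, marker_genes)
  mu <- matrix(baseline, ng, length(groups),
               dimnames = list(genes, groups))
  if (length(marker_genes) > 0) {
    idx <- cbind(match(marker_genes, genes), match(marker_type, groups))
    mu[idx] <- mu[idx] + config$marker_log2_margin + 0.5
  }

  sample_type <- rep(groups, each = nper)
  sample_ids <- paste0(sample_type, "_", sprintf("s%02d", rep(seq_len(nper),
                                                              length(groups))))
  values <- mu[, match(sample_type, groups), drop = FALSE] +
    matrix(rnorm(ng * ns, sd = config$noise_sd), ng, ns)
  dimnames(values) <- list(genes, sample_ids)

  # planted co-expression module: hub = first marker of the last cell type,
  # members share a latent factor within that type's samples
  module_celltype <- types[length(types)]
  hub_candidates <- marker_genes[marker_type == module_celltype]
  truth <- list(marker_map = marker_map, module_genes = character(),
                target_gene = NA_character_, module_celltype = module_celltype)
  if (length(hub_candidates) > 0 && config$module_size >= 2) {
    target_gene <- hub_candidates[1]
    pool <- setdiff(genes[!off], marker_genes)
    members <- sort(c(target_gene,
                      sample(pool, min(config$module_size - 1, length(pool)))))
    type_cols <- which(sample_type == module_celltype)
    latent <- rnorm(length(type_cols))
    values[members, type_cols] <- values[members, type_cols] +
      config$module_loading * matrix(latent, length(members),
                                     length(type_cols), byrow = TRUE)
    truth$module_genes <- members
    truth$target_gene <- target_gene
  }

  det <- draw_detection(values, config)
  bundle <- expression_bundle(
    values,
    samples = tibble(sample_id = sample_ids, group = sample_type),
    genes = tibble(gene_id = genes, probe_set_id = paste0(genes, "_at"),
                   suffix_class = "none"),
    detected = det$detected, detection_p = det$detection_p
  )
  list(bundle = bundle, truth = truth)
}
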