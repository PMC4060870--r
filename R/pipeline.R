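#' Default analysis parameters
#'
#' All thresholds in one place: detection significance 0.05, skin-expressed
#' detection fraction 0.10, fold-change thresholds 1.50 / 0.67, FDR 0.05,
#' 50 representative samples per cell type, signature size 250, knee power
#' 7, PWM match threshold 0.80 of the maximum score, background base
#' frequencies A/C/G/T = 0.30/0.20/0.20/0.30, LD threshold r-squared 0.90,
#' 10000 bootstrap draws.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(
    detection_alpha = 0.05,
    skin_expressed_fraction = 0.10,
    fc_up = 1.50, fc_down = 0.67, max_q = 0.05,
    representatives_k = 50L,
    signature_k = 250L,
    min_detection = 0.10,
    knee_power = 7,
    pwm_threshold = 0.80,
    background = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30),
    r2_threshold = 0.90,
    n_boot = 10000L
  )
}

#' Generate every pipeline input with planted ground truth
#'
#' Runs all four synthetic generators coherently: the paired cohort, the
#' cell-type compendium (with its planted co-expression module), intergenic
#' sequences adjacent to the module genes plus a random draw of other genes
#' (module-adjacent sequences are the motif-enrichment foreground), and the
#' LD-structured variant panel with its planted causal SNPs. The compendium
#' module hub doubles as the analysis target gene and the designated lead
#' SNP sits in the causal SNPs' LD block, so the full analysis has a single
#' planted SNP-motif answer to recover.
#'
#' @param config A [synth_config()].
#' @return List of class `synthetic_inputs`: `cohort`, `compendium`
#'   ([expression_bundle()]s), `sequences`, `annotation`, `pwms`,
#'   `variants`, `genotypes`, `target_gene`, `lead_snp`, `config`, and
#'   `truth` (all planted ground truth combined).
#' @export
generate_synthetic_inputs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cohort <- generate_patient_cohort(config)
  comp <- generate_celltype_compendium(config)

  genes <- cohort$bundle$genes$gene_id
  module <- comp$truth$module_genes
  withr::local_seed(sub_seed(config$seed, 43L))
  others <- sample(setdiff(genes, module),
                   max(0L, config$n_sequences - length(module)))
  adjacent <- c(module, others)[seq_len(min(config$n_sequences,
                                            length(module) + length(others)))]
  genome <- generate_genome_fixture(config, genes = adjacent,
                                    foreground_genes = module)
  variants <- generate_variants(config, genome)

  structure(list(
    cohort = cohort$bundle,
    compendium = comp$bundle,
    sequences = genome$sequences,
    annotation = genome$annotation,
    pwms = genome$pwms,
    variants = variants$variants,
    genotypes = variants$genotypes,
    target_gene = comp$truth$target_gene,
    lead_snp = variants$truth$lead_snp,
    config = config,
    truth = c(cohort$truth, comp$truth, genome$truth, variants$truth)
  ), class = "synthetic_inputs")
}

#' Run the full cellular-dissection analysis
#'
#' Executes the stages end to end: detection filtering, paired differential
#' expression with cross-study consistency, candidate-cell-type assignment
#' with Fisher enrichment of the up-regulated set, cell-type signature
#' scores per patient, the target gene's co-expression network in its
#' candidate cell type, motif enrichment of network-adjacent sequences,
#' LD expansion around the lead SNP, allele-specific motif-match
#' classification of the linked SNPs, and SNP-motif prioritization. Any
#' stage failure aborts with the stage name; completed stage outputs up to
#' that point are attached to the error condition.
#'
#' @param inputs A `synthetic_inputs` list from [generate_synthetic_inputs()]
#'   or a hand-built list with the same elements.
#' @param params Parameter list, see [default_params()].
#' @return A `dissection_result` list with elements `skin_expressed`,
#'   `degs`, `universal_up`, `universal_down`, `profiles`, `assignments`,
#'   `fisher`, `signatures`, `signature_scores`, `candidate_celltype`,
#'   `network`, `motif_counts`, `enrichment`, `ld`, `allele_effects`,
#'   `prioritized`, `manifest`.
#' @export
run_full_analysis <- function(inputs, params = default_params()) {
  required <- c("cohort", "compendium", "sequences", "annotation", "pwms",
                "variants", "genotypes", "target_gene", "lead_snp")
  missing <- setdiff(required, names(inputs))
  missing <- c(missing, required[vapply(required, function(f)
    is.null(inputs[[f]]), TRUE)])
  if (length(missing) > 0) {
    abort(paste0("configuration error: missing input(s): ",
                 paste(unique(missing), collapse = ", ")))
  }
  done <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            class = "dissection_stage_error", partial = done)
    })
  }

  done$skin_expressed <- stage("detection", {
    skin_expressed_filter(inputs$cohort, params$skin_expressed_fraction)
  })

  done$degs <- stage("differential_expression", {
    paired_de_stats(inputs$cohort, genes = done$skin_expressed) |>
      call_degs(fc_up = params$fc_up, fc_down = params$fc_down,
                max_q = params$max_q)
  })
  done$universal_up <- stage("universal_genes",
                             universal_response_genes(done$degs, "up"))
  done$universal_down <- stage("universal_genes",
                               universal_response_genes(done$degs, "down"))

  done$profiles <- stage("celltype_profiles", celltype_profiles(inputs$compendium))
  done$assignments <- stage("assignment", {
    assign_cell_types(done$profiles, min_detection = params$min_detection)
  })

  done$fisher <- stage("fisher_enrichment", {
    deg_up <- intersect(done$degs$gene_id[done$degs$direction == "up"],
                        done$assignments$gene_id)
    bg <- intersect(done$skin_expressed, done$assignments$gene_id)
    if (length(deg_up) == 0) {
      tibble(cell_type = character(), odds_ratio = numeric(), p = numeric())
    } else {
      types <- sort(unique(done$assignments$assigned))
      types <- setdiff(types, "UNASSIGNED")
      bind_rows(lapply(types, function(t) {
        fisher_assignment_enrichment(deg_up, bg, done$assignments, t)
      }))
    }
  })

  done$signatures <- stage("signatures", {
    types <- setdiff(unique(inputs$compendium$samples$group), "normal_skin")
    lapply(setNames(types, types), function(t) {
      build_signature(inputs$compendium, t, k = params$signature_k,
                      detection_threshold = params$min_detection,
                      allow_fewer = TRUE, genes = done$skin_expressed)
    })
  })
  done$signature_scores <- stage("signature_scores", {
    fc <- 2^attr(done$degs, "patient_log2fc")
    score_patients(done$signatures, fc)
  })

  done$candidate_celltype <- stage("candidate_celltype", {
    a <- done$assignments[done$assignments$gene_id == inputs$target_gene, ]
    if (nrow(a) == 0 || a$assigned == "UNASSIGNED") {
      abort(paste0("target gene ", inputs$target_gene,
                   " has no candidate cell type."))
    }
    a$assigned
  })

  done$network <- stage("coexpression", {
    type_samples <- group_samples(inputs$compendium, done$candidate_celltype)
    expr <- inputs$compendium$values[, type_samples, drop = FALSE]
    type_det <- detection_frequency(inputs$compendium, done$candidate_celltype)
    eligible <- intersect(
      done$skin_expressed,
      type_det$gene_id[type_det$frequency >= params$min_detection]
    )
    build_network(expr, inputs$target_gene,
                  eligible = union(eligible, inputs$target_gene),
                  power = params$knee_power)
  })

  done$motif_counts <- stage("motif_scan", {
    seq_gene <- setNames(inputs$annotation$gene_id, inputs$annotation$seq_id)
    fg_genes <- union(done$network$partners$gene_id, inputs$target_gene)
    type_det <- detection_frequency(inputs$compendium, done$candidate_celltype)
    expressed <- type_det$gene_id[type_det$frequency >= params$min_detection]
    fg_seqs <- names(seq_gene)[seq_gene %in% fg_genes]
    bg_seqs <- setdiff(names(seq_gene)[seq_gene %in% expressed], fg_seqs)
    use <- c(fg_seqs, bg_seqs)
    counts <- count_matches_dictionary(inputs$sequences[use], inputs$pwms,
                                       threshold_fraction = params$pwm_threshold)
    attr(counts, "foreground") <- fg_seqs
    counts
  })

  done$enrichment <- stage("motif_enrichment", {
    motif_enrichment(done$motif_counts,
                     foreground = attr(done$motif_counts, "foreground"),
                     lengths = nchar(inputs$sequences))
  })

  done$ld <- stage("ld_expansion", {
    ld_partners(inputs$genotypes, inputs$lead_snp,
                r2_threshold = params$r2_threshold)
  })

  done$allele_effects <- stage("allele_effects", {
    linked <- inputs$variants[inputs$variants$variant_id %in%
                                done$ld$variant_id, ]
    bind_rows(lapply(seq_len(nrow(linked)), function(i) {
      allele_specific_matches(inputs$sequences, linked[i, ], inputs$pwms,
                              threshold_fraction = params$pwm_threshold)
    }))
  })

  done$prioritized <- stage("prioritization", {
    prioritize_snp_motif_pairs(done$allele_effects, done$enrichment,
                               alpha = params$max_q)
  })

  done$manifest <- list(
    seed = if (!is.null(inputs$config)) inputs$config$seed else NA_integer_,
    params = params,
    package_version = as.character(utils::packageVersion("celldissect")),
    counts = list(
      skin_expressed = length(done$skin_expressed),
      deg_up = sum(done$degs$direction == "up"),
      deg_down = sum(done$degs$direction == "down"),
      universal_up = length(done$universal_up),
      universal_down = length(done$universal_down),
      assigned = sum(done$assignments$assigned != "UNASSIGNED"),
      network_size = done$network$cutoff_n,
      ld_partners = nrow(done$ld),
      effects = nrow(done$allele_effects),
      prioritized = nrow(done$prioritized)
    )
  )
  class(done) <- "dissection_result"
  done
}

#' @export
print.dissection_result <- function(x, ...) {
  cm <- x$manifest$counts
  cat("<dissection_result>\n")
  cat("  skin-expressed genes:", cm$skin_expressed, "\n")
  cat("  DEGs:", cm$deg_up, "up /", cm$deg_down, "down;",
      cm$universal_up, "universal up\n")
  cat("  candidate cell type:", x$candidate_celltype,
      "| network size:", cm$network_size, "\n")
  cat("  LD partners:", cm$ld_partners, "| prioritized SNP-motif pairs:",
      cm$prioritized, "\n")
  invisible(x)
}

#' Write every stage output of a run as plain-text files
#'
#' TSV per tabular stage, a JSON manifest of parameters/seed/row counts, a
#' JSON sidecar for the network, and BED for the motif counts' foreground.
#'
#' @param result A `dissection_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_analysis_outputs <- function(result, dir) {
  stopifnot(inherits(result, "dissection_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name))
  w(tibble(gene_id = result$skin_expressed), "skin_expressed.tsv")
  w(result$degs, "degs.tsv")
  w(tibble(gene_id = result$universal_up), "universal_up.tsv")
  w(result$assignments, "assignments.tsv")
  w(result$fisher, "fisher_enrichment.tsv")
  w(bind_rows(result$signatures), "signatures.tsv")
  w(result$signature_scores, "signature_scores.tsv")
  w(mutate(result$network$partners, rank = row_number()), "network.tsv")
  jsonlite::write_json(
    list(target = result$network$target, cutoff_n = result$network$cutoff_n,
         power = result$network$power),
    file.path(dir, "network_params.json"), auto_unbox = TRUE)
  w(result$motif_counts, "motif_counts.tsv")
  w(result$enrichment, "motif_enrichment.tsv")
  w(result$ld, "ld_partners.tsv")
  w(result$allele_effects, "allele_effects.tsv")
  w(result$prioritized, "prioritized_snp_motif_pairs.tsv")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
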