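#' Simulate a paired lesional/uninvolved patient cohort
#'
#' Generates a gene-by-sample log2 expression matrix for `n_patients`
#' patients, each contributing one lesional (PP) and one uninvolved (PN)
#' biopsy, partitioned among `n_studies` study batches. A fraction of genes
#' is planted as differentially expressed: up-genes gain `planted_log2fc`
#' log2 units in PP, down-genes lose it; all other genes have expected paired
#' difference zero. Per-gene baselines, a shared within-pair patient effect
#' and a gene-by-study batch effect (both of which cancel in the paired
#' difference) make the cohort realistic without breaking the planted
#' contrasts. Detection calls are drawn from a logistic link on expression:
#' `Pr(detected) = plogis(detection_slope * (expr - detection_midpoint))`.
#'
#' @param config A [synth_config()].
#' @return A list with elements `bundle` (an [expression_bundle()]) and
#'   `truth` (list with `deg_up`, `deg_down` gene-id character vectors and
#'   `planted_log2fc`).
#' @export
generate_patient_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  withr::local_seed(sub_seed(config$seed, 11L))

  ng <- config$n_genes
  np <- config$n_patients
  genes <- sprintf("g%04d", seq_len(ng))
  patients <- sprintf("pt%03d", seq_len(np))
  studies <- sprintf("study_%d", rep_len(seq_len(config$n_studies), np))

  n_up <- round(config$frac_deg_up * ng)
  n_down <- round(config$frac_deg_down * ng)
  planted <- sample(genes, n_up + n_down)
  deg_up <- sort(head(planted, n_up))
  deg_down <- sort(tail(planted, n_down))
  delta <- setNames(numeric(ng), genes)
  delta[deg_up] <- config$planted_log2fc
  delta[deg_down] <- -config$planted_log2fc

  baseline <- runif(ng, 4, 10)
  off <- runif(ng) < config$frac_off_genes
  baseline[off] <- runif(sum(off), 0, 1)
  batch_sd <- config$noise_sd / 2
  batch <- matrix(rnorm(ng * config$n_studies, sd = batch_sd),
                  ng, config$n_studies)
  patient_effect <- matrix(rnorm(ng * np, sd = config$noise_sd), ng, np)

  study_idx <- as.integer(factor(studies, levels = unique(studies)))
  shared <- baseline + batch[, study_idx, drop = FALSE] + patient_effect
  pn <- shared + matrix(rnorm(ng * np, sd = config$noise_sd), ng, np)
  pp <- shared + delta + matrix(rnorm(ng * np, sd = config$noise_sd), ng, np)

  values <- cbind(pp, pn)
  sample_ids <- c(paste0(patients, "_PP"), paste0(patients, "_PN"))
  dimnames(values) <- list(genes, sample_ids)
  samples <- tibble(
    sample_id = sample_ids,
    group = rep(c("PP", "PN"), each = np),
    patient_id = rep(patients, 2),
    study_id = rep(studies, 2)
  )

  det <- draw_detection(values, config)
  bundle <- expression_bundle(values, samples,
                              genes = tibble(gene_id = genes,
                                             probe_set_id = paste0(genes, "_at"),
                                             suffix_class = "none"),
                              detected = det$detected,
                              detection_p = det$detection_p)
  list(bundle = bundle,
       truth = list(deg_up = deg_up, deg_down = deg_down,
                    planted_log2fc = config$planted_log2fc))
}

# internal: detection flags + consistent pseudo p-values from the logistic link
draw_detection <- function(values, config, alpha = 0.05) {
  pr <- plogis(config$detection_slope * (values - config$detection_midpoint))
  detected <- matrix(runif(length(values)) < pr, nrow(values), ncol(values),
                     dimnames = dimnames(values))
  u <- matrix(runif(length(values)), nrow(values), ncol(values))
  detection_p <- ifelse(detected, u * alpha, alpha + u * (1 - alpha))
  dimnames(detection_p) <- dimnames(values)
  list(detected = detected, detection_p = detection_p)
}

#' Simulate paired perfect-match/mismatch probe intensities
#'
#' Emulates probe-level data for detection-call testing: each probe set has
#' `n_pairs` perfect-match (PM) / mismatch (MM) probe pairs. MM probes carry
#' background noise only; PM probes add `signal` on top for expressed probe
#' sets, and are exchangeable with MM for unexpressed ones (the null).
#'
#' @param n_probe_sets Number of probe sets to simulate.
#' @param n_pairs Probe pairs per probe set (platform convention: 11).
#' @param signal Mean PM excess over MM for expressed probe sets; 0 gives the
#'   exchangeable null.
#' @param noise_sd Intensity noise standard deviation.
#' @param seed Integer seed.
#' @return List of matrices `pm` and `mm`, probe sets x pairs.
#' @export
simulate_probe_pairs <- function(n_probe_sets, n_pairs = 11L, signal = 0,
                                 noise_sd = 1, seed = 1L) {
  stopifnot(n_probe_sets > 0, n_pairs > 0)
  withr::local_seed(sub_seed(seed, 17L))
  background <- matrix(rnorm(n_probe_sets * n_pairs, mean = 6, sd = noise_sd),
                       n_probe_sets, n_pairs)
  mm <- background + matrix(rnorm(n_probe_sets * n_pairs, sd = noise_sd),
                            n_probe_sets, n_pairs)
  pm <- background + signal +
    matrix(rnorm(n_probe_sets * n_pairs, sd = noise_sd), n_probe_sets, n_pairs)
  list(pm = pm, mm = mm)
}
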