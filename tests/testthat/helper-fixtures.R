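# small, fast configurations and hand-built bundles used across test files

small_config <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 200L, n_patients = 20L, n_studies = 2L,
                   samples_per_celltype = 10L, n_sequences = 40L,
                   seq_length = 300L, n_pwms = 6L, n_snps = 20L,
                   n_individuals = 60L, module_size = 10L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, c(list(seed = seed), args))
}

# a tiny bundle built by hand: genes x samples with explicit detection
make_bundle <- function(values, groups, patient = NULL, study = NULL,
                        detected = NULL) {
  samples <- tibble::tibble(
    sample_id = colnames(values), group = groups,
    patient_id = patient %||% colnames(values),
    study_id = study %||% "study_1"
  )
  expression_bundle(values, samples, detected = detected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force BH step-up oracle (spec formula, capped at 1)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, 1.0)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# independent naive PWM window scorer: per-window cbind lookup, both strands
naive_scan <- function(seq, pwm, threshold_fraction = 0.80) {
  chars <- strsplit(seq, "")[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  L <- pwm$length
  n <- length(code)
  if (n < L) {
    return(tibble::tibble(start = integer(), strand = character(),
                          score = numeric()))
  }
  lo_f <- pwm$logodds
  lo_r <- pwm_revcomp(pwm)$logodds
  thr <- threshold_fraction * pwm$max_score
  out <- list()
  for (o in 0:(n - L)) {
    w <- code[(o + 1):(o + L)]
    if (any(is.na(w))) next
    sf <- sum(lo_f[cbind(w, seq_len(L))])
    sr <- sum(lo_r[cbind(w, seq_len(L))])
    if (sf >= thr) out[[length(out) + 1]] <-
        tibble::tibble(start = o, strand = "+", score = sf)
    if (sr >= thr) out[[length(out) + 1]] <-
        tibble::tibble(start = o, strand = "-", score = sr)
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), strand = character(),
                          score = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), start, strand)
}

random_pwm <- function(len, id = "rpwm", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(5, 4, len, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(sample(4, len, replace = TRUE), seq_len(len))] <- 85
  pwm(counts, id = id)
}

random_dna <- function(n, prob = c(0.30, 0.20, 0.20, 0.30)) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
         collapse = "")
}
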