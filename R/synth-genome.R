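#' Simulate intergenic sequences with planted motif occurrences
#'
#' Draws `n_sequences` intergenic sequences (background base frequencies
#' A/C/G/T = 0.30/0.20/0.20/0.30; lengths uniform in 0.5-1.5 x `seq_length`),
#' each adjacent to one gene, and plants consensus occurrences of a random
#' PWM dictionary at `planted_motif_rate` per kb on random strands without
#' overlap. The first motif of the dictionary acts as the causal motif: its
#' planting rate is multiplied by `fg_motif_boost` within foreground
#' sequences (those adjacent to `foreground_genes`), which is what downstream
#' motif enrichment is expected to detect. A few deliberately broken (single
#' mismatch, below match threshold) causal-motif occurrences are also planted
#' and recorded so the variant generator can build engender-type causal SNPs.
#' Occasional short `N` runs and soft-masked (lower-case) stretches exercise
#' the scanner's masking rules.
#'
#' @param config A [synth_config()].
#' @param genes Character vector of adjacent gene ids, one per sequence
#'   (recycled/truncated to `n_sequences`). Default `g0001...`.
#' @param foreground_genes Genes whose adjacent sequences are flagged
#'   foreground (default none).
#' @param threshold_fraction Match threshold used to verify planted and
#'   broken occurrences (default 0.80).
#' @return List with `sequences` (named character vector), `annotation`
#'   (tibble `seq_id`, `start`, `end`, `gene_id`), `pwms` (list of [pwm()]),
#'   and `truth` (list: `planted_matches` tibble with 0-based half-open
#'   coordinates, `broken_matches` tibble, `foreground` sequence ids,
#'   `causal_motif`).
#' @export
generate_genome_fixture <- function(config, genes = NULL,
                                    foreground_genes = character(),
                                    threshold_fraction = 0.80) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  pwms <- generate_pwm_dictionary(config$n_pwms, config$pwm_length,
                                  seed = config$seed)
  causal_motif <- names(pwms)[1]
  withr::local_seed(sub_seed(config$seed, 31L))

  n <- config$n_sequences
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(n))
  genes <- rep_len(genes, n)
  seq_ids <- sprintf("seq_%04d", seq_len(n))
  lens <- pmax(4L * config$pwm_length,
               as.integer(round(runif(n, 0.5, 1.5) * config$seq_length)))
  fg <- seq_ids[genes %in% foreground_genes]
  bases <- names(DEFAULT_BACKGROUND)

  planted <- list()
  broken <- list()
  sequences <- setNames(character(n), seq_ids)

  for (i in seq_len(n)) {
    chars <- sample(bases, lens[i], replace = TRUE, prob = DEFAULT_BACKGROUND)
    occupied <- integer(0)   # positions already used by a planted feature
    place <- function(width) {
      for (try in 1:50) {
        start <- sample.int(lens[i] - width + 1L, 1L) - 1L  # 0-based
        span <- (start + 1L):(start + width)
        if (!any(span %in% occupied)) return(start)
      }
      NA_integer_
    }
    for (m in names(pwms)) {
      rate <- config$planted_motif_rate * lens[i] / 1000
      if (m == causal_motif && seq_ids[i] %in% fg) {
        rate <- rate * config$fg_motif_boost
      }
      n_occ <- rpois(1, rate)
      if (n_occ == 0) next
      cons <- strsplit(pwm_consensus(pwms[[m]]), "")[[1]]
      for (k in seq_len(n_occ)) {
        start <- place(length(cons))
        if (is.na(start)) next
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") cons else rev_comp_chars(cons)
        chars[(start + 1L):(start + length(cons))] <- ins
        occupied <- c(occupied, (start + 1L):(start + length(cons)))
        planted[[length(planted) + 1L]] <-
          tibble(seq_id = seq_ids[i], start = start,
                 end = start + length(cons), motif_id = m, strand = strand)
      }
    }
    # occasional masking features, kept clear of planted occurrences
    if (runif(1) < 0.2) {
      s <- place(10L)
      if (!is.na(s)) {
        chars[(s + 1L):(s + 10L)] <- "N"
        occupied <- c(occupied, (s + 1L):(s + 10L))
      }
    }
    if (runif(1) < 0.2) {
      s <- place(15L)
      if (!is.na(s)) {
        chars[(s + 1L):(s + 15L)] <- tolower(chars[(s + 1L):(s + 15L)])
        occupied <- c(occupied, (s + 1L):(s + 15L))
      }
    }
    sequences[i] <- paste0(chars, collapse = "")
  }

  # broken causal-motif occurrences: consensus with one low-information-column
  # substitution, verified to fall below the match threshold
  target_seqs <- if (length(fg) > 0) fg else seq_ids
  cpwm <- pwms[[causal_motif]]
  cons <- strsplit(pwm_consensus(cpwm), "")[[1]]
  planted_tbl <- if (length(planted)) bind_rows(planted) else NULL
  n_broken <- min(3L, length(target_seqs))
  for (b in seq_len(n_broken)) {
    sid <- target_seqs[1L + (b - 1L) %% length(target_seqs)]
    chars <- strsplit(sequences[[sid]], "")[[1]]
    len <- length(chars)
    taken <- if (is.null(planted_tbl)) integer(0) else {
      pt <- planted_tbl[planted_tbl$seq_id == sid, ]
      unlist(purrr::map2(pt$start, pt$end, function(s, e) (s + 1L):e))
    }
    ok <- FALSE
    for (try in 1:50) {
      start <- sample.int(len - length(cons) + 1L, 1L) - 1L
      span <- (start + 1L):(start + length(cons))
      if (any(span %in% taken)) next
      if (any(chars[span] %in% c("N")) || any(chars[span] != toupper(chars[span]))) next
      col <- sample.int(length(cons), 1L)
      alt_bases <- setdiff(bases, cons[col])
      alt <- alt_bases[which.min(cpwm$logodds[alt_bases, col])]
      cand <- cons
      cand[col] <- alt
      window <- paste0(cand, collapse = "")
      frac <- best_fraction(window, cpwm)
      if (is.na(frac) || frac >= threshold_fraction) next
      chars[span] <- cand
      sequences[sid] <- paste0(chars, collapse = "")
      broken[[length(broken) + 1L]] <-
        tibble(seq_id = sid, start = start, end = start + length(cons),
               motif_id = causal_motif, strand = "+",
               broken_col = col, broken_base = alt, consensus_base = cons[col])
      ok <- TRUE
      break
    }
    if (!ok) next
  }

  empty_pm <- tibble(seq_id = character(), start = integer(), end = integer(),
                     motif_id = character(), strand = character())
  list(
    sequences = sequences,
    annotation = tibble(seq_id = seq_ids, start = 0L, end = lens,
                        gene_id = genes),
    pwms = pwms,
    truth = list(
      planted_matches = if (length(planted)) bind_rows(planted) else empty_pm,
      broken_matches = if (length(broken)) bind_rows(broken) else
        tibble(seq_id = character(), start = integer(), end = integer(),
               motif_id = character(), strand = character(),
               broken_col = integer(), broken_base = character(),
               consensus_base = character()),
      foreground = fg,
      causal_motif = causal_motif
    )
  )
}

# internal: complement of a character vector of bases, reversed
rev_comp_chars <- function(chars) {
  rev(chartr("ACGT", "TGCA", chars))
}

# internal: best score fraction over all windows and both strands, without
# any thresholding (log-odds fractions can be negative)
best_fraction <- function(window_seq, pwm, score_scale = "logodds",
                          details = FALSE) {
  code <- encode_dna(window_seq)
  bounds_f <- score_bounds(pwm, score_scale)
  bounds_r <- score_bounds(pwm_revcomp(pwm), score_scale)
  sf <- score_windows(code, bounds_f$lo)
  sr <- score_windows(code, bounds_r$lo)
  all_scores <- c(sf, sr)
  strands <- c(rep("+", length(sf)), rep("-", length(sr)))
  offsets <- c(seq_along(sf), seq_along(sr)) - 1L
  if (all(is.na(all_scores)) || length(all_scores) == 0) {
    if (details) return(list(fraction = NA_real_, strand = NA_character_,
                             offset = NA_integer_))
    return(NA_real_)
  }
  best <- which.max(all_scores)
  frac <- score_fraction_of(all_scores[best], bounds_f, score_scale)
  if (details) {
    return(list(fraction = frac, strand = strands[best],
                offset = offsets[best]))
  }
  frac
}
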