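#' @name scanning
#' @title PWM scanning of nucleotide sequences
#'
#' @description
#' `scan_sequence()` slides a PWM over every offset of a sequence on both
#' strands, scores each window as a log2-odds sum against the background, and
#' reports windows whose score reaches `threshold_fraction` of the motif's
#' maximum achievable score. Windows containing `N` or soft-masked
#' (lower-case) bases are skipped. Reverse-strand matches are found by
#' scanning with the reverse-complement PWM and are reported in forward
#' coordinates (0-based, half-open). Overlapping matches of the same motif
#' are merged strand-agnostically into one counted interval, so a site
#' matched on both strands is never double-counted.
NULL

# internal: encode A/C/G/T -> 1..4; N and lower-case (masked) -> NA
encode_dna <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !chars %in% c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")
  if (any(bad)) {
    abort(paste0("invalid sequence character(s): ",
                 paste(unique(chars[bad]), collapse = ", ")))
  }
  match(chars, c("A", "C", "G", "T"))
}

# internal: log-odds score at every window start; NA where window is masked
score_windows <- function(code, lo) {
  n <- length(code)
  L <- ncol(lo)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  s <- numeric(nw)
  for (j in seq_len(L)) {
    s <- s + unname(lo[, j][code[j:(j + nw - 1L)]])
  }
  s
}

# internal: score bounds on the requested scale
score_bounds <- function(pwm, score_scale) {
  if (score_scale == "logodds") {
    list(lo = pwm$logodds, max = pwm$max_score, min = pwm$min_score)
  } else {
    lp <- log2(pwm$prob)
    list(lo = lp, max = accumulate_cols(lp, max), min = accumulate_cols(lp, min))
  }
}

# internal: fraction of the maximum achievable score
score_fraction_of <- function(score, bounds, score_scale) {
  if (score_scale == "logodds") score / bounds$max
  else (score - bounds$min) / (bounds$max - bounds$min)
}

#' Scan one sequence with one PWM
#'
#' @param seq Character scalar over A/C/G/T/N (lower-case = masked).
#' @param pwm A [pwm()].
#' @param threshold_fraction Report windows scoring at least this fraction of
#'   the maximum achievable score (default 0.80).
#' @param score_scale `"logodds"` (default; fraction = score / max log-odds)
#'   or `"prob"` (fraction of the min-max range of summed log-probabilities,
#'   the convention of probability-scale matchers).
#' @param merge Merge overlapping matches of this motif into single counted
#'   intervals (default `TRUE`).
#' @param seq_id Optional sequence id carried into the result.
#' @return Tibble with columns `seq_id`, `motif_id`, `start`, `end` (0-based,
#'   half-open, forward coordinates), `strand`, `score`, `score_fraction`.
#'   When `merge = TRUE` an interval spans all overlapping raw matches and
#'   carries the best raw score/strand.
#' @export
scan_sequence <- function(seq, pwm, threshold_fraction = 0.80,
                          score_scale = c("logodds", "prob"),
                          merge = TRUE, seq_id = NA_character_) {
  stopifnot(inherits(pwm, "pwm"), is.character(seq), length(seq) == 1)
  score_scale <- match.arg(score_scale)
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    abort("`threshold_fraction` must be in (0, 1].")
  }
  code <- encode_dna(seq)
  L <- pwm$length
  empty <- tibble(seq_id = character(), motif_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = numeric(), score_fraction = numeric())
  if (length(code) < L) return(empty)

  bounds_f <- score_bounds(pwm, score_scale)
  bounds_r <- score_bounds(pwm_revcomp(pwm), score_scale)
  sf <- score_windows(code, bounds_f$lo)
  sr <- score_windows(code, bounds_r$lo)
  thr <- if (score_scale == "logodds") {
    threshold_fraction * bounds_f$max
  } else {
    bounds_f$min + threshold_fraction * (bounds_f$max - bounds_f$min)
  }

  hits <- function(s, strand) {
    keep <- which(!is.na(s) & s >= thr)
    if (length(keep) == 0) return(NULL)
    tibble(seq_id = seq_id, motif_id = pwm$id,
           start = keep - 1L, end = keep - 1L + L, strand = strand,
           score = s[keep],
           score_fraction = score_fraction_of(s[keep], bounds_f, score_scale))
  }
  out <- bind_rows(hits(sf, "+"), hits(sr, "-"))
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- arrange(out, .data$start, .data$strand)
  if (merge) out <- merge_matches(out)
  out
}

#' Merge overlapping matches of the same motif
#'
#' Strand-agnostic: a merged interval counts once regardless of the strands
#' involved; it spans the union of the overlapping raw matches and keeps the
#' best raw score, its strand and its fraction. Idempotent.
#'
#' @param matches Tibble as returned by [scan_sequence()] (one motif per
#'   `motif_id`/`seq_id` combination is merged independently).
#' @return Tibble with the same columns, merged intervals.
#' @export
merge_matches <- function(matches) {
  if (nrow(matches) == 0) return(matches)
  parts <- split(matches,
                 paste(matches$seq_id, matches$motif_id, sep = "\r"))
  merged <- lapply(parts, function(m) {
    ir <- IRanges::IRanges(start = m$start + 1L, end = m$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    best <- vapply(revmap, function(idx) idx[which.max(m$score[idx])], 1L)
    tibble(seq_id = m$seq_id[best], motif_id = m$motif_id[best],
           start = IRanges::start(red) - 1L, end = IRanges::end(red),
           strand = m$strand[best], score = m$score[best],
           score_fraction = m$score_fraction[best])
  })
  arrange(bind_rows(merged), .data$seq_id, .data$motif_id, .data$start)
}

#' Count merged PWM matches per sequence
#'
#' @param sequences Named character vector of sequences.
#' @param pwm A [pwm()].
#' @inheritParams scan_sequence
#' @return Tibble with columns `seq_id`, `motif_id`, `count`.
#' @export
count_matches <- function(sequences, pwm, threshold_fraction = 0.80,
                          score_scale = c("logodds", "prob")) {
  score_scale <- match.arg(score_scale)
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq_%04d", seq_along(sequences))
  }
  codes <- lapply(sequences, encode_dna)
  tibble(seq_id = names(sequences), motif_id = pwm$id,
         count = unname(count_codes(codes, pwm, threshold_fraction,
                                    score_scale)))
}

# internal: merged match counts from pre-encoded sequences; all raw matches
# share width L, so sorted hit starts merge exactly when gaps are < L
count_codes <- function(codes, pwm, threshold_fraction, score_scale) {
  bf <- score_bounds(pwm, score_scale)
  br <- score_bounds(pwm_revcomp(pwm), score_scale)
  thr <- if (score_scale == "logodds") {
    threshold_fraction * bf$max
  } else {
    bf$min + threshold_fraction * (bf$max - bf$min)
  }
  L <- pwm$length
  vapply(codes, function(code) {
    if (length(code) < L) return(0L)
    sf <- score_windows(code, bf$lo)
    sr <- score_windows(code, br$lo)
    hits <- which((!is.na(sf) & sf >= thr) | (!is.na(sr) & sr >= thr))
    if (length(hits) == 0) return(0L)
    1L + sum(diff(hits) >= L)
  }, 1L)
}
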