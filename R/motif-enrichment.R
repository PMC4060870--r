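#' Motif enrichment in foreground versus background sequences
#'
#' For each motif, fits a semiparametric generalized additive logistic model
#' of foreground membership on the per-sequence match count, with a
#' penalized cubic-spline smooth on log10 sequence length absorbing the
#' count-versus-length confound (optionally also a smooth on GC content).
#' The enrichment statistic is the Wald z of the count coefficient; positive
#' z means the motif is over-represented in foreground sequences. When the
#' length covariate has too few distinct values to support a smooth (under
#' 10), the model reduces to plain logistic regression. Motifs absent from
#' every sequence are reported as degenerate (z = 0, p = 1). q-values are
#' Benjamini-Hochberg over the tested motifs.
#'
#' @param counts Tibble with columns `seq_id`, `motif_id`, `count` (merged
#'   match counts, e.g. from [count_matches()] over the dictionary).
#' @param foreground Character vector of foreground sequence ids; all other
#'   ids in `counts` form the background. Foreground and background must
#'   both be non-empty.
#' @param lengths Named numeric vector of sequence lengths (bases).
#' @param gc Optional named numeric vector of GC fractions.
#' @return A `motif_enrichment` tibble: `motif_id`, `z`, `p`, `q`,
#'   `fg_count`, `bg_count`, `model`, `degenerate`.
#' @export
motif_enrichment <- function(counts, foreground, lengths, gc = NULL) {
  counts <- as_tibble(counts)
  seq_ids <- unique(counts$seq_id)
  fg <- intersect(seq_ids, foreground)
  bg <- setdiff(seq_ids, foreground)
  if (length(fg) == 0 || length(bg) == 0) {
    abort("need non-empty, disjoint foreground and background sequence sets.")
  }
  if (!all(seq_ids %in% names(lengths))) {
    abort("`lengths` must name every sequence in `counts`.")
  }

  per_motif <- split(counts, counts$motif_id)
  rows <- lapply(per_motif, function(m) {
    m <- m[match(seq_ids, m$seq_id), ]
    y <- as.integer(seq_ids %in% fg)
    cnt <- ifelse(is.na(m$count), 0L, m$count)
    fg_count <- sum(cnt[y == 1])
    bg_count <- sum(cnt[y == 0])
    if (all(cnt == cnt[1])) {
      return(tibble(motif_id = m$motif_id[!is.na(m$motif_id)][1],
                    z = 0, p = 1, fg_count = fg_count, bg_count = bg_count,
                    model = "degenerate", degenerate = TRUE))
    }
    log_len <- log10(lengths[seq_ids])
    dat <- data.frame(y = y, count = cnt, log_len = log_len)
    use_smooth <- length(unique(log_len)) >= 10
    if (!is.null(gc)) dat$gc <- gc[seq_ids]
    fit <- tryCatch(suppressWarnings({
      if (use_smooth) {
        form <- if (is.null(gc)) y ~ count + s(log_len, bs = "cr")
                else y ~ count + s(log_len, bs = "cr") + s(gc, bs = "cr")
        mgcv::gam(form, family = binomial(), data = dat)
      } else {
        glm(y ~ count, family = binomial(), data = dat)
      }
    }), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(motif_id = m$motif_id[!is.na(m$motif_id)][1],
                    z = 0, p = 1, fg_count = fg_count, bg_count = bg_count,
                    model = "failed", degenerate = TRUE))
    }
    sm <- summary(fit)
    ptab <- if (inherits(fit, "gam")) sm$p.table else coef(sm)
    z <- ptab["count", if (inherits(fit, "gam")) "z value" else "z value"]
    p <- 2 * stats::pnorm(-abs(z))
    tibble(motif_id = m$motif_id[!is.na(m$motif_id)][1],
           z = unname(z), p = unname(p),
           fg_count = fg_count, bg_count = bg_count,
           model = if (inherits(fit, "gam")) "gam_logistic" else "glm_logistic",
           degenerate = FALSE)
  })
  out <- bind_rows(rows)
  out <- mutate(out, q = bh_fdr(.data$p), .after = "p")
  out <- arrange(out, desc(.data$z))
  class(out) <- c("motif_enrichment", class(out))
  out
}

#' Count matches of a whole PWM dictionary over a sequence set
#'
#' Convenience wrapper: [count_matches()] for every motif, row-bound.
#'
#' @param sequences Named character vector.
#' @param pwms List of [pwm()] objects.
#' @inheritParams scan_sequence
#' @return Tibble `seq_id`, `motif_id`, `count`.
#' @export
count_matches_dictionary <- function(sequences, pwms,
                                     threshold_fraction = 0.80,
                                     score_scale = c("logodds", "prob")) {
  score_scale <- match.arg(score_scale)
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq_%04d", seq_along(sequences))
  }
  codes <- lapply(sequences, encode_dna)
  bind_rows(lapply(pwms, function(p) {
    tibble(seq_id = names(sequences), motif_id = p$id,
           count = unname(count_codes(codes, p, threshold_fraction,
                                      score_scale)))
  }))
}
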