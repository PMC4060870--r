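#' Position weight matrix with log-odds scoring parameters
#'
#' Builds a PWM from a 4 x L count (or probability) matrix with rows A, C, G,
#' T. Columns are converted to probabilities with a small pseudocount spread
#' according to the background base frequencies, and scored as log2 odds
#' against that background. `max_score` is the sum over columns of the best
#' per-column log-odds, so a window can never exceed it; match thresholds are
#' expressed as a fraction of `max_score`.
#'
#' @param counts Numeric 4 x L matrix; rows must be (or be named) A, C, G, T.
#' @param id Motif identifier.
#' @param source Free-text provenance tag (default "synthetic").
#' @param pseudocount Total pseudocount per column, distributed across bases
#'   proportionally to `background` (default 0.01).
#' @param background Named base frequencies; default intergenic
#'   A/C/G/T = 0.30/0.20/0.20/0.30.
#' @return An object of class `pwm` with elements `id`, `source`, `prob`,
#'   `logodds`, `max_score`, `min_score`, `length`, `background`,
#'   `pseudocount`.
#' @export
pwm <- function(counts, id, source = "synthetic", pseudocount = 0.01,
                background = DEFAULT_BACKGROUND) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("`counts` must have 4 rows (A, C, G, T).")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(counts < 0) || ncol(counts) < 1) {
    abort("`counts` must be non-negative with at least one column.")
  }
  bg <- background[c("A", "C", "G", "T")]
  if (any(is.na(bg)) || abs(sum(bg) - 1) > 1e-8) {
    abort("`background` must be named A/C/G/T frequencies summing to 1.")
  }
  prob <- sweep(counts + pseudocount * bg, 2, colSums(counts) + pseudocount, "/")
  logodds <- log2(prob / bg)
  structure(
    list(id = id, source = source, prob = prob, logodds = logodds,
         max_score = accumulate_cols(logodds, max),
         min_score = accumulate_cols(logodds, min),
         length = ncol(prob), background = bg, pseudocount = pseudocount),
    class = "pwm"
  )
}

# internal: column-wise extreme summed with the same left-to-right double
# accumulation the scanner uses, so a perfect window reaches the bound exactly
accumulate_cols <- function(m, f) {
  acc <- 0
  for (j in seq_len(ncol(m))) acc <- acc + f(m[, j])
  acc
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$id, " (", x$source, "), width ", x$length,
      ", consensus ", pwm_consensus(x),
      ", max log-odds ", round(x$max_score, 2), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per column)
#'
#' Ties resolve to the first base in A < C < G < T order.
#' @param x A [pwm()].
#' @return Character scalar of length `x$length`.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste0(c("A", "C", "G", "T")[apply(x$prob, 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#'
#' Scoring a sequence with the reverse-complement PWM at a forward offset is
#' equivalent to scoring the original PWM on the minus strand of that window.
#' @param x A [pwm()].
#' @return A [pwm()] (same id, columns reversed, bases complemented).
#' @export
pwm_revcomp <- function(x) {
  stopifnot(inherits(x, "pwm"))
  swap <- function(m) {
    m <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
    rownames(m) <- c("A", "C", "G", "T")
    m
  }
  out <- x
  out$prob <- swap(x$prob)
  out$logodds <- swap(x$logodds)
  out
}

#' Generate a dictionary of sharp random PWMs
#'
#' Each column has one dominant base (count 85) with the rest split evenly
#' (count 5 each), giving well-defined consensus sequences that occur rarely
#' by chance but are recovered reliably when planted.
#'
#' @param n_pwms,pwm_length Dictionary size and motif width.
#' @param seed Integer seed.
#' @param prefix Motif id prefix.
#' @return List of [pwm()] objects named by motif id.
#' @export
generate_pwm_dictionary <- function(n_pwms, pwm_length, seed = 1L,
                                    prefix = "motif") {
  stopifnot(n_pwms > 0, pwm_length > 0)
  withr::local_seed(sub_seed(seed, 29L))
  lapply(setNames(seq_len(n_pwms),
                  sprintf("%s_%02d", prefix, seq_len(n_pwms))), function(i) {
    dominant <- sample(4, pwm_length, replace = TRUE)
    counts <- matrix(5, 4, pwm_length,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[cbind(dominant, seq_len(pwm_length))] <- 85
    pwm(counts, id = sprintf("%s_%02d", prefix, i))
  })
}
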