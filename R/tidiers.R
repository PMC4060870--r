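#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects: `tidy()` returns
#' one row per element (gene, rank, draw), `glance()` one row per fit.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.gsea_result <- function(x, ...) {
  tibble(rank = seq_along(x$curve),
         overlap_fraction = x$curve,
         diagonal = seq_along(x$curve) / x$universe_size)
}

#' @rdname tidiers
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(area = x$area, p = x$p, set_size = x$set_size,
         universe_size = x$universe_size, degenerate = x$degenerate)
}

#' @rdname tidiers
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble(draw = seq_along(x$null_samples), statistic = x$null_samples)
}

#' @rdname tidiers
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble(observed = x$observed, p_low = x$p_low, p_high = x$p_high,
         n_boot = x$n_boot, seed = x$seed)
}

#' @rdname tidiers
#' @export
tidy.coexpression_network <- function(x, ...) {
  mutate(x$ranking, rank = row_number(),
         in_network = row_number() <= x$cutoff_n)
}

#' @rdname tidiers
#' @export
glance.coexpression_network <- function(x, ...) {
  tibble(target = x$target, cutoff_n = x$cutoff_n,
         n_positive = nrow(x$ranking), power = x$power, empty = x$empty)
}

#' @rdname tidiers
#' @export
tidy.hc_result <- function(x, ...) {
  h <- x$hclust
  tibble(step = seq_len(nrow(h$merge)),
         left = h$merge[, 1], right = h$merge[, 2], height = h$height)
}
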