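#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the main result types: the cumulative
#' overlap curve of an area statistic, the knee of a co-expression ranking,
#' the enrichment z profile of a motif dictionary, and a patient-by-cell-type
#' signature score tile map.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank / nrow(df))) +
    ggplot2::geom_line(ggplot2::aes(y = .data$overlap_fraction),
                       colour = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "rank fraction", y = "cumulative overlap",
                  title = sprintf("area = %.3f, p = %.2g",
                                  object$area, object$p)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.coexpression_network <- function(object, ...) {
  df <- tidy(object)
  m <- nrow(df)
  df$y <- df$r_s^object$power / df$r_s[1]^object$power
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank / m, y = .data$y,
                                   colour = .data$in_network)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$cutoff_n / m, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "rank fraction",
                  y = sprintf("r_s^%d (normalized)", object$power),
                  title = sprintf("%s: N = %d", object$target,
                                  object$cutoff_n)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  df <- mutate(as_tibble(object),
               motif_id = factor(.data$motif_id,
                                 levels = rev(.data$motif_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$motif_id,
                                   fill = .data$q < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey60"),
                               name = "FDR < 0.05") +
    ggplot2::labs(x = "enrichment z", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.signature_scores <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$cell_type, y = .data$patient_id,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
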