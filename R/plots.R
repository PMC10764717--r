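#' Dot plot of ordered KS bit scores
#'
#' The classic presentation of the score continuum: sequences on the x-axis
#' ordered by decreasing FAS-model bit score, the three model scores on the
#' y-axis, the AFPK band shaded.
#'
#' @param dotplot A table from [dotplot_table()].
#' @param config The [classifier_config()] whose band to shade (optional).
#' @return A ggplot object.
#' @export
plot_dotplot <- function(dotplot, config = NULL) {
  need <- c("rank", "fas_bits", "pks_bits", "fasii_bits")
  if (!is.data.frame(dotplot) || !all(need %in% names(dotplot))) {
    abort("`dotplot` must be a table from dotplot_table().")
  }
  long <- tidyr::pivot_longer(dotplot,
                              cols = c("fas_bits", "pks_bits", "fasii_bits"),
                              names_to = "model", values_to = "bits")
  long$model <- factor(long$model, levels = c("fas_bits", "pks_bits", "fasii_bits"),
                       labels = c("FAS", "PKS", "FASII"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$bits,
                                          colour = .data$model)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "sequence rank (by FAS score)", y = "bit score",
                  colour = "model") +
    ggplot2::theme_minimal()
  if (!is.null(config)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = config$band_low, ymax = config$band_high,
                               alpha = 0.15, fill = "goldenrod")
  }
  p
}

#' Scatter plot of an embedding
#'
#' Coloured by cluster (if a `cluster` column is present) or by a `clade`
#' column joined from `reference`.
#'
#' @param object A `ks_embedding`.
#' @param reference Optional tibble with `seq_id` and `clade`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ks_embedding
#' @export
autoplot.ks_embedding <- function(object, reference = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(reference)) {
    df <- dplyr::left_join(df, reference[, c("seq_id", "clade")], by = "seq_id")
    colour <- "clade"
  } else if ("cluster" %in% names(df)) {
    df$cluster <- factor(df$cluster)
    colour <- "cluster"
  } else {
    colour <- NULL
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  }
  p + ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}
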