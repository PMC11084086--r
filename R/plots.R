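# ggplot2 figures for the three diagnostics and the RSCU ordination.

#' Neutrality plot (GC12 versus GC3)
#'
#' Per-gene GC12 against GC3 with the OLS line, faceted by strain when more
#' than one is present.
#'
#' @param x A `cub_analysis` or a diagnostics tibble with `gc12`, `gc3`
#'   (and optionally `strain`).
#' @return A ggplot object.
#' @export
plot_neutrality <- function(x) {
  d <- if (inherits(x, "cub_analysis")) x$diagnostics else x
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gc3, y = .data$gc12)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::labs(x = "GC3", y = "GC12", title = "Neutrality plot") +
    ggplot2::theme_minimal()
  if ("strain" %in% names(d) && length(unique(d$strain)) > 1) {
    p <- p + ggplot2::facet_wrap(~strain)
  }
  p
}

#' ENC-GC3s plot with the mutation-only expected curve
#'
#' Observed per-gene ENC against GC3s; the solid curve is the expected ENC
#' under mutation pressure alone ([enc_expected()]). Points well below the
#' curve indicate forces beyond mutation.
#'
#' @inheritParams plot_neutrality
#' @return A ggplot object.
#' @export
plot_enc_gc3s <- function(x) {
  d <- if (inherits(x, "cub_analysis")) x$diagnostics else x
  curve <- tibble::tibble(gc3s = seq(0, 1, by = 0.005))
  curve$enc <- enc_expected(curve$gc3s)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gc3s, y = .data$enc_obs)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$gc3s, y = .data$enc),
                       inherit.aes = FALSE) +
    ggplot2::geom_point(alpha = 0.8, colour = "firebrick") +
    ggplot2::coord_cartesian(ylim = c(15, 62)) +
    ggplot2::labs(x = "GC3s", y = "ENC", title = "ENC-GC3s plot") +
    ggplot2::theme_minimal()
  if ("strain" %in% names(d) && length(unique(d$strain)) > 1) {
    p <- p + ggplot2::facet_wrap(~strain)
  }
  p
}

#' PR2-bias plot
#'
#' Per-gene A3/(A3+T3) against G3/(G3+C3); the cross-hair at (0.5, 0.5)
#' marks strand-symmetric usage.
#'
#' @inheritParams plot_neutrality
#' @return A ggplot object.
#' @export
plot_pr2 <- function(x) {
  d <- if (inherits(x, "cub_analysis")) x$diagnostics else x
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gc_bias,
                                       y = .data$at_bias)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::geom_point(alpha = 0.8, colour = "darkorange3") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3/(G3+C3)", y = "A3/(A3+T3)",
                  title = "PR2-bias plot") +
    ggplot2::theme_minimal()
  if ("strain" %in% names(d) && length(unique(d$strain)) > 1) {
    p <- p + ggplot2::facet_wrap(~strain)
  }
  p
}

#' Correspondence-analysis biplot
#'
#' Row (gene) principal coordinates on the first two axes, with axis
#' labels carrying the inertia share.
#'
#' @param x A `cub_coa` object.
#' @param show_columns Overlay codon (column) coordinates (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_coa <- function(x, show_columns = FALSE) {
  stopifnot(inherits(x, "cub_coa"))
  if (x$n_axes < 2) stop("fewer than 2 axes to plot", call. = FALSE)
  lab <- function(i) sprintf("Axis %d (%.1f%%)", i, x$inertia$inertia_pct[[i]])
  p <- ggplot2::ggplot(x$row_coords,
                       ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.7,
                       size = 3) +
    ggplot2::labs(x = lab(1), y = lab(2),
                  title = "Correspondence analysis of RSCU") +
    ggplot2::theme_minimal()
  if (show_columns) {
    p <- p + ggplot2::geom_point(data = x$col_coords, colour = "grey50",
                                 shape = 3)
  }
  p
}

#' @export
autoplot.cub_coa <- function(object, ...) plot_coa(object, ...)

#' Indicator-correlation heatmap
#'
#' Pearson correlations between usage indicators with significance stars.
#'
#' @param x A `cub_cormat` from [indicator_correlations()].
#' @return A ggplot object.
#' @export
plot_correlations <- function(x) {
  stopifnot(inherits(x, "cub_cormat"))
  d <- tibble::as_tibble(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
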