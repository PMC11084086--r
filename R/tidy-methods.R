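# broom-style accessors for the fitted objects.

#' @describeIn neutrality_fit One row per regression term (estimate only).
#' @param x A `neutrality_fit` object.
#' @param ... Unused.
#' @export
tidy.neutrality_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "gc3"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @describeIn neutrality_fit One-row model summary (slope, R^2, p, n,
#'   mutation-dominant flag).
#' @export
glance.neutrality_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    p_value = x$p_value,
    n_points = x$n_points,
    mutation_dominant = x$mutation_dominant
  )
}

#' @describeIn correspondence_analysis Per-axis inertia table.
#' @param x A `cub_coa` object.
#' @param ... Unused.
#' @export
tidy.cub_coa <- function(x, ...) {
  x$inertia
}

#' @describeIn correspondence_analysis One-row summary (total inertia, axis
#'   count, leading-axis share).
#' @export
glance.cub_coa <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    n_axes = x$n_axes,
    axis1_inertia_pct = if (x$n_axes >= 1) x$inertia$inertia_pct[[1L]]
                        else NA_real_
  )
}

#' @describeIn indicator_correlations Long correlation tibble (the object
#'   itself, stripped of its class).
#' @param x A `cub_cormat` object.
#' @param ... Unused.
#' @export
tidy.cub_cormat <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @describeIn rscu_cluster Merge-height table of the underlying
#'   dendrogram.
#' @param x A `cub_tree` object.
#' @param ... Unused.
#' @export
tidy.cub_tree <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$hclust$height),
    height = x$hclust$height
  )
}
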