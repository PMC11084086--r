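#' Expected ENC under mutation pressure alone
#'
#' The expected effective number of codons of a gene whose codon usage is
#' driven purely by its synonymous third-position G+C content:
#' `2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)`. Genes sitting on or near this
#' curve are compatible with mutation pressure alone; genes well below it
#' point to additional forces such as translational selection.
#'
#' @param gc3s Numeric vector of GC3s values in `[0, 1]`.
#' @return Expected ENC (same length as `gc3s`).
#' @examples
#' enc_expected(c(0, 0.5, 1))   # 31.0, 60.5, 32.0
#' @export
enc_expected <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1, na.rm = TRUE)) {
    stop("gc3s must lie in [0, 1]", call. = FALSE)
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC ratio: relative shortfall of observed versus expected ENC
#'
#' `(enc_exp - enc_obs) / enc_exp`; positive when the observed ENC falls
#' below the mutation-only expectation. Conventionally reported as a
#' percentage (multiply by 100).
#'
#' @param enc_exp Expected ENC (e.g. [enc_expected()]).
#' @param enc_obs Observed ENC.
#' @return Numeric vector of ratios.
#' @export
enc_ratio <- function(enc_exp, enc_obs) {
  stopifnot(all(enc_exp > 0, na.rm = TRUE))
  (enc_exp - enc_obs) / enc_exp
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 (mean G+C at codon positions 1
#' and 2) on GC3, with the two-sided Pearson correlation test attached. A
#' significant positive correlation is read as mutation pressure acting on
#' all three codon positions alike ("mutation-dominant"); its absence as
#' natural selection constraining positions 1-2 independently of 3.
#'
#' @param data Tibble with numeric columns `gc12` and `gc3` (one row per
#'   gene), e.g. from [composition_profile()].
#' @param alpha Significance level for the mutation-dominant call
#'   (default 0.05).
#' @return Object of class `neutrality_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n_points`, `mutation_dominant`,
#'   and the underlying `lm` fit. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
neutrality_fit <- function(data, alpha = 0.05) {
  stopifnot(all(c("gc12", "gc3") %in% names(data)))
  d <- data[stats::complete.cases(data[c("gc12", "gc3")]), c("gc12", "gc3")]
  if (nrow(d) < 3) {
    stop("neutrality_fit needs at least 3 genes with defined GC12/GC3",
         call. = FALSE)
  }
  if (stats::sd(d$gc3) == 0) {
    warning("GC3 is constant; slope undefined", call. = FALSE)
    fit <- list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, p_value = NA_real_,
                n_points = nrow(d), mutation_dominant = NA, model = NULL)
    return(structure(fit, class = "neutrality_fit"))
  }
  model <- stats::lm(gc12 ~ gc3, data = d)
  ct <- stats::cor.test(d$gc3, d$gc12, method = "pearson")
  fit <- list(
    slope = unname(stats::coef(model)[["gc3"]]),
    intercept = unname(stats::coef(model)[["(Intercept)"]]),
    r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value,
    n_points = nrow(d),
    mutation_dominant = ct$p.value < alpha,
    model = model
  )
  structure(fit, class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("<neutrality_fit> GC12 ~ GC3,", x$n_points, "genes\n")
  cat(sprintf("  slope %.4f, intercept %.4f, R^2 %.4f, p %.4g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  cat("  interpretation:",
      if (isTRUE(x$mutation_dominant)) "mutation-dominant (significant correlation)"
      else "selection-dominant (no significant correlation)", "\n")
  invisible(x)
}

#' PR2-bias coordinates (vector form)
#'
#' Parity rule 2 analysis of third-position composition:
#' `at_bias = A3 / (A3 + T3)` and `gc_bias = G3 / (G3 + C3)`, tallied by
#' default over the fourfold-degenerate codon quartets (Sueoka's
#' construction: XY-groups whose four codons all encode the same amino
#' acid), or over all synonymous codons. At (0.5, 0.5) the two strands are
#' used symmetrically -- no bias. Quadrants follow the biological reading:
#' 1 = A>T and G>C, 2 = T>A and G>C, 3 = T>A and C>G, 4 = A>T and C>G;
#' points on a boundary get `NA`.
#'
#' @param counts Named numeric codon-count vector.
#' @param code A [genetic_code()] object.
#' @param mode `"fourfold"` (default) or `"all_synonymous"`.
#' @return One-row tibble: `a3`, `t3`, `g3`, `c3`, `at_bias`, `gc_bias`,
#'   `quadrant`.
#' @export
pr2_point <- function(counts, code = genetic_code(),
                      mode = c("fourfold", "all_synonymous")) {
  assert_genetic_code(code)
  mode <- match.arg(mode)
  eligible <- pr2_eligible_codons(code, mode)
  n <- counts[eligible]
  n[is.na(n)] <- 0
  third <- substr(eligible, 3L, 3L)
  a3 <- sum(n[third == "A"]); t3 <- sum(n[third == "T"])
  g3 <- sum(n[third == "G"]); c3 <- sum(n[third == "C"])
  at <- if (a3 + t3 > 0) a3 / (a3 + t3) else NA_real_
  gc <- if (g3 + c3 > 0) g3 / (g3 + c3) else NA_real_
  tibble::tibble(
    a3 = a3, t3 = t3, g3 = g3, c3 = c3,
    at_bias = at, gc_bias = gc,
    quadrant = pr2_quadrant(at, gc)
  )
}

pr2_eligible_codons <- function(code, mode) {
  if (mode == "all_synonymous") return(synonymous_codons(code))
  # fourfold quartets: first-two-base groups whose 4 codons share one aa
  codons <- code$sense_codons
  stem <- substr(codons, 1L, 2L)
  keep <- vapply(unique(stem), function(st) {
    quad <- paste0(st, c("A", "C", "G", "T"))
    all(quad %in% codons) &&
      length(unique(code$codon_to_aa[quad])) == 1L
  }, logical(1))
  quartets <- unique(stem)[keep]
  codons[stem %in% quartets]
}

pr2_quadrant <- function(at, gc) {
  if (is.na(at) || is.na(gc) || at == 0.5 || gc == 0.5) return(NA_integer_)
  if (at > 0.5 && gc > 0.5) 1L
  else if (at < 0.5 && gc > 0.5) 2L
  else if (at < 0.5 && gc < 0.5) 3L
  else 4L
}

#' PR2-bias coordinates per gene (tidy form)
#'
#' @param counts Tidy count table from [count_codons()].
#' @inheritParams pr2_point
#' @return Tibble with one row per strain x gene plus the [pr2_point()]
#'   columns.
#' @export
pr2_points <- function(counts, code = genetic_code(),
                       mode = c("fourfold", "all_synonymous")) {
  mode <- match.arg(mode)
  counts |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("strain", "gene")))) |>
    dplyr::group_modify(function(d, key) {
      pr2_point(count_vec_from_tbl(d, code), code, mode)
    }) |>
    dplyr::ungroup()
}

#' Per-gene selection diagnostics table
#'
#' Combines, for every strain x gene, the neutrality-plot coordinates
#' (GC12, GC3), the ENC-GC3s plot quantities (observed ENC, expected ENC at
#' the gene's GC3s, ENC ratio in percent) and the PR2-bias coordinates.
#'
#' @param seqs Tibble with `strain`, `gene`, `seq`.
#' @param code A [genetic_code()] object.
#' @param pr2_mode Passed to [pr2_points()].
#' @return Tibble, one row per gene: `strain`, `gene`, `gc12`, `gc3`,
#'   `gc3s`, `enc_obs`, `enc_exp`, `enc_ratio_pct`, `at_bias`, `gc_bias`,
#'   `quadrant`.
#' @export
selection_diagnostics <- function(seqs, code = genetic_code(),
                                  pr2_mode = c("fourfold", "all_synonymous")) {
  pr2_mode <- match.arg(pr2_mode)
  comp <- composition_profile(seqs, code)
  counts <- count_codons(seqs, code)
  enc <- counts |>
    dplyr::group_by(.data$strain, .data$gene) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(enc_obs = enc_wright(count_vec_from_tbl(d, code), code))
    }) |>
    dplyr::ungroup()
  pr2 <- pr2_points(counts, code, pr2_mode)
  comp |>
    dplyr::select("strain", "gene", "gc12", "gc3", "gc3s") |>
    dplyr::left_join(enc, by = c("strain", "gene")) |>
    dplyr::mutate(
      enc_exp = enc_expected(.data$gc3s),
      enc_ratio_pct = 100 * enc_ratio(.data$enc_exp, .data$enc_obs)
    ) |>
    dplyr::left_join(
      dplyr::select(pr2, "strain", "gene", "at_bias", "gc_bias", "quadrant"),
      by = c("strain", "gene")
    )
}
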