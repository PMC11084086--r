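#' ENC-ranked expression split
#'
#' Orders genes by Wright's ENC, using low ENC (strong bias) as the proxy
#' for high expression, and takes a fraction off each end: the lowest-ENC
#' genes form the putative high-expression set, the highest-ENC genes the
#' low-expression set. Each set has `max(1, floor(fraction * n))` genes
#' (so a 12-gene set at the conventional 10% yields one gene per end). Ties
#' in ENC are broken by gene name for determinism.
#'
#' @param gene_enc Tibble with columns `gene` and `enc`.
#' @param fraction Fraction of genes per end (default 0.10).
#' @return Object of class `expression_split`: list with `high` and `low`
#'   gene-name vectors, `fraction` and `n_take`.
#' @export
expression_split <- function(gene_enc, fraction = 0.10) {
  stopifnot(all(c("gene", "enc") %in% names(gene_enc)))
  d <- gene_enc[!is.na(gene_enc$enc), , drop = FALSE]
  n <- nrow(d)
  if (n < 2) stop("expression_split needs at least 2 genes with defined ENC",
                  call. = FALSE)
  n_take <- max(1L, as.integer(floor(fraction * n)))
  if (fraction * n >= n / 2 || 2L * n_take > n) {
    stop(sprintf(
      "fraction %.3g of %d genes would make the high and low sets overlap",
      fraction, n), call. = FALSE)
  }
  ord <- order(d$enc, d$gene)
  structure(
    list(
      high = d$gene[ord[seq_len(n_take)]],
      low = d$gene[ord[seq.int(n - n_take + 1L, n)]],
      fraction = fraction,
      n_take = n_take
    ),
    class = "expression_split"
  )
}

#' @export
print.expression_split <- function(x, ...) {
  cat("<expression_split>", x$n_take, "gene(s) per end (fraction",
      x$fraction, ")\n")
  cat("  high expression (low ENC):", paste(x$high, collapse = ", "), "\n")
  cat("  low expression (high ENC):", paste(x$low, collapse = ", "), "\n")
  invisible(x)
}

#' Per-codon difference in RSCU between gene sets
#'
#' `delta_rscu = rscu_high - rscu_low` per sense codon; `NA` where either
#' side is unobserved. Within any family fully observed in both sets the
#' differences sum to zero, because RSCU sums to the family size on each
#' side.
#'
#' @param high,low Tidy RSCU tables (columns `codon`, `rscu`; e.g. from
#'   [rscu()] on pooled counts of each set).
#' @return Tibble: `codon`, `aa`, `rscu_high`, `rscu_low`, `delta_rscu`.
#' @export
delta_rscu <- function(high, low) {
  h <- dplyr::select(high, "codon", dplyr::any_of("aa"), rscu_high = "rscu")
  l <- dplyr::select(low, "codon", rscu_low = "rscu")
  dplyr::inner_join(h, l, by = "codon") |>
    dplyr::mutate(delta_rscu = .data$rscu_high - .data$rscu_low)
}

#' Three-way codon classification
#'
#' Flags each sense codon as high-frequency (overall RSCU > `rscu_threshold`),
#' highly expressed (delta-RSCU > `delta_threshold`), and optimal (both),
#' using strict inequalities.
#'
#' @param rscu_overall Tidy RSCU table over all genes pooled (columns
#'   `codon`, `rscu`, optionally `aa`).
#' @param delta Output of [delta_rscu()].
#' @param delta_threshold Delta-RSCU cut-off (default 0.08).
#' @param rscu_threshold Overall-RSCU cut-off (default 1.0).
#' @return Tibble: `codon`, `aa`, `rscu`, `delta_rscu`, `high_frequency`,
#'   `highly_expressed`, `optimal`.
#' @export
classify_codons <- function(rscu_overall, delta, delta_threshold = 0.08,
                            rscu_threshold = 1.0) {
  dplyr::select(rscu_overall, "codon", dplyr::any_of("aa"), "rscu") |>
    dplyr::left_join(dplyr::select(delta, "codon", "delta_rscu"),
                     by = "codon") |>
    dplyr::mutate(
      high_frequency = !is.na(.data$rscu) & .data$rscu > rscu_threshold,
      highly_expressed = !is.na(.data$delta_rscu) &
        .data$delta_rscu > delta_threshold,
      optimal = .data$high_frequency & .data$highly_expressed
    )
}

#' Optimal-codon determination for one or more strains
#'
#' Runs the full procedure per strain: per-gene ENC, ENC-ranked expression
#' split, RSCU of the pooled high- and low-expression counts (or the mean
#' of per-gene RSCU vectors with `pool = FALSE`), delta-RSCU, and the
#' three-way classification against the strain's overall pooled RSCU.
#'
#' @param counts Tidy count table from [count_codons()] covering one or
#'   more strains.
#' @param code A [genetic_code()] object.
#' @param fraction Expression-split fraction (default 0.10).
#' @param delta_threshold,rscu_threshold Classification cut-offs.
#' @param pool Pool codon counts within each set before computing RSCU
#'   (default `TRUE`); otherwise average the per-gene RSCU vectors.
#' @return Tibble, one row per strain x sense codon, with the
#'   [classify_codons()] columns.
#' @export
optimal_codon_analysis <- function(counts, code = genetic_code(),
                                   fraction = 0.10, delta_threshold = 0.08,
                                   rscu_threshold = 1.0, pool = TRUE) {
  assert_genetic_code(code)
  has_strain <- "strain" %in% names(counts)
  if (!has_strain) counts$strain <- "all"
  out <- purrr::map_dfr(split(counts, counts$strain), function(sc) {
    strain <- sc$strain[[1L]]
    vecs <- lapply(split(sc, sc$gene), count_vec_from_tbl, code = code)
    enc <- vapply(vecs, enc_wright, numeric(1), code = code)
    split_ <- expression_split(
      tibble::tibble(gene = names(vecs), enc = unname(enc)), fraction
    )
    set_rscu <- function(genes) {
      if (pool) {
        v <- rscu_vector(Reduce(`+`, vecs[genes]), code)
      } else {
        per <- vapply(genes, function(g) rscu_vector(vecs[[g]], code),
                      numeric(length(code$sense_codons)))
        v <- rowMeans(matrix(per, ncol = length(genes)), na.rm = TRUE)
        names(v) <- code$sense_codons
        v[is.nan(v)] <- NA_real_
      }
      tibble::tibble(codon = names(v),
                     aa = unname(code$codon_to_aa[names(v)]),
                     rscu = unname(v))
    }
    overall <- set_rscu(names(vecs))
    d <- delta_rscu(set_rscu(split_$high), set_rscu(split_$low))
    cls <- classify_codons(overall, d, delta_threshold, rscu_threshold)
    dplyr::bind_cols(tibble::tibble(strain = strain), cls)
  })
  if (!has_strain) out$strain <- NULL
  out
}
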