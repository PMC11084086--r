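#' Count codons in a single CDS
#'
#' Exact triplet tally of one validated coding sequence over the 64 codons.
#'
#' @param seq A CDS string (length a multiple of 3, alphabet A/C/G/T).
#' @param code A [genetic_code()] object (fixes the codon order of the
#'   returned vector).
#' @return Named integer vector over all 64 codons (stops included; callers
#'   decide whether to drop them).
#' @export
codon_count_vector <- function(seq, code = genetic_code()) {
  n <- nchar(seq)
  codons <- names(code$codon_to_aa)
  if (n == 0L) {
    return(stats::setNames(integer(length(codons)), codons))
  }
  starts <- seq.int(1L, n, 3L)
  tri <- substring(seq, starts, starts + 2L)
  stats::setNames(tabulate(factor(tri, levels = codons), length(codons)),
                  codons)
}

#' Count codons per gene
#'
#' Tidy codon-count table: one row per (strain, gene, codon). Stop codons
#' are tallied but excluded by default, so `sum(count)` within a gene is the
#' number of sense codons.
#'
#' @param seqs Tibble with columns `strain`, `gene`, `seq` (one CDS per row).
#' @param code A [genetic_code()] object.
#' @param exclude_stops Drop stop-codon rows (default `TRUE`).
#' @return Tibble with columns `strain`, `gene`, `codon`, `aa`, `count`,
#'   including zero-count rows so every gene covers the same codon grid.
#' @examples
#' seqs <- tibble::tibble(strain = "s1", gene = "g1", seq = "ATGATGTTTTAA")
#' count_codons(seqs) |> dplyr::filter(count > 0)
#' @export
count_codons <- function(seqs, code = genetic_code(), exclude_stops = TRUE) {
  assert_genetic_code(code)
  ct <- codon_table(code)
  if (exclude_stops) ct <- ct[!ct$is_stop, , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    v <- codon_count_vector(seqs$seq[[i]], code)
    tibble::tibble(
      strain = seqs$strain[[i]],
      gene = seqs$gene[[i]],
      codon = ct$codon,
      aa = ct$aa,
      count = as.integer(v[ct$codon])
    )
  })
  out
}

#' Pool codon counts over genes or strains
#'
#' @param counts Tidy count table from [count_codons()].
#' @param by Grouping columns to keep (e.g. `"strain"` to pool a strain's
#'   genes into one aggregate table; `character(0)` pools everything).
#' @return Tibble with columns `by`, `codon`, `aa`, `count`.
#' @export
pool_counts <- function(counts, by = "strain") {
  counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "codon", "aa")))) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Nucleotide and codon-position composition per gene
#'
#' For each CDS: overall base fractions; G+C content at codon positions 1-3
#' (GC1/GC2/GC3, over all codons including any terminal stop), their overall
#' and positional summaries (GC, GC12 = (GC1+GC2)/2); and the synonymous
#' third-position statistics GC3s and A3s/T3s/G3s/C3s, computed over
#' synonymous codons only (families of size >= 2; Met, Trp and stops
#' excluded). A3s..C3s follow the per-base denominator convention: the
#' numerator counts synonymous codons ending in the base, the denominator
#' counts synonymous codons whose family can end in that base -- which is
#' why the four values need not sum to 1.
#'
#' A gene with no synonymous codons at all gets `NA` for GC3s and A3s..C3s
#' (undefined, not zero).
#'
#' @param seqs Tibble with columns `strain`, `gene`, `seq`.
#' @param code A [genetic_code()] object.
#' @return Tibble, one row per input row: `strain`, `gene`, `length_nt`,
#'   `n_codons`, `frac_a`, `frac_t`, `frac_g`, `frac_c`, `gc1`, `gc2`, `gc3`,
#'   `gc12`, `gc`, `n_syn`, `gc3s`, `a3s`, `t3s`, `g3s`, `c3s`.
#' @export
composition_profile <- function(seqs, code = genetic_code()) {
  assert_genetic_code(code)
  ct <- codon_table(code)
  syn <- stats::setNames(ct$is_synonymous, ct$codon)
  third <- stats::setNames(ct$third_base, ct$codon)
  can_end <- family_third_bases(code)
  aa_of <- code$codon_to_aa
  # per-codon logical: does this codon's family contain a codon ending in B?
  can_end_codon <- lapply(c("A", "T", "G", "C"), function(b) {
    stats::setNames(vapply(ct$codon, function(cc) {
      a <- aa_of[[cc]]
      a != "*" && b %in% can_end[[a]]
    }, logical(1)), ct$codon)
  })
  names(can_end_codon) <- c("A", "T", "G", "C")

  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    s <- seqs$seq[[i]]
    n <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    pos <- rep_len(1:3, n)
    isgc <- ch %in% c("G", "C")
    gc1 <- mean(isgc[pos == 1L])
    gc2 <- mean(isgc[pos == 2L])
    gc3 <- mean(isgc[pos == 3L])

    starts <- seq.int(1L, n, 3L)
    cods <- substring(s, starts, starts + 2L)
    cods_syn <- cods[syn[cods]]
    n_syn <- length(cods_syn)
    if (n_syn > 0) {
      t3 <- third[cods_syn]
      gc3s <- mean(t3 %in% c("G", "C"))
      x3s <- vapply(c("A", "T", "G", "C"), function(b) {
        denom <- sum(can_end_codon[[b]][cods_syn])
        if (denom == 0) NA_real_ else sum(t3 == b) / denom
      }, numeric(1))
    } else {
      gc3s <- NA_real_
      x3s <- rep(NA_real_, 4)
    }

    tibble::tibble(
      strain = seqs$strain[[i]],
      gene = seqs$gene[[i]],
      length_nt = n,
      n_codons = n %/% 3L,
      frac_a = mean(ch == "A"),
      frac_t = mean(ch == "T"),
      frac_g = mean(ch == "G"),
      frac_c = mean(ch == "C"),
      gc1 = gc1, gc2 = gc2, gc3 = gc3,
      gc12 = (gc1 + gc2) / 2,
      gc = mean(isgc),
      n_syn = n_syn,
      gc3s = gc3s,
      a3s = x3s[[1L]], t3s = x3s[[2L]], g3s = x3s[[3L]], c3s = x3s[[4L]]
    )
  })
}
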