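# Vector-level workers operate on a named codon-count vector (as returned by
# codon_count_vector() or extracted from the tidy count table); the
# data-frame-first verbs below map them over genes.

count_vec_from_tbl <- function(counts, code) {
  codons <- names(code$codon_to_aa)
  v <- stats::setNames(numeric(length(codons)), codons)
  v[counts$codon] <- counts$count
  v
}

#' Relative synonymous codon usage (vector form)
#'
#' RSCU(c) = k * n_c / sum of counts over c's synonymous family, for family
#' size k: the observed count relative to the expectation under uniform use
#' of the family. 1 means no bias; values above 1 mark preferred codons.
#' Families with zero total usage get `NA` (unobserved, not unbiased).
#'
#' @param counts Named numeric vector of codon counts (64 or sense codons).
#' @param code A [genetic_code()] object.
#' @return Named numeric vector over the sense codons.
#' @export
rscu_vector <- function(counts, code = genetic_code()) {
  assert_genetic_code(code)
  out <- stats::setNames(rep(NA_real_, length(code$sense_codons)),
                         code$sense_codons)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    n <- counts[fam]
    n[is.na(n)] <- 0
    tot <- sum(n)
    if (tot > 0) out[fam] <- length(fam) * n / tot
  }
  out
}

#' Relative synonymous codon usage (tidy form)
#'
#' Adds an `rscu` column to a tidy codon-count table, computed within each
#' group defined by the non-codon columns (per gene, per strain aggregate,
#' or overall).
#'
#' @param counts Tibble with columns `codon`, `count` and any grouping
#'   columns among `strain`, `gene`.
#' @param code A [genetic_code()] object.
#' @return The input with columns `aa` and `rscu` (stop codons dropped).
#' @export
rscu <- function(counts, code = genetic_code()) {
  assert_genetic_code(code)
  grp <- intersect(c("strain", "gene"), names(counts))
  counts |>
    dplyr::filter(.data$codon %in% code$sense_codons) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(d, key) {
      v <- rscu_vector(count_vec_from_tbl(d, code), code)
      d$rscu <- unname(v[d$codon])
      d
    }) |>
    dplyr::ungroup()
}

#' Wright's effective number of codons (ENC)
#'
#' Wright's estimator: within each amino-acid family with at least two
#' observations, codon homozygosity is estimated as
#' `F = (n * sum(p_i^2) - 1) / (n - 1)`; homozygosities are averaged within
#' degeneracy classes and ENC is the sum over classes of
#' (number of amino acids in class) / (mean F), plus one per single-codon
#' amino acid (ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 under the standard code).
#' The result is capped to `[20, number of sense codons]` (61 under table 1).
#'
#' When the 3-fold class (Ile) is not computable it is imputed as the mean
#' of the 2-fold and 4-fold class averages; any other missing class drops
#' its term and the partial ENC is rescaled by the represented amino-acid
#' count. `NA` if no class is computable.
#'
#' @param counts Named numeric codon-count vector.
#' @param code A [genetic_code()] object.
#' @return ENC value in `[20, 61]` (or `NA`).
#' @export
enc_wright <- function(counts, code = genetic_code()) {
  assert_genetic_code(code)
  fam_size <- code$family_size
  f_hat <- rep(NA_real_, length(code$families))
  names(f_hat) <- names(code$families)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    if (length(fam) < 2L) next
    n <- counts[fam]
    n[is.na(n)] <- 0
    tot <- sum(n)
    if (tot < 2) next
    p <- n / tot
    f_hat[[aa]] <- (tot * sum(p^2) - 1) / (tot - 1)
  }

  classes <- sort(unique(fam_size[fam_size >= 2L]))
  n_single <- sum(fam_size == 1L)
  f_bar <- vapply(classes, function(k) {
    f <- f_hat[names(fam_size)[fam_size == k]]
    f <- f[!is.na(f) & f > 0]
    if (length(f) == 0) NA_real_ else mean(f)
  }, numeric(1))
  names(f_bar) <- as.character(classes)

  # Ile-class fallback: mean of flanking 2- and 4-fold class averages
  if ("3" %in% names(f_bar) && is.na(f_bar[["3"]]) &&
      !is.na(f_bar["2"]) && !is.na(f_bar["4"])) {
    f_bar[["3"]] <- mean(c(f_bar[["2"]], f_bar[["4"]]))
  }

  n_aa_class <- vapply(classes, function(k) sum(fam_size == k), numeric(1))
  present <- !is.na(f_bar)
  if (!any(present)) return(NA_real_)
  enc <- n_single + sum(n_aa_class[present] / f_bar[present])
  if (!all(present)) {
    represented <- n_single + sum(n_aa_class[present])
    enc <- enc * (n_single + sum(n_aa_class)) / represented
  }
  max(20, min(enc, length(code$sense_codons)))
}

#' Relative adaptiveness weights for CAI
#'
#' From a reference codon-count table (conventionally pooled counts of
#' highly expressed genes), each codon's weight is its count divided by the
#' count of the most-used codon in its family, so the best codon of every
#' family has weight 1. Codons unobserved in the reference get a small floor
#' (default 0.01) rather than zero, so the geometric mean stays defined; a
#' family entirely absent from the reference gets the floor throughout, with
#' a warning.
#'
#' @param reference Named numeric codon-count vector, or a tidy count table
#'   with `codon` and `count` columns (pooled over the reference genes).
#' @param code A [genetic_code()] object.
#' @param floor Weight assigned to unobserved codons (default 0.01).
#' @return Tibble with columns `codon`, `aa`, `w`.
#' @export
cai_weights <- function(reference, code = genetic_code(), floor = 0.01) {
  assert_genetic_code(code)
  if (is.data.frame(reference)) {
    reference <- count_vec_from_tbl(reference, code)
  }
  w <- stats::setNames(rep(NA_real_, length(code$sense_codons)),
                       code$sense_codons)
  empty <- character(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    n <- reference[fam]
    n[is.na(n)] <- 0
    if (max(n) == 0) {
      w[fam] <- floor
      empty <- c(empty, aa)
    } else {
      w[fam] <- pmax(n / max(n), floor)
    }
  }
  if (length(empty) > 0) {
    warning("cai_weights: no reference usage for amino acid(s) ",
            paste(empty, collapse = ", "), "; floor applied", call. = FALSE)
  }
  tibble::tibble(
    codon = names(w),
    aa = unname(code$codon_to_aa[names(w)]),
    w = unname(w)
  )
}

weight_vec <- function(weights, code) {
  if (is.data.frame(weights)) {
    stats::setNames(weights$w, weights$codon)
  } else {
    weights
  }
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness weights over all codon
#' occurrences in the gene, excluding single-codon amino acids (Met, Trp
#' under the standard code) and stops. 1 means every codon is the reference
#' set's favourite.
#'
#' @param counts Named numeric codon-count vector.
#' @param weights Output of [cai_weights()] (tibble) or a named weight
#'   vector.
#' @param code A [genetic_code()] object.
#' @return CAI in (0, 1], or `NA` if the gene has no eligible codons.
#' @export
cai_index <- function(counts, weights, code = genetic_code()) {
  assert_genetic_code(code)
  w <- weight_vec(weights, code)
  eligible <- synonymous_codons(code)
  n <- counts[eligible]
  n[is.na(n)] <- 0
  tot <- sum(n)
  if (tot == 0) return(NA_real_)
  exp(sum(n * log(w[eligible])) / tot)
}

#' Codon bias index (CBI)
#'
#' Normalised excess usage of a set of optimal codons over the random
#' expectation: `CBI = (N_opt - N_ran) / (N_tot - N_ran)` where `N_tot`
#' counts codons of synonymous families (Met/Trp/stops excluded), `N_opt`
#' those falling in `optimal_set`, and `N_ran` the expected optimal count
#' under uniform within-family usage. 1 = only optimal codons, 0 = random,
#' negative = optimal codons avoided.
#'
#' @param counts Named numeric codon-count vector.
#' @param optimal_set Character vector of optimal codons (subset of the
#'   sense codons).
#' @param code A [genetic_code()] object.
#' @return CBI in `[-1, 1]`, or `NA` when degenerate (`N_tot == N_ran`).
#' @export
cbi_index <- function(counts, optimal_set, code = genetic_code()) {
  assert_genetic_code(code)
  stopifnot(all(optimal_set %in% code$sense_codons))
  n_tot <- 0; n_opt <- 0; n_ran <- 0
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    if (length(fam) < 2L) next
    n <- counts[fam]
    n[is.na(n)] <- 0
    k_opt <- sum(fam %in% optimal_set)
    n_tot <- n_tot + sum(n)
    n_opt <- n_opt + sum(n[fam %in% optimal_set])
    n_ran <- n_ran + sum(n) * k_opt / length(fam)
  }
  if (n_tot == n_ran) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' Frequency of optimal codons (FOP)
#'
#' Fraction of a gene's synonymous codons (families of size >= 2) that
#' belong to the optimal set.
#'
#' @inheritParams cbi_index
#' @return FOP in `[0, 1]`, or `NA` if the gene has no synonymous codons.
#' @export
fop_index <- function(counts, optimal_set, code = genetic_code()) {
  assert_genetic_code(code)
  stopifnot(all(optimal_set %in% code$sense_codons))
  eligible <- synonymous_codons(code)
  n <- counts[eligible]
  n[is.na(n)] <- 0
  tot <- sum(n)
  if (tot == 0) return(NA_real_)
  sum(n[eligible %in% optimal_set]) / tot
}

# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

check_protein <- function(protein, what) {
  if (nchar(protein) == 0) {
    stop(what, ": empty protein sequence", call. = FALSE)
  }
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  bad <- which(!(aa %in% names(KYTE_DOOLITTLE)))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-standard residue '%s' at position %d",
                 what, aa[bad[1L]], bad[1L]), call. = FALSE)
  }
  aa
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues of a protein; positive
#' values indicate hydrophobic (membrane-like) proteins, negative
#' hydrophilic ones.
#'
#' @param protein Amino-acid string over the 20 standard residues
#'   (vectorised).
#' @return Numeric vector of GRAVY values.
#' @examples
#' gravy("GGGG")   # -0.4
#' gravy("IF")     # 3.65
#' @export
gravy <- function(protein) {
  vapply(protein, function(p) {
    mean(KYTE_DOOLITTLE[check_protein(p, "gravy")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Aromaticity (AROMO)
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp) in a protein.
#'
#' @inheritParams gravy
#' @return Numeric vector of proportions in `[0, 1]`.
#' @examples
#' aromo("FYWA")   # 0.75
#' @export
aromo <- function(protein) {
  vapply(protein, function(p) {
    aa <- check_protein(p, "aromo")
    mean(aa %in% c("F", "Y", "W"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-gene codon-usage index table
#'
#' One row per strain x gene with ENC, CAI, CBI, FOP, GRAVY and AROMO plus
#' the full composition profile. CAI weights and the optimal-codon set are,
#' by default, derived per strain from the data itself: the ENC-ranked
#' expression split ([expression_split()]) provides the high-expression
#' reference for CAI, and the delta-RSCU classification
#' ([optimal_codon_analysis()]) provides the optimal set for CBI/FOP. Both
#' can be overridden.
#'
#' @param seqs Tibble with `strain`, `gene`, `seq`.
#' @param code A [genetic_code()] object.
#' @param fraction Expression-split fraction used for the self-contained
#'   defaults (default 0.10).
#' @param cai_ref Optional [cai_weights()] tibble applied to every strain.
#' @param optimal_set Optional character vector of optimal codons applied to
#'   every strain.
#' @return Tibble with one row per strain x gene.
#' @export
gene_indices <- function(seqs, code = genetic_code(), fraction = 0.10,
                         cai_ref = NULL, optimal_set = NULL) {
  assert_genetic_code(code)
  comp <- composition_profile(seqs, code)
  counts <- count_codons(seqs, code)

  per_strain <- lapply(split(seq_len(nrow(seqs)), seqs$strain), function(ix) {
    sseqs <- seqs[ix, , drop = FALSE]
    scounts <- counts[counts$strain == sseqs$strain[[1L]], , drop = FALSE]
    vecs <- lapply(split(scounts, scounts$gene),
                   count_vec_from_tbl, code = code)
    enc <- vapply(sseqs$gene, function(g) enc_wright(vecs[[g]], code),
                  numeric(1))

    weights <- cai_ref
    opt <- optimal_set
    if (is.null(weights) || is.null(opt)) {
      split_ <- expression_split(
        tibble::tibble(gene = sseqs$gene, enc = enc), fraction
      )
      if (is.null(weights)) {
        high_pool <- Reduce(`+`, vecs[split_$high])
        weights <- suppressWarnings(cai_weights(high_pool, code))
      }
      if (is.null(opt)) {
        cls <- optimal_codon_analysis(scounts, code, fraction = fraction)
        opt <- cls$codon[cls$optimal]
      }
    }

    prot <- suppressWarnings(translate_cds(sseqs$seq, code))
    tibble::tibble(
      strain = sseqs$strain,
      gene = sseqs$gene,
      enc = unname(enc),
      cai = vapply(sseqs$gene, function(g)
        cai_index(vecs[[g]], weights, code), numeric(1), USE.NAMES = FALSE),
      cbi = vapply(sseqs$gene, function(g)
        cbi_index(vecs[[g]], opt, code), numeric(1), USE.NAMES = FALSE),
      fop = vapply(sseqs$gene, function(g)
        fop_index(vecs[[g]], opt, code), numeric(1), USE.NAMES = FALSE),
      gravy = gravy(prot),
      aromo = aromo(prot)
    )
  })

  dplyr::bind_rows(per_strain) |>
    dplyr::left_join(comp, by = c("strain", "gene"))
}
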