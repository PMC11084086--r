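# Synthetic codon-biased CDS generator. Emulates the statistical structure
# of an AT-rich mitochondrial core-gene set (strains x genes, short AT-rich
# genes with low GC3s and tunable within-family codon bias) so the whole
# analysis pipeline is testable without any downloads. Draws are i.i.d. per
# codon: no phylogeny or substitution process is simulated.

# The 12 mitochondrial core protein-coding genes with realistic lengths
# (multiples of 3 spanning ~370-2262 nt; rps3 longest, nad3 shortest).
CORE_PCG_LENGTHS <- c(
  atp6 = 780, cob = 1161, cox1 = 1608, cox2 = 750, cox3 = 810,
  nad1 = 1080, nad2 = 1650, nad3 = 369, nad4 = 1485, nad5 = 1980,
  nad6 = 660, rps3 = 2262
)

# Hydrophobic, AT-rich amino-acid profile typical of membrane-bound
# respiratory-chain proteins (GRAVY > 0): heavy on Leu/Ile/Phe/Ser/Val.
AA_PROFILE_MEMBRANE <- c(
  A = 0.035, R = 0.020, N = 0.070, D = 0.025, C = 0.010,
  Q = 0.020, E = 0.020, G = 0.045, H = 0.015, I = 0.115,
  L = 0.145, K = 0.055, M = 0.025, F = 0.110, P = 0.025,
  S = 0.075, T = 0.045, W = 0.015, Y = 0.050, V = 0.050
)

# Basic-residue-rich profile for a ribosomal-protein-like hydrophilic gene
# (GRAVY < 0): heavy on Lys/Arg/Asn/Ser/Glu.
AA_PROFILE_RIBOSOMAL <- c(
  A = 0.040, R = 0.060, N = 0.080, D = 0.040, C = 0.005,
  Q = 0.030, E = 0.050, G = 0.050, H = 0.020, I = 0.070,
  L = 0.095, K = 0.110, M = 0.020, F = 0.050, P = 0.030,
  S = 0.100, T = 0.050, W = 0.010, Y = 0.040, V = 0.050
)

#' Specification for the synthetic CDS generator
#'
#' Collects everything [simulate_strain()] needs: the gene roster with
#' per-gene lengths, per-gene target GC3s, the within-family bias
#' concentration, amino-acid frequencies, and an optional forced
#' preferred-codon set. Defaults emulate an 8-strain x 12-gene AT-rich
#' mitochondrial core-gene panel: gene lengths 369-2262 nt, per-gene target
#' GC3s spread over 0.06-0.21, and a bias concentration in the strong-bias
#' regime (per-gene ENC well below 35).
#'
#' `bias_concentration` is the Dirichlet concentration of the within-family
#' codon distribution around its GC3-tilt: `Inf` means the tilt is used
#' exactly (pure mutation pressure, no extra bias); small values make one
#' codon per family dominate (strong bias).
#'
#' @param n_strains Number of strains (default 8).
#' @param genes Tibble with columns `gene`, `length_nt` (multiples of 3) and
#'   optionally per-gene `target_gc3` and `bias_concentration` overriding
#'   the spec-level values. Default: the 12 core-gene roster.
#' @param target_gc3 Per-gene target synonymous GC3 in `[0, 1]`; recycled.
#'   Default: an even spread over `[0.06, 0.21]`.
#' @param bias_concentration Dirichlet concentration (> 0, may be `Inf`);
#'   default 3, which puts per-gene ENC around 30 -- the strong-bias
#'   regime (ENC < 35) typical of AT-rich mitochondrial core genes.
#' @param aa_frequencies Named probability vector over the 20 amino acids;
#'   default a hydrophobic membrane-protein profile. Genes listed in
#'   `hydrophilic_genes` use a basic-residue profile instead.
#' @param hydrophilic_genes Genes simulated with the hydrophilic profile
#'   (default `"rps3"`).
#' @param preferred_codons Optional character vector: one forced preferred
#'   codon per (multi-codon) family, boosted in the genes named by
#'   `preferred_genes`.
#' @param preferred_genes Genes in which `preferred_codons` are boosted
#'   (default: all genes, if `preferred_codons` is given).
#' @param preference_boost Multiplicative tilt boost for a forced preferred
#'   codon (default 8).
#' @param gc12_coupling Nonnegative coupling of amino-acid choice to the
#'   gene's mutational GC parameter: 0 (default) leaves GC12 independent of
#'   target GC3; positive values tilt amino-acid frequencies towards
#'   GC-rich first/second codon positions in proportion to `target_gc3`,
#'   producing the shared-mutational-pressure regime of a neutrality plot.
#' @param code A [genetic_code()] object.
#' @param seed Integer master seed; per-(strain, gene) substreams are
#'   derived by stable hashing so results are reproducible and adding a
#'   gene does not perturb the others.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(n_strains = 8,
                     genes = NULL,
                     target_gc3 = NULL,
                     bias_concentration = 3,
                     aa_frequencies = AA_PROFILE_MEMBRANE,
                     hydrophilic_genes = "rps3",
                     preferred_codons = NULL,
                     preferred_genes = NULL,
                     preference_boost = 8,
                     gc12_coupling = 0,
                     code = genetic_code(),
                     seed = 1) {
  assert_genetic_code(code)
  if (is.null(genes)) {
    genes <- tibble::tibble(gene = names(CORE_PCG_LENGTHS),
                            length_nt = unname(CORE_PCG_LENGTHS))
  }
  stopifnot(all(c("gene", "length_nt") %in% names(genes)))
  if (any(genes$length_nt %% 3L != 0L)) {
    stop("gene lengths must be multiples of 3", call. = FALSE)
  }
  if (!"target_gc3" %in% names(genes)) {
    if (is.null(target_gc3)) {
      target_gc3 <- seq(0.06, 0.21, length.out = nrow(genes))
    }
    genes$target_gc3 <- rep_len(target_gc3, nrow(genes))
  }
  if (!"bias_concentration" %in% names(genes)) {
    genes$bias_concentration <- rep_len(bias_concentration, nrow(genes))
  }
  stopifnot(all(genes$target_gc3 >= 0 & genes$target_gc3 <= 1),
            all(genes$bias_concentration > 0))
  aa_frequencies <- aa_frequencies / sum(aa_frequencies)
  if (!is.null(preferred_codons)) {
    stopifnot(all(preferred_codons %in% code$sense_codons))
    if (is.null(preferred_genes)) preferred_genes <- genes$gene
  }
  structure(
    list(
      n_strains = as.integer(n_strains),
      genes = genes,
      aa_frequencies = aa_frequencies,
      hydrophilic_genes = hydrophilic_genes,
      preferred_codons = preferred_codons,
      preferred_genes = preferred_genes,
      preference_boost = preference_boost,
      gc12_coupling = gc12_coupling,
      code = code,
      seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("<sim_spec>", x$n_strains, "strains x", nrow(x$genes), "genes, seed",
      x$seed, "\n")
  cat("  target GC3:", sprintf("%.2f-%.2f", min(x$genes$target_gc3),
                               max(x$genes$target_gc3)),
      " bias concentration:",
      paste(unique(x$genes$bias_concentration), collapse = "/"), "\n")
  if (!is.null(x$preferred_codons)) {
    cat("  forced preferred codons in:",
        paste(x$preferred_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

# Stable 31-bit string hash for per-(strain, gene) RNG substreams.
derive_seed <- function(seed, ...) {
  key <- paste(seed, ..., sep = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Within-family codon probabilities under GC3 tilt and Dirichlet bias
#'
#' Builds the codon distribution of one amino-acid family in two steps:
#' (i) a GC3 tilt assigning total mass `target_gc3` to the G/C-ending codons
#' of the family (split evenly) and `1 - target_gc3` to the A/T-ending ones
#' (renormalised when the family can only end one way); a forced preferred
#' codon's tilt weight is multiplied by `preference_boost`; then (ii) a
#' Dirichlet draw with concentration `bias_concentration` around that tilt.
#' `bias_concentration = Inf` skips the draw and returns the tilt exactly.
#' Uses the current RNG state; single-codon families return probability 1.
#'
#' @param aa One-letter amino-acid code.
#' @param code A [genetic_code()] object.
#' @param target_gc3 Target share of G/C-ending codons in `[0, 1]`.
#' @param bias_concentration Positive Dirichlet concentration or `Inf`.
#' @param preferred Optional forced preferred codon within the family.
#' @param preference_boost Tilt multiplier for `preferred` (default 8).
#' @return Named probability vector over the family's codons.
#' @export
biased_codon_distribution <- function(aa, code = genetic_code(),
                                      target_gc3 = 0.5,
                                      bias_concentration = Inf,
                                      preferred = NULL,
                                      preference_boost = 8) {
  assert_genetic_code(code)
  fam <- code$families[[aa]]
  if (is.null(fam)) stop("unknown amino acid: ", aa, call. = FALSE)
  if (length(fam) == 1L) return(stats::setNames(1, fam))
  third <- substr(fam, 3L, 3L)
  is_gc <- third %in% c("G", "C")
  tilt <- numeric(length(fam))
  if (any(is_gc)) tilt[is_gc] <- target_gc3 / sum(is_gc)
  if (any(!is_gc)) tilt[!is_gc] <- (1 - target_gc3) / sum(!is_gc)
  if (sum(tilt) == 0) tilt <- rep(1 / length(fam), length(fam))
  tilt <- tilt / sum(tilt)
  if (!is.null(preferred) && preferred %in% fam) {
    tilt[fam == preferred] <- tilt[fam == preferred] * preference_boost
    tilt <- tilt / sum(tilt)
  }
  p <- if (is.infinite(bias_concentration)) {
    tilt
  } else {
    g <- stats::rgamma(length(fam), shape = bias_concentration * tilt)
    if (sum(g) == 0) tilt else g / sum(g)
  }
  stats::setNames(p, fam)
}

# Mean G+C fraction at codon positions 1-2, per amino acid (over its family).
aa_gc12_content <- function(code) {
  vapply(code$families, function(fam) {
    mean(vapply(fam, function(cc) {
      sum(strsplit(substr(cc, 1L, 2L), "")[[1L]] %in% c("G", "C")) / 2
    }, numeric(1)))
  }, numeric(1))
}

simulate_gene_seq <- function(length_nt, target_gc3, bias_concentration,
                              preferred, preference_boost, aa_freq,
                              gc12_coupling, code) {
  n_body <- length_nt %/% 3L - 2L
  if (n_body < 1L) stop("gene too short to simulate", call. = FALSE)
  if (gc12_coupling > 0) {
    w <- aa_freq * exp(gc12_coupling * target_gc3 * aa_gc12_content(code)[names(aa_freq)])
    aa_freq <- w / sum(w)
  }
  dists <- lapply(names(code$families), function(aa) {
    biased_codon_distribution(
      aa, code, target_gc3, bias_concentration,
      preferred = if (is.null(preferred)) NULL else {
        hit <- preferred[preferred %in% code$families[[aa]]]
        if (length(hit)) hit[[1L]] else NULL
      },
      preference_boost = preference_boost
    )
  })
  names(dists) <- names(code$families)
  aas <- sample(names(aa_freq), n_body, replace = TRUE, prob = aa_freq)
  codons <- character(n_body)
  for (aa in unique(aas)) {
    idx <- which(aas == aa)
    d <- dists[[aa]]
    codons[idx] <- if (length(d) == 1L) names(d) else {
      sample(names(d), length(idx), replace = TRUE, prob = d)
    }
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Simulate one strain's coding sequences
#'
#' Draws every gene of the spec for one strain: amino acids i.i.d. from the
#' gene's amino-acid profile, codons from the per-family biased
#' distributions, with ATG prepended and a single TAA stop appended.
#' Deterministic given `(spec$seed, strain_index)`; different strain
#' indices give different sequences.
#'
#' @param spec A [sim_spec()] object.
#' @param strain_index Integer strain number (1-based).
#' @return Tibble with columns `strain`, `gene`, `seq`, `length_nt`.
#' @export
simulate_strain <- function(spec, strain_index) {
  stopifnot(inherits(spec, "sim_spec"))
  strain <- sprintf("strain_%02d", strain_index)
  rows <- purrr::map_dfr(seq_len(nrow(spec$genes)), function(i) {
    g <- spec$genes[i, ]
    preferred <- if (!is.null(spec$preferred_codons) &&
                     g$gene %in% spec$preferred_genes) {
      spec$preferred_codons
    } else NULL
    aa_freq <- if (g$gene %in% spec$hydrophilic_genes) {
      p <- AA_PROFILE_RIBOSOMAL
      p / sum(p)
    } else {
      spec$aa_frequencies
    }
    seq <- withr::with_seed(
      derive_seed(spec$seed, strain_index, g$gene),
      simulate_gene_seq(g$length_nt, g$target_gc3, g$bias_concentration,
                        preferred, spec$preference_boost, aa_freq,
                        spec$gc12_coupling, spec$code)
    )
    tibble::tibble(strain = strain, gene = g$gene, seq = seq,
                   length_nt = nchar(seq))
  })
  rows
}

#' Simulate the full strains x genes CDS panel
#'
#' @param spec A [sim_spec()] object.
#' @return Tibble with one row per strain x gene (`strain`, `gene`, `seq`,
#'   `length_nt`), with the generator's ground truth attached as attribute
#'   `"ground_truth"` (per-gene target GC3, bias concentration, forced
#'   preferred codons).
#' @export
simulate_cds <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  out <- purrr::map_dfr(seq_len(spec$n_strains),
                        function(i) simulate_strain(spec, i))
  gt <- spec$genes
  gt$preferred_forced <- !is.null(spec$preferred_codons) &
    gt$gene %in% (spec$preferred_genes %||% character(0))
  attr(out, "ground_truth") <- gt
  out
}

#' Simulate a gene panel for neutrality-plot calibration
#'
#' Generates `n_genes` single-strain genes whose per-gene mutational GC
#' parameter (the target GC3) is drawn uniformly from `gc3_range`. With
#' `coupled = TRUE` the amino-acid frequencies are tilted by the same
#' parameter (shared mutational pressure: GC12 and GC3 co-vary); with
#' `coupled = FALSE` GC12 is independent of GC3. Returns the per-gene
#' composition needed for [neutrality_fit()].
#'
#' @param n_genes Number of genes (default 50).
#' @param coupled Share the mutational parameter between codon positions
#'   1-2 and 3?
#' @param length_nt Gene length in nt (default 360).
#' @param gc3_range Range of the per-gene mutational parameter.
#' @param coupling Coupling strength when `coupled` (default 6).
#' @param code A [genetic_code()] object.
#' @param seed Integer seed.
#' @return Tibble with columns `gene`, `gc12`, `gc3`.
#' @export
simulate_neutrality_panel <- function(n_genes = 50, coupled = TRUE,
                                      length_nt = 360,
                                      gc3_range = c(0.05, 0.45),
                                      coupling = 6,
                                      code = genetic_code(), seed = 1) {
  targets <- withr::with_seed(
    derive_seed(seed, "targets"),
    stats::runif(n_genes, gc3_range[[1L]], gc3_range[[2L]])
  )
  genes <- tibble::tibble(
    gene = sprintf("g%03d", seq_len(n_genes)),
    length_nt = length_nt,
    target_gc3 = targets,
    bias_concentration = Inf
  )
  spec <- sim_spec(
    n_strains = 1, genes = genes, hydrophilic_genes = character(0),
    gc12_coupling = if (coupled) coupling else 0, code = code, seed = seed
  )
  seqs <- simulate_strain(spec, 1L)
  comp <- composition_profile(seqs, code)
  tibble::tibble(gene = comp$gene, gc12 = comp$gc12, gc3 = comp$gc3)
}
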