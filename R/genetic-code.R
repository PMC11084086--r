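#' Build a genetic-code object
#'
#' Wraps an NCBI translation table into the structure the rest of the package
#' works with: the 64-codon to amino-acid map, the synonymous-codon families,
#' and the derived codon classes (sense, stop, single-codon amino acids).
#' Under the standard code (table 1) there are 61 sense codons, Met and Trp
#' are the single-codon amino acids, and 59 sense codons remain once they are
#' excluded -- the codon space used for RSCU-based multivariate analysis.
#'
#' @param table_id Integer NCBI translation table number (1 = standard,
#'   4 = mold/protozoan mitochondrial, where UGA encodes Trp).
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character over the 64 DNA codons, `"*"`
#'   marks stops), `families` (named list, amino acid -> synonymous codons),
#'   `family_size` (named integer per amino acid), `sense_codons`,
#'   `stop_codons`, and `single_codon_aas`.
#'
#' @examples
#' code <- genetic_code()
#' length(code$sense_codons)           # 61
#' code$families[["L"]]                # the six leucine codons
#' genetic_code(4)$families[["W"]]     # TGA + TGG under table 4
#' @export
genetic_code <- function(table_id = 1) {
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  codons <- names(tab)
  aa <- unname(tab)
  sense <- codons[aa != "*"]
  families <- split(sense, aa[aa != "*"])
  fam_size <- vapply(families, length, integer(1))
  structure(
    list(
      table_id = as.integer(table_id),
      codon_to_aa = stats::setNames(aa, codons),
      families = families,
      family_size = fam_size,
      sense_codons = sense,
      stop_codons = codons[aa == "*"],
      single_codon_aas = names(fam_size)[fam_size == 1L]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI translation table", x$table_id, "\n")
  cat("  sense codons:", length(x$sense_codons),
      " stop codons:", length(x$stop_codons), "\n")
  cat("  single-codon amino acids:",
      paste(x$single_codon_aas, collapse = ", "), "\n")
  invisible(x)
}

is_genetic_code <- function(x) inherits(x, "genetic_code")

assert_genetic_code <- function(code) {
  if (!is_genetic_code(code)) {
    stop("`code` must be a genetic_code object; see genetic_code()",
         call. = FALSE)
  }
  code
}

#' Tabular view of a genetic code
#'
#' @param code A [genetic_code()] object.
#'
#' @return A tibble with one row per codon: `codon`, `aa` (`"*"` for stop),
#'   `family_size`, `third_base`, `is_stop`, and `is_synonymous` (sense codon
#'   belonging to a family of size >= 2 -- the codons entering GC3s and the
#'   synonymous third-position statistics).
#' @examples
#' codon_table() |> dplyr::filter(is_synonymous) |> nrow()  # 59 under table 1
#' @export
codon_table <- function(code = genetic_code()) {
  assert_genetic_code(code)
  codons <- names(code$codon_to_aa)
  aa <- unname(code$codon_to_aa)
  fam <- ifelse(aa == "*", NA_integer_, code$family_size[aa])
  tibble::tibble(
    codon = codons,
    aa = aa,
    family_size = as.integer(fam),
    third_base = substr(codons, 3L, 3L),
    is_stop = aa == "*",
    is_synonymous = !is.na(fam) & fam >= 2L
  )
}

# Sense codons in families of size >= 2 (excludes Met/Trp under table 1).
synonymous_codons <- function(code = genetic_code()) {
  code$sense_codons[code$family_size[code$codon_to_aa[code$sense_codons]] >= 2L]
}

# Third bases a family can end in, per amino acid: named list aa -> character.
family_third_bases <- function(code = genetic_code()) {
  lapply(code$families, function(cs) unique(substr(cs, 3L, 3L)))
}
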