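# Fixtures and independent brute-force oracles used across the suite.

# Standard-code family lists written out by hand (independent of the
# package's genetic_code() construction).
FAMILIES_STD <- list(
  F = c("TTT", "TTC"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  I = c("ATT", "ATC", "ATA"),
  M = "ATG",
  V = c("GTT", "GTC", "GTA", "GTG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  T = c("ACT", "ACC", "ACA", "ACG"),
  A = c("GCT", "GCC", "GCA", "GCG"),
  Y = c("TAT", "TAC"),
  H = c("CAT", "CAC"),
  Q = c("CAA", "CAG"),
  N = c("AAT", "AAC"),
  K = c("AAA", "AAG"),
  D = c("GAT", "GAC"),
  E = c("GAA", "GAG"),
  C = c("TGT", "TGC"),
  W = "TGG",
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  G = c("GGT", "GGC", "GGA", "GGG")
)

# Naive Wright estimator: direct transcription of the formula, including
# the published fallback rules (F3 <- mean(F2, F4); other missing class ->
# drop term and rescale by represented amino-acid count; cap to [20, 61]).
enc_bruteforce <- function(counts) {
  f_by_k <- list()
  n_by_k <- list()
  for (aa in names(FAMILIES_STD)) {
    fam <- FAMILIES_STD[[aa]]
    k <- length(fam)
    if (k == 1) next
    kk <- as.character(k)
    n_by_k[[kk]] <- c(n_by_k[[kk]], aa)
    n <- counts[fam]
    n[is.na(n)] <- 0
    tot <- sum(n)
    if (tot < 2) next
    p <- n / tot
    f <- (tot * sum(p^2) - 1) / (tot - 1)
    if (f > 0) f_by_k[[kk]] <- c(f_by_k[[kk]], f)
  }
  ks <- c("2", "3", "4", "6")
  fbar <- sapply(ks, function(k) {
    if (is.null(f_by_k[[k]])) NA_real_ else mean(f_by_k[[k]])
  })
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- mean(c(fbar[["2"]], fbar[["4"]]))
  }
  nk <- sapply(ks, function(k) length(n_by_k[[k]]))
  present <- !is.na(fbar)
  if (!any(present)) return(NA_real_)
  enc <- 2 + sum(nk[present] / fbar[present])
  if (!all(present)) {
    enc <- enc * (2 + sum(nk)) / (2 + sum(nk[present]))
  }
  max(20, min(enc, 61))
}

# Random codon-count table over the 61 sense codons.
random_count_table <- function(lambda = 8) {
  sense <- unlist(FAMILIES_STD, use.names = FALSE)
  stats::setNames(stats::rpois(length(sense), lambda), sense)
}

# Eigen-decomposition CA oracle: inertias of the chi-square standardized
# residual matrix, computed via eigen() on its cross-product.
ca_inertia_oracle <- function(m) {
  p <- m / sum(m)
  r <- rowSums(p)
  cl <- colSums(p)
  keep <- cl > 0
  p <- p[, keep, drop = FALSE]
  cl <- cl[keep]
  s <- (p - outer(r, cl)) / sqrt(outer(r, cl))
  ev <- eigen(crossprod(s), symmetric = TRUE)$values
  ev[ev > max(ev, 0) * 1e-10]
}

# Random small CDS tibble (valid codon structure, no stops inside).
random_cds_tbl <- function(n_genes = 3, n_codons = 50, strain = "s1") {
  sense <- unlist(FAMILIES_STD, use.names = FALSE)
  tibble::tibble(
    strain = strain,
    gene = sprintf("g%02d", seq_len(n_genes)),
    seq = vapply(seq_len(n_genes), function(i) {
      paste(sample(sense, n_codons, replace = TRUE), collapse = "")
    }, character(1))
  )
}

# Two-feature GenBank flat file exercising join() and complement();
# CDS1 = ATG AAA TTT TAA at 1..12, CDS2 = revcomp spliced across two exons.
write_genbank_fixture <- function(path) {
  genome <- paste0(
    "atgaaatttta", "a",          # 1..12   CDS1 (plus strand)
    "gggg",                      # 13..16  spacer
    "ttacatcgg",                 # 17..25  exon2 of CDS2 (minus strand)
    "cc",                        # 26..27  spacer
    "ccctaacat"                  # 28..36  exon1 of CDS2 (minus strand)
  )
  stopifnot(nchar(genome) == 36)
  lines <- c(
    "LOCUS       TESTSEQ                   36 bp    DNA     circular 01-JAN-2020",
    "DEFINITION  synthetic two-CDS fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..36",
    "                     /organism=\"synthetic construct\"",
    "     CDS             1..12",
    "                     /gene=\"atp6\"",
    "                     /product=\"ATP synthase subunit 6\"",
    "     CDS             complement(join(17..25,28..36))",
    "                     /product=\"hypothetical protein\"",
    "ORIGIN",
    "        1 atgaaatttt aagggyttac atcggcceee",  # placeholder, fixed below
    "//"
  )
  # write the real sequence in GenBank 60-per-line blocks of 10
  blocks <- substring(genome, seq(1, 36, 10), pmin(seq(1, 36, 10) + 9, 36))
  lines[grep("^        1", lines)] <-
    paste0("        1 ", paste(blocks, collapse = " "))
  writeLines(lines, path)
  invisible(genome)
}
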