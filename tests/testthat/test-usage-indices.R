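code1 <- genetic_code(1)

counts_from <- function(...) {
  x <- c(...)
  v <- stats::setNames(numeric(64), names(code1$codon_to_aa))
  v[names(x)] <- x
  v
}

test_that("RSCU follows the k * n / total definition, families sum to k", {
  # 2-codon family, uniform and exclusive usage
  v <- rscu_vector(counts_from(TTT = 5, TTC = 5))
  expect_equal(unname(v[c("TTT", "TTC")]), c(1, 1))
  v <- rscu_vector(counts_from(TTT = 10, TTC = 0))
  expect_equal(unname(v[c("TTT", "TTC")]), c(2, 0))
  # 4-codon family (4,2,1,1) -> (2, 1, 0.5, 0.5)
  v <- rscu_vector(counts_from(GCT = 4, GCC = 2, GCA = 1, GCG = 1))
  expect_equal(unname(v[c("GCT", "GCC", "GCA", "GCG")]), c(2, 1, 0.5, 0.5))
  # unobserved families are NA, not zero
  expect_true(is.na(v[["AAA"]]))

  # family-sum conservation on random tables
  withr::local_seed(21)
  for (i in 1:20) {
    v <- rscu_vector(random_count_table())
    for (aa in names(FAMILIES_STD)) {
      fam <- FAMILIES_STD[[aa]]
      if (all(!is.na(v[fam]))) {
        expect_equal(sum(v[fam]), length(fam), tolerance = 1e-9)
      }
    }
  }
})

test_that("tidy rscu() computes per-group values matching rscu_vector()", {
  withr::local_seed(3)
  tbl <- random_cds_tbl(n_genes = 2, n_codons = 80)
  out <- rscu(count_codons(tbl))
  for (g in unique(out$gene)) {
    sub <- out[out$gene == g, ]
    v <- rscu_vector(codon_count_vector(tbl$seq[tbl$gene == g]))
    expect_equal(stats::setNames(sub$rscu, sub$codon)[names(v)], v)
  }
})

test_that("ENC hits its theoretical extremes", {
  # one codon per amino acid -> 20
  one_each <- counts_from(stats::setNames(
    rep(30, 20), vapply(FAMILIES_STD, `[[`, character(1), 1)
  ))
  expect_equal(enc_wright(one_each), 20)
  # every sense codon used equally -> capped at 61
  uniform <- stats::setNames(rep(10, 64), names(code1$codon_to_aa))
  expect_equal(enc_wright(uniform), 61)
})

test_that("ENC agrees with the brute-force Wright estimator", {
  withr::local_seed(42)
  for (i in 1:100) {
    x <- random_count_table(lambda = sample(c(2, 5, 20), 1))
    expect_equal(enc_wright(x), enc_bruteforce(x), tolerance = 1e-9)
  }
})

test_that("ENC and CAI are invariant to codon order within the gene", {
  withr::local_seed(8)
  s <- paste(sample(unlist(FAMILIES_STD), 120, replace = TRUE), collapse = "")
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  s2 <- paste(sample(cods), collapse = "")
  w <- cai_weights(random_count_table(20))
  expect_equal(enc_wright(codon_count_vector(s)),
               enc_wright(codon_count_vector(s2)))
  expect_equal(cai_index(codon_count_vector(s), w),
               cai_index(codon_count_vector(s2), w))
})

test_that("CAI weights and index follow the geometric-mean definition", {
  # a reference covering only Phe floors every other family, with a warning
  expect_warning(w <- cai_weights(counts_from(TTT = 10, TTC = 5)),
                 "floor applied")
  wv <- stats::setNames(w$w, w$codon)
  expect_equal(unname(wv[c("TTT", "TTC")]), c(1, 0.5))
  w <- suppressWarnings(cai_weights(counts_from(TTT = 7, TTC = 7)))
  wv <- stats::setNames(w$w, w$codon)
  expect_equal(unname(wv[c("TTT", "TTC")]), c(1, 1))
  # zero-count codon floors at 0.01, never 0
  expect_true(all(w$w >= 0.01))

  # gene using only weight-1 codons -> CAI = 1
  ref <- random_count_table(20)
  w <- cai_weights(ref)
  wv <- stats::setNames(w$w, w$codon)
  best <- vapply(FAMILIES_STD, function(fam) {
    fam[which.max(wv[fam])]
  }, character(1))
  gene <- counts_from(stats::setNames(rep(4, 20), unname(best)))
  expect_equal(cai_index(gene, w), 1)

  # log-domain brute force on a mixed 10-codon toy gene
  toy <- counts_from(TTT = 3, TTC = 2, GCT = 4, AAA = 1)
  elig <- c(rep("TTT", 3), rep("TTC", 2), rep("GCT", 4), "AAA")
  expect_equal(cai_index(toy, w), exp(mean(log(wv[elig]))))

  # constant weights: every codon at w = 0.5 -> CAI 0.5
  whalf <- w; whalf$w <- rep(0.5, nrow(whalf))
  expect_equal(cai_index(toy, whalf), 0.5)
})

test_that("CBI is 1 at maximal bias, 0 at random usage, negative at avoidance", {
  optimal <- c("TTT", "GCT", "AAA")
  only_opt <- counts_from(TTT = 10, GCT = 5, AAA = 8)
  expect_equal(cbi_index(only_opt, optimal), 1)
  # uniform within-family usage = exactly the random expectation
  uniform <- stats::setNames(rep(6, 64), names(code1$codon_to_aa))
  expect_equal(cbi_index(uniform, optimal), 0)
  # avoiding the optimal codons drives CBI negative
  avoid <- counts_from(TTC = 10, GCC = 5, GCA = 5, AAG = 8)
  expect_lt(cbi_index(avoid, optimal), 0)
  # degenerate: no multi-codon family in the optimal set and no usage
  expect_true(is.na(cbi_index(counts_from(ATG = 5), optimal)))
})

test_that("FOP is the optimal fraction of synonymous codons", {
  optimal <- c("TTT", "GCT")
  x <- counts_from(TTT = 30, TTC = 50, GCT = 0, GCA = 40)
  expect_equal(fop_index(x, optimal), 30 / 120)
  expect_equal(fop_index(counts_from(TTT = 9), optimal), 1)
  expect_equal(fop_index(x, character(0)), 0)
})

test_that("GRAVY and AROMO match the residue tables", {
  expect_equal(gravy("GGGG"), -0.4)
  expect_equal(gravy("IF"), 3.65)
  # Lys/Arg-rich ribosomal-protein-like peptide is hydrophilic
  expect_lt(gravy("KKRKNKRSEK"), 0)
  expect_error(gravy("GGXG"), "position 3")
  expect_equal(aromo("FFFF"), 1)
  expect_equal(aromo("GGGG"), 0)
  expect_equal(aromo("FYWA"), 0.75)
})

test_that("indices on pooled counts equal indices on concatenated genes", {
  withr::local_seed(17)
  tbl <- random_cds_tbl(n_genes = 3, n_codons = 60)
  pooled <- Reduce(`+`, lapply(tbl$seq, codon_count_vector))
  concat <- codon_count_vector(paste(tbl$seq, collapse = ""))
  expect_equal(pooled, concat)
  expect_equal(enc_wright(pooled), enc_wright(concat))
  expect_equal(rscu_vector(pooled), rscu_vector(concat))
})

test_that("stronger within-family bias lowers ENC towards 20", {
  withr::local_seed(33)
  enc_at <- vapply(c(Inf, 5, 0.5), function(conc) {
    spec <- sim_spec(
      n_strains = 1,
      genes = tibble::tibble(gene = "g1", length_nt = 3000,
                             target_gc3 = 0.5,
                             bias_concentration = conc),
      hydrophilic_genes = character(0), seed = 4
    )
    seqs <- simulate_strain(spec, 1)
    enc_wright(codon_count_vector(seqs$seq[[1]]))
  }, numeric(1))
  expect_true(all(diff(enc_at) < 0))
  expect_gt(enc_at[[1]], 55)   # uniform tilt at GC3 = 0.5 is near 61
  expect_lt(enc_at[[3]], 35)   # strong bias regime
})
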