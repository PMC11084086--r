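test_that("expression split takes max(1, floor(fraction*n)) per end", {
  enc12 <- tibble::tibble(gene = sprintf("g%02d", 1:12),
                          enc = c(31, 25, 40, 55, 33, 45, 29, 50, 38,
                                  42, 36, 60))
  sp <- expression_split(enc12, 0.10)
  expect_equal(sp$n_take, 1L)               # floor(1.2) with min-1 rule
  expect_equal(sp$high, "g02")              # lowest ENC
  expect_equal(sp$low, "g12")               # highest ENC
  expect_length(intersect(sp$high, sp$low), 0)

  enc20 <- tibble::tibble(gene = sprintf("g%02d", 1:20), enc = 20 + 1:20)
  sp20 <- expression_split(enc20, 0.10)
  expect_equal(sp20$n_take, 2L)
  expect_equal(sp20$high, c("g01", "g02"))
  expect_equal(sp20$low, c("g19", "g20"))

  # minimal case: the lower-ENC gene goes to the high-expression set
  sp2 <- expression_split(tibble::tibble(gene = c("a", "b"),
                                         enc = c(50, 30)), 0.10)
  expect_equal(sp2$high, "b")
  expect_equal(sp2$low, "a")

  # ENC ties break lexically by gene name
  spt <- expression_split(tibble::tibble(gene = c("z", "a", "m"),
                                         enc = c(30, 30, 45)), 0.10)
  expect_equal(spt$high, "a")

  # a fraction at or above one half would overlap the sets
  expect_error(expression_split(enc12, 0.5), "overlap")
})

test_that("delta-RSCU subtracts per codon and conserves family sums", {
  code <- genetic_code()
  mk <- function(v) {
    tibble::tibble(codon = names(v),
                   aa = unname(code$codon_to_aa[names(v)]),
                   rscu = unname(v))
  }
  high <- mk(rscu_vector(c(TTT = 10, TTC = 0)))
  low <- mk(rscu_vector(c(TTT = 5, TTC = 5)))
  d <- delta_rscu(high, low)
  dv <- stats::setNames(d$delta_rscu, d$codon)
  expect_equal(unname(dv[c("TTT", "TTC")]), c(1, -1))
  # identical vectors -> all-zero deltas where observed
  d0 <- delta_rscu(high, high)
  expect_true(all(d0$delta_rscu[!is.na(d0$delta_rscu)] == 0))
  # missing in either side -> NA
  expect_true(is.na(dv[["GGG"]]))

  # family-sum conservation on random tables
  withr::local_seed(7)
  for (i in 1:10) {
    h <- mk(rscu_vector(random_count_table()))
    l <- mk(rscu_vector(random_count_table()))
    d <- delta_rscu(h, l)
    dv <- stats::setNames(d$delta_rscu, d$codon)
    for (aa in names(FAMILIES_STD)) {
      fam <- FAMILIES_STD[[aa]]
      if (length(fam) > 1 && all(!is.na(dv[fam]))) {
        expect_equal(sum(dv[fam]), 0, tolerance = 1e-9)
      }
    }
  }
})

test_that("classification uses strict thresholds on both axes", {
  tbl <- tibble::tibble(
    codon = c("TTT", "TTC", "TTA", "TTG"),
    aa = c("F", "F", "L", "L"),
    rscu = c(1.2, 0.9, 1.0, 1.5)
  )
  delta <- tibble::tibble(codon = tbl$codon,
                          delta_rscu = c(0.10, 0.10, 0.08, NA))
  cls <- classify_codons(tbl, delta)
  expect_equal(cls$optimal, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(cls$high_frequency, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(cls$highly_expressed, c(TRUE, TRUE, FALSE, FALSE))
  # containment: optimal implies both flags
  expect_true(all(!cls$optimal | (cls$high_frequency & cls$highly_expressed)))
})

test_that("forced preferred codons are recovered from simulated data", {
  withr::local_seed(51)
  code <- genetic_code()
  # one preferred codon per multi-codon family
  preferred <- vapply(code$families[lengths(code$families) > 1],
                      function(fam) sample(fam, 1), character(1))
  genes <- tibble::tibble(
    gene = sprintf("g%02d", 1:12),
    length_nt = 6000,
    target_gc3 = 0.5,
    bias_concentration = Inf
  )
  spec <- sim_spec(
    n_strains = 1, genes = genes, hydrophilic_genes = character(0),
    preferred_codons = unname(preferred),
    preferred_genes = c("g01", "g02"),
    preference_boost = 12, seed = 99
  )
  seqs <- simulate_strain(spec, 1)
  cls <- optimal_codon_analysis(count_codons(seqs, code), code)
  flagged <- cls$codon[cls$optimal]
  precision <- mean(flagged %in% preferred)
  recall <- mean(preferred %in% flagged)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
  # count containment invariant
  n <- colSums(cls[c("high_frequency", "highly_expressed", "optimal")])
  expect_lte(n[["optimal"]], min(n[["high_frequency"]],
                                 n[["highly_expressed"]]))
})
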