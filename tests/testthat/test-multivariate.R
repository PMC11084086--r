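test_that("CA of identical rows has zero total inertia and no axes", {
  m <- matrix(rep(c(1, 2, 3, 4), each = 3), nrow = 3)
  out <- correspondence_analysis(m)
  expect_equal(out$total_inertia, 0, tolerance = 1e-12)
  expect_equal(out$n_axes, 0)
})

test_that("CA inertias match the brute-force eigendecomposition", {
  m <- matrix(c(4, 2, 1, 1,
                1, 5, 2, 0,
                2, 2, 6, 3), nrow = 3, byrow = TRUE)
  out <- correspondence_analysis(m)
  oracle <- ca_inertia_oracle(m)
  expect_equal(out$inertia$inertia, oracle, tolerance = 1e-9)
  expect_equal(sum(out$inertia$inertia_pct), 100, tolerance = 1e-9)
  # axes ordered by decreasing inertia
  expect_true(all(diff(out$inertia$inertia) <= 1e-12))
})

test_that("CA total inertia equals chi-square / grand total", {
  withr::local_seed(19)
  for (i in 1:10) {
    m <- matrix(stats::rpois(5 * 8, 6) + 0.5, nrow = 5)
    out <- correspondence_analysis(m)
    chi2 <- suppressWarnings(stats::chisq.test(m)$statistic)
    expect_equal(out$total_inertia, unname(chi2) / sum(m),
                 tolerance = 1e-9)
  }
})

test_that("CA is invariant to global row scaling", {
  withr::local_seed(23)
  m <- matrix(stats::runif(4 * 6, 0.1, 2), nrow = 4)
  a <- correspondence_analysis(m)
  b <- correspondence_analysis(3.7 * m)
  expect_equal(a$inertia, b$inertia, tolerance = 1e-9)
  expect_equal(a$row_coords$axis1, b$row_coords$axis1, tolerance = 1e-9)
})

test_that("CA agrees with vegan's unconstrained correspondence analysis", {
  skip_if_not_installed("vegan")
  withr::local_seed(29)
  m <- matrix(stats::rpois(6 * 10, 5) + 1, nrow = 6)
  out <- correspondence_analysis(m)
  vg <- vegan::cca(as.data.frame(m))
  ev <- as.numeric(vg$CA$eig)
  expect_equal(out$inertia$inertia[seq_along(ev)], ev, tolerance = 1e-8)
})

test_that("rscu_matrix produces the fixed 59-codon space with 0 imputation", {
  withr::local_seed(31)
  tbl <- random_cds_tbl(n_genes = 3, n_codons = 25)
  rs <- rscu(count_codons(tbl))
  m <- rscu_matrix(rs, rows = "gene")
  expect_equal(ncol(m) - 1L, 59L)
  expect_false(any(is.na(m[-1])))
  # unobserved families show as 0, observed values carried through
  long <- tidyr::pivot_longer(m, -gene, names_to = "codon")
  merged <- dplyr::left_join(long, rs, by = c("gene", "codon"))
  expect_equal(merged$value, tidyr::replace_na(merged$rscu, 0))
})

test_that("indicator correlations match the textbook formula", {
  withr::local_seed(37)
  d <- tibble::tibble(
    a = stats::rnorm(12), b = stats::rnorm(12)
  )
  d$dup <- d$a
  d$neg <- -d$a
  cm <- indicator_correlations(d, c("a", "b", "dup", "neg"))
  g <- function(v1, v2) cm[cm$var1 == v1 & cm$var2 == v2, ]
  expect_equal(g("a", "dup")$r, 1)
  expect_lt(g("a", "dup")$p, 1e-12)
  expect_equal(g("a", "dup")$stars, "**")
  expect_equal(g("a", "neg")$r, -1)
  # direct covariance oracle
  r_manual <- sum((d$a - mean(d$a)) * (d$b - mean(d$b))) /
    sqrt(sum((d$a - mean(d$a))^2) * sum((d$b - mean(d$b))^2))
  expect_equal(g("a", "b")$r, r_manual, tolerance = 1e-12)
  # symmetry and unit diagonal
  expect_equal(g("b", "a")$r, g("a", "b")$r)
  expect_equal(g("a", "a")$r, 1)
  # constant column yields NA, not an error
  d$const <- 1
  cm2 <- indicator_correlations(d, c("a", "const"))
  expect_true(is.na(cm2[cm2$var1 == "a" & cm2$var2 == "const", ]$r))
  # square accessor
  m <- cor_matrix(cm)
  expect_equal(m["a", "neg"], -1)
  expect_true(isSymmetric(m))
})

test_that("clustering merges identical profiles first and exports Newick", {
  m <- rbind(
    s1 = c(1, 0, 2, 1), s2 = c(1, 0, 2, 1),     # identical pair
    s3 = c(5, 5, 0, 0), s4 = c(0, 5, 5, 5)
  )
  tr <- rscu_cluster(m)
  expect_equal(min(tr$hclust$height), 0)
  expect_setequal(tr$hclust$labels[-tr$hclust$merge[1, ]], c("s1", "s2"))
  expect_s3_class(tr$phylo, "phylo")
  expect_setequal(tr$phylo$tip.label, rownames(m))
  # newick parses back to the same tips
  reread <- ape::read.tree(text = tr$newick)
  expect_setequal(reread$tip.label, rownames(m))
})

test_that("close pair merges first; topology matches manual linkage", {
  # 3 points on a line: distances d(a,b)=1, d(b,c)=9, d(a,c)=10
  m <- cbind(x = c(a = 0, b = 1, c = 10), y = 0)
  tr <- rscu_cluster(m)
  expect_setequal(tr$hclust$labels[-tr$hclust$merge[1, ]], c("a", "b"))
  # 4-strain fixture agglomerated by hand (average linkage):
  # pts 0, 2, 9, 10 -> (c,d) merge at 1, (a,b) at 2, then the two
  # clusters at mean cross-distance (9+10+7+8)/4 = 8.5
  m4 <- cbind(x = c(a = 0, b = 2, c = 9, d = 10), y = 0)
  tr4 <- rscu_cluster(m4)
  expect_equal(sort(tr4$hclust$height), c(1, 2, 8.5))
  expect_equal(ape::dist.topo(
    ape::unroot(tr4$phylo),
    ape::unroot(ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);"))
  )[[1]], 0)
})

test_that("clustering is invariant to row order up to topology", {
  withr::local_seed(41)
  m <- matrix(stats::runif(5 * 8), nrow = 5,
              dimnames = list(paste0("s", 1:5), NULL))
  t1 <- rscu_cluster(m)
  t2 <- rscu_cluster(m[sample(5), ])
  expect_equal(ape::dist.topo(ape::unroot(t1$phylo),
                              ape::unroot(t2$phylo))[[1]], 0)
})

test_that("duplicate strain labels are rejected", {
  m <- matrix(1:8, nrow = 2, dimnames = list(c("s1", "s1"), NULL))
  expect_error(rscu_cluster(m), "duplicate")
})
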