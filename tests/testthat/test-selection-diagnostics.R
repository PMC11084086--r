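test_that("expected-ENC curve hits its closed-form anchor points", {
  expect_identical(enc_expected(0.5), 60.5)
  expect_identical(enc_expected(0), 31)
  expect_identical(enc_expected(1), 32)
  expect_error(enc_expected(1.2), "0, 1")
  # maximum near 0.5; symmetric under s -> 1-s up to the linear +s term
  grid <- seq(0, 1, by = 0.01)
  vals <- enc_expected(grid)
  expect_equal(grid[which.max(vals)], 0.5, tolerance = 0.02)
  expect_equal(vals - grid, rev(vals - grid), tolerance = 1e-9)
})

test_that("ENC ratio is the relative shortfall", {
  expect_equal(enc_ratio(40, 40), 0)
  expect_equal(enc_ratio(40, 30), 0.25)
  expect_error(enc_ratio(-1, 5))
})

test_that("neutrality fit recovers a collinear relationship exactly", {
  d <- tibble::tibble(gc3 = c(0.1, 0.2, 0.3), gc12 = c(0.2, 0.3, 0.4))
  fit <- neutrality_fit(d)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0.1)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$mutation_dominant)
  expect_equal(glance(fit)$n_points, 3)
  expect_equal(tidy(fit)$estimate, c(0.1, 1))
})

test_that("independent GC12/GC3 gives a null slope and p > 0.05", {
  withr::local_seed(2)
  d <- tibble::tibble(gc3 = stats::runif(1000, 0.05, 0.45),
                      gc12 = 0.33 + stats::rnorm(1000, 0, 0.02))
  fit <- neutrality_fit(d)
  expect_lt(abs(fit$slope), 0.05)
  expect_gt(fit$p_value, 0.05)
  expect_false(fit$mutation_dominant)
})

test_that("degenerate neutrality inputs are handled", {
  expect_error(neutrality_fit(tibble::tibble(gc3 = 0.1, gc12 = 0.2)),
               "at least 3")
  expect_warning(
    fit <- neutrality_fit(tibble::tibble(gc3 = rep(0.1, 4),
                                         gc12 = c(0.1, 0.2, 0.3, 0.4))),
    "constant"
  )
  expect_true(is.na(fit$slope))
})

test_that("PR2 point sits at the centre for symmetric counts", {
  x <- stats::setNames(numeric(64), names(genetic_code()$codon_to_aa))
  x[c("GGA", "GGT", "GGG", "GGC")] <- c(7, 7, 3, 3)  # A3=T3, G3=C3
  p <- pr2_point(x)
  expect_equal(p$at_bias, 0.5)
  expect_equal(p$gc_bias, 0.5)
  expect_true(is.na(p$quadrant))
})

test_that("PR2 tallies fourfold thirds exactly and assigns quadrants", {
  code <- genetic_code()
  x <- stats::setNames(numeric(64), names(code$codon_to_aa))
  # fourfold families: GG (Gly) and CT (Leu quartet); TT (Phe/Leu) is not
  x[c("GGA", "GGT", "GGC", "CTT", "CTC")] <- c(2, 5, 4, 3, 1)
  x[c("TTT", "TTA")] <- c(100, 100)  # must be ignored in fourfold mode
  p <- pr2_point(x, code, mode = "fourfold")
  expect_equal(p$a3, 2); expect_equal(p$t3, 8)
  expect_equal(p$g3, 0); expect_equal(p$c3, 5)
  expect_equal(p$at_bias, 2 / 10)
  expect_equal(p$gc_bias, 0)
  expect_equal(p$quadrant, 3L)  # T > A and C > G
  # all_synonymous mode now sees the two-fold families too
  p2 <- pr2_point(x, code, mode = "all_synonymous")
  expect_equal(p2$t3, 8 + 100)
  expect_equal(p2$a3, 2 + 100)

  # quadrant convention: 1 = A>T & G>C, 4 = A>T & C>G
  x2 <- stats::setNames(numeric(64), names(code$codon_to_aa))
  x2[c("GGA", "GGG")] <- c(5, 3)
  expect_equal(pr2_point(x2)$quadrant, 1L)
  x2[c("GGA", "GGG", "GGC")] <- c(5, 1, 3)
  expect_equal(pr2_point(x2)$quadrant, 4L)
})

test_that("strand-symmetrised third positions land exactly on centre", {
  # under parity rule 2, a table whose third-position usage is balanced
  # between complementary bases within each family must sit at (0.5, 0.5)
  withr::local_seed(6)
  code <- genetic_code()
  x <- stats::setNames(as.numeric(stats::rpois(64, 10)),
                       names(code$codon_to_aa))
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  partner <- paste0(substr(names(x), 1, 2), comp[substr(names(x), 3, 3)])
  sym <- x + x[partner]
  names(sym) <- names(x)
  p <- pr2_point(sym)
  expect_equal(p$at_bias, 0.5)
  expect_equal(p$gc_bias, 0.5)
})

test_that("mutation-only simulated genes track the expected curve", {
  withr::local_seed(14)
  targets <- seq(0.35, 0.65, length.out = 6)
  genes <- tibble::tibble(
    gene = sprintf("g%d", seq_along(targets)),
    length_nt = 6000, target_gc3 = targets, bias_concentration = Inf
  )
  spec <- sim_spec(n_strains = 1, genes = genes,
                   hydrophilic_genes = character(0), seed = 10)
  d <- selection_diagnostics(simulate_strain(spec, 1))
  expect_lt(mean(abs(d$enc_ratio_pct)), 2)
})
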