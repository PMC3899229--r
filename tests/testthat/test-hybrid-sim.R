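test_that("parental simulator hits its calibration targets deterministically", {
  spec <- synthetic_pop_spec(n_loci = 39, target_fst = 0.25,
                             target_Ho = c(W = 0.46, D = 0.71), seed = 1)
  gm <- simulate_parental_pops(spec)
  cal <- attr(gm, "calibration")
  expect_lt(abs(weir_cockerham_theta(gm, c("W", "D")) - 0.25), 0.03)
  expect_lt(abs(cal$realized_Ho[1] - 0.46), 0.05)
  expect_lt(abs(cal$realized_Ho[2] - 0.71), 0.05)
  # same spec and seed reproduce bit-identical matrices; other seeds differ
  gm2 <- simulate_parental_pops(spec)
  expect_identical(gm$a1, gm2$a1)
  gm3 <- simulate_parental_pops(synthetic_pop_spec(seed = 2))
  expect_false(identical(gm$a1, gm3$a1))
  # weak divergence limit
  lo <- suppressWarnings(simulate_parental_pops(synthetic_pop_spec(
    n_loci = 60, target_fst = 0.011, target_Ho = c(0.6, 0.6), seed = 4)))
  expect_lte(weir_cockerham_theta(lo, c("W", "D")), 0.05)
  # infeasible heterozygosity is rejected before sampling
  expect_error(simulate_parental_pops(synthetic_pop_spec(
    target_Ho = c(0.9, 0.7), target_Na = c(2, 7), seed = 1)), "infeasible")
})

test_that("frequency-pool crossing follows its sampling model", {
  # fixed parental pools: all offspring heterozygous (1,2)
  A <- toy_gm(matrix(1L, 5, 3), matrix(1L, 5, 3), rep("A", 5))
  B <- toy_gm(matrix(2L, 5, 3), matrix(2L, 5, 3), rep("B", 5),
              ids = sprintf("b%d", 1:5))
  off <- simulate_cross(A, B, 50, seed = 1)
  expect_true(all(off$a1 == 1L & off$a2 == 2L))
  # same-pool cross converges to the pool frequencies (chi-square GOF)
  pool <- hwe_gm(40, list(c(.5, .3, .2)), seed = 6)
  self <- simulate_cross(pool, pool, 1000, seed = 7)
  obs <- table(factor(c(self$a1, self$a2), levels = 1:3))
  pool_f <- table(factor(c(pool$a1, pool$a2), levels = 1:3)) / (2 * 40)
  expect_gt(chisq.test(obs, p = as.numeric(pool_f))$p.value, 0.001)
  # reproducible under a fixed seed
  expect_identical(simulate_cross(A, B, 10, seed = 3)$a1,
                   simulate_cross(A, B, 10, seed = 3)$a1)
  # undefined locus in a pool is an error
  A2 <- A; A2$a1[, 2] <- NA; A2$a2[, 2] <- NA
  expect_error(simulate_cross(A2, B, 5, seed = 1), "no alleles")
})

test_that("expected ancestry follows the pedigree", {
  expect_equal(expected_ancestry("F1"), 0.5)
  expect_equal(expected_ancestry("F2"), 0.5)
  expect_equal(expected_ancestry(c("BC1W", "BC2W", "BC3W")),
               c(0.75, 0.875, 0.9375))
  expect_equal(expected_ancestry(c("BC1D", "BC2D", "BC3D")),
               1 - c(0.75, 0.875, 0.9375))
  expect_error(expected_ancestry("BC9"), "unknown")
})

test_that("class panels realize their Mendelian ancestry expectations", {
  # diagnostic parents: count wolf alleles directly
  L <- 39; n <- 60
  W <- toy_gm(matrix(1L, n, L), matrix(1L, n, L), rep("W", n),
              ids = sprintf("w%02d", 1:n))
  D <- toy_gm(matrix(2L, n, L), matrix(2L, n, L), rep("D", n),
              ids = sprintf("d%02d", 1:n))
  sim <- simulate_class_panel(W, D, n_per_class = n, seed = 7)
  expect_equal(n_ind(sim$gm), n * 10)
  wfrac <- function(cl) {
    idx <- sim$gm$meta$group == cl
    mean(c(sim$gm$a1[idx, ], sim$gm$a2[idx, ]) == 1L)
  }
  # F1 exactly heterozygous everywhere
  idx <- sim$gm$meta$group == "F1"
  expect_true(all(sim$gm$a1[idx, ] != sim$gm$a2[idx, ]))
  for (cl in c("F2", "BC1W", "BC2W", "BC3W", "BC1D", "BC2D")) {
    e <- expected_ancestry(cl)
    se <- sqrt(e * (1 - e) / (2 * L * n))
    expect_lt(abs(wfrac(cl) - e), 3 * se + 0.01)
  }
  # BC1W is homozygous wolf at about half its loci
  idx <- sim$gm$meta$group == "BC1W"
  expect_equal(mean(sim$gm$a1[idx, ] == 1L & sim$gm$a2[idx, ] == 1L), 0.5,
               tolerance = 0.05)
  # determinism and the alternative third-backcross pedigree
  sim2 <- simulate_class_panel(W, D, n_per_class = n, seed = 7)
  expect_identical(sim$gm$a1, sim2$gm$a1)
  alt <- simulate_class_panel(W, D, classes = c("BC3W"), n_per_class = n,
                              seed = 7, bc3_from_f2 = TRUE)
  expect_equal(alt$pedigree[["BC3W"]], "F2 x W")
  af <- mean(c(alt$gm$a1, alt$gm$a2) == 1L)
  expect_equal(af, 0.75, tolerance = 0.03)  # F2 x W carries 3/4 wolf genome
})

test_that("simulated parental populations sit at Hardy-Weinberg", {
  par <- simulate_parental_pops(synthetic_pop_spec(n_loci = 20, seed = 9))
  for (g in c("W", "D")) {
    r <- fis_hwe_test(par, g, n_perm = 150, seed = 2)
    expect_gt(r$p_value, 0.01)
  }
})
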