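test_that("diversity summary matches closed forms", {
  # one locus, 10 diploids at p = (0.5, 0.5): UHe = (20/19) * 0.5
  gm <- toy_gm(matrix(rep(c(1L, 2L), each = 5)), matrix(rep(c(1L, 2L), each = 5)),
               rep("A", 10))
  d <- suppressWarnings(diversity_summary(gm, "A"))
  expect_equal(d$UHe, (20 / 19) * 0.5, tolerance = 1e-12)
  # monomorphic locus: Ho = UHe = 0
  gm0 <- toy_gm(matrix(1L, 4, 1), matrix(1L, 4, 1), rep("A", 4))
  d0 <- diversity_summary(gm0, "A")
  expect_equal(d0$Ho, 0); expect_equal(d0$UHe, 0)
  # private alleles: allele 7 only in group A
  gmP <- toy_gm(rbind(7L, 1L, 1L, 1L), rbind(7L, 1L, 1L, 1L),
                c("A", "A", "B", "B"))
  expect_gte(diversity_summary(gmP, "A")$Np, 1)
})

test_that("F_IS sign and permutation null behave correctly", {
  # all heterozygous: excess heterozygosity, F_IS < 0
  gm_het <- toy_gm(matrix(1L, 12, 1), matrix(2L, 12, 1), rep("A", 12))
  r <- fis_hwe_test(gm_het, "A", n_perm = 200, seed = 1)
  expect_lt(r$Fis, 0)
  # fully inbred: all homozygotes at p = 0.5 gives F_IS = 1
  gm_hom <- toy_gm(matrix(rep(c(1L, 2L), 6)), matrix(rep(c(1L, 2L), 6)), rep("A", 12))
  expect_equal(fis_hwe_test(gm_hom, "A", n_perm = 200, seed = 1)$Fis, 1,
               tolerance = 1e-12)
  expect_error(fis_hwe_test(toy_gm(matrix(1L, 4, 1), matrix(1L, 4, 1),
                                   rep("A", 4)), "A"), "monomorphic")
  # p-values roughly uniform under HWE (KS on 30 replicate datasets)
  ps <- vapply(1:30, function(s) {
    gm <- hwe_gm(25, list(c(.5, .5), c(.3, .3, .4)), seed = 1000 + s)
    fis_hwe_test(gm, "A", n_perm = 120, seed = s)$p_value
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("UHe >= Ho if and only if F_IS >= 0 (algebraic identity)", {
  for (s in 1:10) {
    gm <- hwe_gm(15, list(c(.6, .4), c(.2, .3, .5), c(.25, .25, .5)), seed = s)
    d <- diversity_summary(gm, "A")
    expect_equal(d$Fis >= 0, d$UHe >= d$Ho)
  }
})

test_that("pairwise linkage tests detect dependence and keep the null rate", {
  # duplicated locus = perfect association
  set.seed(5)
  l1 <- cbind(sample(1:3, 40, TRUE), sample(1:3, 40, TRUE))
  gm_dup <- toy_gm(cbind(l1[, 1], l1[, 1]), cbind(l1[, 2], l1[, 2]), rep("A", 40))
  r <- ld_pairwise_test(gm_dup, "A", n_perm = 200, seed = 2)
  expect_lte(r$p_matrix["L1", "L2"], 1 / 201 + 1e-12)
  expect_equal(r$pct_LE, 100)
  # single polymorphic locus: error
  gm1 <- toy_gm(cbind(c(1L, 2L, 1L), 1L), cbind(c(2L, 2L, 1L), 1L), rep("A", 3))
  expect_error(ld_pairwise_test(gm1, "A"), "polymorphic")
  # independent loci: few significant pairs after Bonferroni
  gm_ind <- hwe_gm(40, replicate(6, c(.4, .3, .3), simplify = FALSE), seed = 11)
  r2 <- ld_pairwise_test(gm_ind, "A", n_perm = 150, seed = 3)
  expect_lte(r2$n_significant, 2)
  expect_equal(r2$n_tested, choose(6, 2))
})

test_that("probabilities of identity match closed forms and multiply", {
  gm <- hwe_gm(20, list(c(.5, .5), c(.5, .5)), seed = 1)
  fr <- allele_frequencies(gm)
  # impose exact frequencies through a handmade table
  fr$freq$A$L1 <- c("1" = .5, "2" = .5)
  fr$freq$A$L2 <- c("1" = .5, "2" = .5)
  expect_equal(pid_unrelated(fr, "A", "L1"), 0.375, tolerance = 1e-12)
  expect_equal(pid_sibs(fr, "A", "L1"), 0.59375, tolerance = 1e-12)
  expect_equal(pid_unrelated(fr, "A", c("L1", "L2")), 0.375^2, tolerance = 1e-12)
  fr$freq$A$L1 <- c("1" = 1)
  expect_equal(pid_unrelated(fr, "A", "L1"), 1)
  expect_equal(pid_sibs(fr, "A", "L1"), 1)
  # PIDsibs >= PID over random frequency vectors, and both shrink with loci
  set.seed(99)
  for (i in 1:200) {
    p <- as.numeric(rmultinom(1, 50, rep(1, sample(2:6, 1)))) / 50
    p <- p[p > 0]
    frx <- fr
    frx$freq$A$L1 <- setNames(p, seq_along(p))
    expect_gte(pid_sibs(frx, "A", "L1"), pid_unrelated(frx, "A", "L1"))
  }
})

test_that("Weir-Cockerham theta agrees with the ANOVA oracle", {
  # frozen toy: two demes of 10, allele-1 counts 15/20 vs 5/20
  a1 <- c(rep(1L, 5), rep(1L, 5), rep(1L, 5), rep(2L, 5))
  a2 <- c(rep(1L, 5), rep(2L, 5), rep(2L, 5), rep(2L, 5))
  gm <- toy_gm(matrix(a1), matrix(a2), rep(c("A", "B"), each = 10))
  expect_equal(weir_cockerham_theta(gm, c("A", "B")), 0.377777777777778,
               tolerance = 1e-12)
  expect_equal(weir_cockerham_theta(gm, c("A", "B")),
               wc_theta_oracle(gm, c("A", "B")), tolerance = 1e-12)
  # random multilocus, multiallelic, with missing data
  set.seed(17)
  for (rep in 1:5) {
    a1 <- matrix(sample(1:4, 120, TRUE), 30, 4)
    a2 <- matrix(sample(1:4, 120, TRUE), 30, 4)
    gm <- toy_gm(a1, a2, rep(c("A", "B", "C"), each = 10))
    expect_equal(weir_cockerham_theta(gm, c("A", "B", "C")),
                 wc_theta_oracle(gm, c("A", "B", "C")), tolerance = 1e-12)
  }
  # fixed difference: theta = 1; identical groups: theta near 0
  gmd <- diagnostic_pair(10, 3)
  expect_equal(weir_cockerham_theta(gmd, c("A", "B")), 1)
  same <- hwe_gm(20, list(c(.5, .5), c(.3, .7)), seed = 4)
  same$meta$group <- rep(c("A", "B"), 10)
  expect_lte(abs(weir_cockerham_theta(same, c("A", "B"))), 0.05)
})

test_that("theta recovers the island-model differentiation level", {
  # plain Balding-Nichols draws at F = 0.25 (no calibration machinery)
  set.seed(21)
  L <- 100; n <- 60
  a1A <- a2A <- matrix(NA_integer_, n, L); a1B <- a2B <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    anc <- as.numeric(rmultinom(1, 100, rep(1, 8))) / 100
    anc <- pmax(anc, 1e-3); anc <- anc / sum(anc)
    shape <- anc * (1 - 0.25) / 0.25
    pA <- rgamma(8, shape); pA <- pA / sum(pA)
    pB <- rgamma(8, shape); pB <- pB / sum(pB)
    a1A[, l] <- sample.int(8, n, TRUE, prob = pA)
    a2A[, l] <- sample.int(8, n, TRUE, prob = pA)
    a1B[, l] <- sample.int(8, n, TRUE, prob = pB)
    a2B[, l] <- sample.int(8, n, TRUE, prob = pB)
  }
  gm <- gm_rbind(toy_gm(a1A, a2A, rep("A", n), ids = sprintf("A%03d", 1:n)),
                 toy_gm(a1B, a2B, rep("B", n), ids = sprintf("B%03d", 1:n)))
  expect_lt(abs(weir_cockerham_theta(gm, c("A", "B")) - 0.25), 0.03)
})

test_that("PhiPT behaves at its extremes and under label permutation", {
  # two groups, within distance 0, between distance 1
  d <- matrix(1, 6, 6) - diag(6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0
  r <- amova_phipt(d, rep(c("A", "B"), each = 3), n_perm = 99, seed = 1)
  expect_equal(r$phi_pt, 1)
  # random labels on a random matrix: phi near 0, permutation p not extreme
  set.seed(8)
  x <- matrix(rnorm(60), 20, 3)
  dd <- as.matrix(dist(x))
  r2 <- amova_phipt(dd, sample(rep(c("A", "B"), each = 10)), n_perm = 199, seed = 2)
  expect_lt(abs(r2$phi_pt), 0.15)
  expect_gt(r2$p_value, 0.01)
  # haplotype mismatch distance on the packaged mtDNA table: WIT and DIT
  # share no haplotype, so the between-group component dominates, but the
  # 8-haplotype diversity within DIT keeps PhiPT well below 1
  t3 <- load_fixture_tables("table3")
  haps <- c(rep(rownames(t3$counts), t3$counts[, "WIT"]),
            rep(rownames(t3$counts), t3$counts[, "DIT"]))
  grp <- c(rep("WIT", sum(t3$counts[, "WIT"])), rep("DIT", sum(t3$counts[, "DIT"])))
  r3 <- amova_phipt(haplotype_mismatch_dist(haps), grp, n_perm = 99, seed = 3)
  expect_gt(r3$phi_pt, 0.6)
  expect_lte(r3$p_value, 0.05)
})

test_that("allele-count genotype distances feed the AMOVA as documented", {
  # hom 1/1 vs hom 2/2 at one locus: count vectors (2,0) vs (0,2)
  gm <- toy_gm(rbind(1L, 1L, 2L), rbind(1L, 1L, 2L), c("A", "A", "B"))
  D <- gm_allele_count_dist(gm)
  expect_equal(unname(D[1, 2]), 0)
  expect_equal(unname(D[1, 3]), sqrt(8))
  # missing locus in one member: remaining loci rescaled to the panel size
  gm2 <- toy_gm(rbind(c(1L, 1L), c(2L, NA)), rbind(c(1L, 1L), c(2L, NA)),
                c("A", "B"))
  expect_equal(unname(gm_allele_count_dist(gm2)[1, 2]), sqrt(8 * 2))
  # diagnostic groups: PhiPT from these distances is 1
  gmd <- diagnostic_pair(5, 4)
  r <- amova_phipt(gm_allele_count_dist(gmd), gmd$meta$group, n_perm = 49,
                   seed = 1)
  expect_equal(r$phi_pt, 1)
})

test_that("Queller-Goodnight relatedness has the expected moments", {
  freqs <- replicate(39, {
    p <- as.numeric(rmultinom(1, 60, c(.4, .3, .2, .1))) / 60
    pmax(p, 1e-6) / sum(pmax(p, 1e-6))
  }, simplify = FALSE)
  ref <- hwe_gm(200, freqs, group = "R", seed = 31)
  fr <- allele_frequencies(ref)
  # unrelated pairs: mean r near 0
  set.seed(32)
  rs <- vapply(1:250, function(i) {
    pair <- sample(ref$meta$id, 2)
    queller_goodnight_r(ref, pair, fr, "R")
  }, 0)
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.03)
  # parent-offspring pairs: mean r near 0.5
  set.seed(33)
  po <- vapply(1:250, function(i) {
    p1 <- sample(n_ind(ref), 1); p2 <- sample(n_ind(ref), 1)
    child_a1 <- integer(39); child_a2 <- integer(39)
    for (l in 1:39) {
      child_a1[l] <- if (runif(1) < .5) ref$a1[p1, l] else ref$a2[p1, l]
      child_a2[l] <- if (runif(1) < .5) ref$a1[p2, l] else ref$a2[p2, l]
    }
    fam <- gm_rbind(ref, toy_gm(matrix(child_a1, 1), matrix(child_a2, 1),
                                "R", loci = ref$loci, ids = "child"))
    queller_goodnight_r(fam, c(fam$meta$id[p1], "child"), fr, "R")
  }, 0)
  expect_equal(mean(po, na.rm = TRUE), 0.5, tolerance = 0.05)
  # sharing no alleles anywhere gives negative r
  gm2 <- toy_gm(rbind(c(1L, 1L), c(3L, 3L)), rbind(c(2L, 2L), c(4L, 4L)),
                c("R", "R"), ids = c("u", "v"))
  fr2 <- allele_frequencies(gm2)
  expect_lt(queller_goodnight_r(gm2, c("u", "v"), fr2, "R"), 0)
})
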