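# Shared small fixtures for the sampler tests: two moderately diverged
# populations plus admixed classes, modest chain lengths.
adm_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      par <- simulate_parental_pops(synthetic_pop_spec(n_loci = 30, seed = 2))
      sim <- simulate_class_panel(gm_subset(par, groups = "W"),
                                  gm_subset(par, groups = "D"),
                                  classes = c("P_W", "P_D", "F1", "BC1W", "BC1D"),
                                  n_per_class = 40, seed = 3)
      cache <<- list(par = par, sim = sim)
    }
    cache
  }
})

test_that("two diverged populations separate cleanly at K = 2", {
  fx <- adm_fixture()
  cfg <- admixture_config(K = 2, n_burnin = 300, n_iter = 1500, n_chains = 2,
                          seed = 4)
  fit <- run_admixture_mcmc(fx$par, cfg)
  expect_equal(unname(rowSums(fit$Q)), rep(1, n_ind(fx$par)), tolerance = 1e-9)
  kW <- cluster_of_group(fit, "W")
  expect_gte(mean(fit$Q[fit$groups == "W", kW]), 0.95)
  expect_gte(mean(fit$Q[fit$groups == "D", 3 - kW]), 0.95)
  # credible bounds are ordered and bracket the per-individual sample median
  expect_true(all(fit$CI90$lower <= fit$CI90$upper))
  med <- apply(fit$Qsamples, c(2, 3), stats::median)
  expect_true(all(fit$CI90$lower <= med + 1e-9))
  expect_true(all(fit$CI90$upper >= med - 1e-9))
})

test_that("K = 1 gives unit ancestry exactly and popinfo anchors clusters", {
  fx <- adm_fixture()
  fit1 <- run_admixture_mcmc(fx$par, admixture_config(K = 1, n_burnin = 50,
                                                      n_iter = 300, n_chains = 1,
                                                      seed = 1))
  expect_true(all(fit1$Q == 1))
  # popinfo: flagged reference individuals keep q fixed at their own cluster
  cfgp <- admixture_config(K = 2, n_burnin = 300, n_iter = 1200, n_chains = 1,
                           use_popinfo = TRUE,
                           update_freqs_from_flagged_only = TRUE, seed = 6)
  allgm <- gm_rbind(fx$par, fx$sim$gm)
  fitp <- run_admixture_mcmc(allgm, cfgp)
  expect_equal(fitp$cluster_names, c("W", "D"))
  expect_true(all(fitp$Q[fitp$groups == "W", "W"] == 1))
  f1q <- fitp$Q[fitp$groups == "F1", "W"]
  expect_equal(mean(f1q), 0.5, tolerance = 0.05)
  # an empty declared reference cluster is an error
  cfgbad <- cfgp; cfgbad$ref_groups <- c("W", "D", "ghost")
  expect_error(run_admixture_mcmc(allgm, cfgbad), "ghost")
})

test_that("a fully heterozygous individual at diagnostic loci sits at q = 1/2", {
  gm <- diagnostic_pair(20, 30)
  mid <- toy_gm(matrix(1L, 1, 30), matrix(2L, 1, 30), "X", loci = gm$loci,
                ids = "mid")
  fit <- run_admixture_mcmc(gm_rbind(gm, mid),
                            admixture_config(K = 2, n_burnin = 300,
                                             n_iter = 2000, n_chains = 2, seed = 3))
  expect_equal(unname(fit$Q["mid", 1]), 0.5, tolerance = 0.05)
})

test_that("posterior mean q tracks pedigree ancestry across classes", {
  fx <- adm_fixture()
  allgm <- gm_rbind(fx$par, fx$sim$gm)
  fit <- run_admixture_mcmc(allgm, admixture_config(K = 2, n_burnin = 400,
                                                    n_iter = 2500, n_chains = 2,
                                                    seed = 8))
  kW <- cluster_of_group(fit, "W")
  truth <- c(W = 1, D = 0, P_W = 1, P_D = 0, F1 = 0.5, BC1W = 0.75, BC1D = 0.25)
  qW <- fit$Q[, kW]
  expect_gt(cor(qW, truth[fit$groups]), 0.95)
})

test_that("Ln P(D) estimator and Delta-K follow their definitions", {
  expect_equal(estimate_lnpd(rep(-100, 200)), -100)
  expect_equal(estimate_lnpd(c(-100, -102)), -102)
  expect_error(estimate_lnpd(c(-1, NaN)), "non-finite")
  # frozen arithmetic example: means (-5000,-4000,-3900,-3890), sd = 1
  x <- 1 / sqrt(2)
  lnpd <- rbind(c(-5000, -4000, -3900, -3890) + x,
                c(-5000, -4000, -3900, -3890) - x)
  dk <- delta_k(lnpd)
  expect_equal(dk$delta_K, c(NA, 900, 90, NA), tolerance = 1e-9)
  expect_equal(attr(dk, "best_K"), 2L)
  # a linear Ln P(D) sequence has zero curvature
  lin <- rbind(seq(-500, -200, by = 100) + x, seq(-500, -200, by = 100) - x)
  expect_equal(delta_k(lin)$delta_K, c(NA, 0, 0, NA), tolerance = 1e-9)
  expect_warning(delta_k(rbind(c(-10, -5, -4), c(-10, -5, -4))), "Inf")
  expect_error(delta_k(matrix(1:3, 1)), "2 chains")
})

test_that("Delta-K recovers K = 2 on two-population data", {
  par <- simulate_parental_pops(synthetic_pop_spec(n_loci = 20,
                                                   n_individuals = c(30, 30),
                                                   seed = 5))
  lnpd <- sapply(1:4, function(k) {
    fit <- run_admixture_mcmc(par, admixture_config(K = k, n_burnin = 200,
                                                    n_iter = 1200, n_chains = 2,
                                                    seed = 10 + k))
    fit$lnPD
  })
  colnames(lnpd) <- 1:4
  dk <- delta_k(lnpd)
  expect_equal(attr(dk, "best_K"), 2L)
})

test_that("credible intervals come from the retained samples", {
  fx <- adm_fixture()
  fit <- run_admixture_mcmc(fx$par, admixture_config(K = 2, n_burnin = 200,
                                                     n_iter = 1000, n_chains = 1,
                                                     seed = 2))
  ci <- credible_intervals(fit, level = 0.5)
  expect_true(all(ci$lower >= fit$CI90$lower - 1e-12))
  expect_true(all(ci$upper <= fit$CI90$upper + 1e-12))
  # identical seeds give bit-identical results
  fit2 <- run_admixture_mcmc(fx$par, admixture_config(K = 2, n_burnin = 200,
                                                      n_iter = 1000, n_chains = 1,
                                                      seed = 2))
  expect_identical(fit$Q, fit2$Q)
  expect_identical(fit$lnPD, fit2$lnPD)
})
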