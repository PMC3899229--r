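#' Configuration for the Bayesian admixture sampler
#'
#' Desk-scale defaults: 40 000 retained sweeps after 4 000 burn-in, 2 chains,
#' allele-frequency prior lambda = 1, admixture parameter alpha initialised
#' at 1 with a Uniform(0, 10] prior and Metropolis proposal sd 0.025.
#'
#' @param K number of clusters (>= 1)
#' @param n_burnin burn-in sweeps (>= 0)
#' @param n_iter retained sweeps after burn-in (> n_burnin)
#' @param thin keep every `thin`-th retained sweep for credible intervals
#' @param lambda Dirichlet allele-frequency prior parameter (> 0)
#' @param alpha_init,alpha_max,alpha_prop_sd Metropolis settings for the
#'   Dirichlet admixture parameter alpha (uniform prior on (0, alpha_max])
#' @param use_popinfo anchor flagged individuals (popflag) to their declared
#'   group's cluster
#' @param update_freqs_from_flagged_only with popinfo, let only flagged
#'   individuals update cluster allele frequencies
#' @param n_chains independent chains (>= 1; >= 2 needed for Delta-K)
#' @param seed integer RNG seed (chains use derived sub-seeds)
#' @param ref_groups optional explicit reference groups for popinfo
#'   (defaults to the groups of the flagged individuals, in order of
#'   appearance)
#' @return a list of class `admixture_config`.
#' @export
admixture_config <- function(K = 2L, n_burnin = 4000L, n_iter = 40000L,
                             thin = 10L, lambda = 1.0, alpha_init = 1.0,
                             alpha_max = 10.0, alpha_prop_sd = 0.025,
                             use_popinfo = FALSE,
                             update_freqs_from_flagged_only = FALSE,
                             n_chains = 2L, seed = 1L, ref_groups = NULL) {
  if (K < 1) stop("K must be >= 1")
  if (n_burnin < 0 || n_iter <= n_burnin)
    stop("need n_iter > n_burnin >= 0")
  if (lambda <= 0) stop("lambda must be > 0")
  structure(list(K = as.integer(K), n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 lambda = lambda, alpha_init = alpha_init,
                 alpha_max = alpha_max, alpha_prop_sd = alpha_prop_sd,
                 use_popinfo = isTRUE(use_popinfo),
                 update_freqs_from_flagged_only = isTRUE(update_freqs_from_flagged_only),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 ref_groups = ref_groups),
            class = "admixture_config")
}

# internal: encode alleles as 1..A_l per locus; 0 = missing
.encode_alleles <- function(gm) {
  alleles <- gm_alleles(gm)
  L <- n_loci(gm)
  e1 <- e2 <- matrix(0L, n_ind(gm), L)
  for (l in seq_len(L)) {
    e1[, l] <- match(gm$a1[, l], alleles[[l]])
    e2[, l] <- match(gm$a2[, l], alleles[[l]])
  }
  e1[is.na(e1)] <- 0L; e2[is.na(e2)] <- 0L
  list(a1 = e1, a2 = e2, n_alleles = pmax(lengths(alleles), 1L), alleles = alleles)
}

# internal: derived chain seed, kept within 32-bit range
.chain_seed <- function(seed, chain) as.integer((as.double(seed) * 7919 + chain * 104729) %% 2147483647)

#' Run the Bayesian admixture MCMC
#'
#' Gibbs sampler for the admixture model with independent cluster allele
#' frequencies: latent allele-copy origins, Dirichlet(lambda) frequency
#' priors, Dirichlet(alpha) ancestry priors with alpha updated by Metropolis.
#' With `use_popinfo`, individuals whose `popflag` is set are anchored to
#' their declared group's cluster (their q is fixed), and with
#' `update_freqs_from_flagged_only` only they update cluster frequencies.
#' Multiple chains are aligned to the first chain (greedy bijective matching
#' on ancestry columns) and pooled.
#'
#' @param gm a [genotype_matrix()] (>= 2 polymorphic loci)
#' @param cfg an [admixture_config()]
#' @return an object of class `admixture_result` with elements `Q`
#'   (individual x cluster posterior means, rows sum to 1), `CI90` (`lower`
#'   and `upper` 90% credible bound matrices), `lnPD` (per chain),
#'   `lnL_trace` (list per chain), `cluster_freqs`, `alpha`, `K`,
#'   `cluster_names`, `cfg`.
#' @export
run_admixture_mcmc <- function(gm, cfg = admixture_config()) {
  enc <- .encode_alleles(gm)
  if (sum(enc$n_alleles > 1) < 2 && cfg$K > 1)
    stop("need at least 2 polymorphic loci")
  n_pattern <- length(unique(apply(cbind(gm$a1, gm$a2), 1, paste, collapse = "/")))
  if (cfg$K > n_pattern)
    warning("K exceeds the number of distinct multilocus genotype patterns")
  popflag_cluster <- rep(0L, n_ind(gm))
  cluster_names <- paste0("cluster", seq_len(cfg$K))
  if (cfg$use_popinfo) {
    flagged <- which(gm$meta$popflag)
    if (!length(flagged)) stop("use_popinfo requires flagged individuals")
    refs <- cfg$ref_groups
    if (is.null(refs)) refs <- unique(gm$meta$group[flagged])
    empty <- refs[!refs %in% gm$meta$group[flagged]]
    if (length(empty))
      stop("reference cluster(s) with no flagged individuals: ",
           paste(empty, collapse = ", "))
    if (length(refs) > cfg$K)
      stop("more reference groups than clusters (K = ", cfg$K, ")")
    popflag_cluster[flagged] <- match(gm$meta$group[flagged], refs)
    popflag_cluster[is.na(popflag_cluster)] <- 0L
    cluster_names[seq_along(refs)] <- refs
  }

  chains <- vector("list", cfg$n_chains)
  old <- .save_rng(); on.exit(.restore_rng(old))
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(.chain_seed(cfg$seed, ch))
    chains[[ch]] <- .admixture_gibbs_cpp(enc$a1, enc$a2, enc$n_alleles, cfg$K,
                                         cfg$n_burnin, cfg$n_iter, cfg$thin,
                                         cfg$lambda, cfg$alpha_init,
                                         cfg$alpha_max, cfg$alpha_prop_sd,
                                         popflag_cluster,
                                         cfg$update_freqs_from_flagged_only)
  }

  # align chains 2.. to chain 1 by greedy bijective matching on Q columns
  perms <- vector("list", cfg$n_chains)
  perms[[1]] <- seq_len(cfg$K)
  anchored <- any(popflag_cluster > 0)
  for (ch in seq_len(cfg$n_chains)[-1]) {
    if (anchored) { perms[[ch]] <- seq_len(cfg$K); next }
    cost <- matrix(0, cfg$K, cfg$K)
    for (i in seq_len(cfg$K)) for (j in seq_len(cfg$K))
      cost[i, j] <- sum(abs(chains[[1]]$Q[, i] - chains[[ch]]$Q[, j]))
    perm <- rep(NA_integer_, cfg$K)
    for (s in seq_len(cfg$K)) {
      idx <- which(cost == min(cost), arr.ind = TRUE)[1, ]
      perm[idx[1]] <- idx[2]
      cost[idx[1], ] <- Inf; cost[, idx[2]] <- Inf
    }
    perms[[ch]] <- perm
  }

  N <- n_ind(gm); K <- cfg$K
  Q <- matrix(0, N, K)
  samples <- list()
  for (ch in seq_len(cfg$n_chains)) {
    perm <- perms[[ch]]
    Q <- Q + chains[[ch]]$Q[, perm, drop = FALSE]
    samples[[ch]] <- chains[[ch]]$Qsamples[, , perm, drop = FALSE]
  }
  Q <- Q / cfg$n_chains
  Q <- Q / rowSums(Q)
  dimnames(Q) <- list(gm$meta$id, cluster_names)
  allsamp <- abind_first(samples)
  lower <- upper <- matrix(NA_real_, N, K, dimnames = dimnames(Q))
  for (k in seq_len(K)) {
    qs <- allsamp[, , k, drop = FALSE]
    lower[, k] <- apply(qs, 2, stats::quantile, probs = 0.05, names = FALSE)
    upper[, k] <- apply(qs, 2, stats::quantile, probs = 0.95, names = FALSE)
  }
  lnPD <- vapply(chains, function(x) estimate_lnpd(x$lnL), 0)
  freq <- chains[[1]]$Pmean[perms[[1]], , , drop = FALSE]
  structure(list(Q = Q, CI90 = list(lower = lower, upper = upper),
                 lnPD = lnPD, lnL_trace = lapply(chains, `[[`, "lnL"),
                 Qsamples = allsamp,
                 cluster_freqs = freq, n_alleles = enc$n_alleles,
                 alpha = mean(vapply(chains, function(x) mean(x$alpha), 0)),
                 K = K, cluster_names = cluster_names, cfg = cfg,
                 ids = gm$meta$id, groups = gm$meta$group),
            class = "admixture_result")
}

# internal: bind 3-d arrays along the first dimension
abind_first <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(NA_real_, c(sum(vapply(lst, function(x) dim(x)[1], 0L)), d[2], d[3]))
  at <- 0L
  for (x in lst) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture_result: K = %d, %d individuals, %d chain(s)\n",
              x$K, nrow(x$Q), length(x$lnPD)))
  cat(sprintf("  Ln P(D) per chain: %s\n",
              paste(sprintf("%.1f", x$lnPD), collapse = ", ")))
  cat(sprintf("  mean alpha: %.3f\n", x$alpha))
  invisible(x)
}

#' Estimate Ln P(D) from a log-likelihood trace
#'
#' The harmonic-style estimator used for Bayesian cluster-number choice:
#' `mean(lnL) - var(lnL)/2` over retained sweeps.
#'
#' @param trace numeric vector of post-burn-in log-likelihood values (all
#'   finite; a zero-variance trace returns its mean)
#' @return the Ln P(D) estimate.
#' @export
estimate_lnpd <- function(trace) {
  if (any(!is.finite(trace))) stop("non-finite values in log-likelihood trace")
  if (length(trace) < 2) stop("need >= 2 retained sweeps")
  mean(trace) - stats::var(trace) / 2
}

#' Delta-K statistic for choosing the number of clusters
#'
#' The second-order rate of change of Ln P(D) across consecutive K,
#' standardised by the across-chain standard deviation:
#' `DeltaK(K) = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`.
#'
#' @param lnpd matrix of Ln P(D) values, chains in rows, consecutive K
#'   values in columns; column names give the K values (default: 1, 2, ...)
#' @return a data frame with K, mean and sd of Ln P(D), and Delta-K (NA at
#'   the boundary K; Inf with a warning where sd = 0), plus attribute
#'   `best_K` (argmax Delta-K).
#' @export
delta_k <- function(lnpd) {
  lnpd <- as.matrix(lnpd)
  if (nrow(lnpd) < 2) stop("need >= 2 chains per K")
  ks <- if (!is.null(colnames(lnpd))) as.integer(colnames(lnpd)) else seq_len(ncol(lnpd))
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  m <- colMeans(lnpd)
  s <- apply(lnpd, 2, stats::sd)
  dk <- rep(NA_real_, length(ks))
  for (j in seq_along(ks)[-c(1, length(ks))]) {
    num <- abs(m[j + 1] - 2 * m[j] + m[j - 1])
    if (s[j] == 0) {
      warning("sd = 0 at K = ", ks[j], "; Delta-K reported as Inf")
      dk[j] <- Inf
    } else dk[j] <- num / s[j]
  }
  out <- data.frame(K = ks, mean_lnPD = m, sd_lnPD = s, delta_K = dk)
  attr(out, "best_K") <- ks[which.max(dk)]
  out
}

#' Credible intervals for ancestry proportions
#'
#' Empirical per-individual, per-cluster quantiles of the retained ancestry
#' samples.
#'
#' @param fit an [run_admixture_mcmc()] result
#' @param level credible level (default 0.90)
#' @return list of `lower` and `upper` matrices (individuals x clusters).
#' @export
credible_intervals <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "admixture_result"))
  a <- (1 - level) / 2
  N <- nrow(fit$Q); K <- fit$K
  lower <- upper <- matrix(NA_real_, N, K, dimnames = dimnames(fit$Q))
  for (k in seq_len(K)) {
    qs <- fit$Qsamples[, , k, drop = FALSE]
    lower[, k] <- apply(qs, 2, stats::quantile, probs = a, names = FALSE)
    upper[, k] <- apply(qs, 2, stats::quantile, probs = 1 - a, names = FALSE)
  }
  list(lower = lower, upper = upper)
}

#' Cluster most associated with a group
#'
#' @param fit an [run_admixture_mcmc()] result
#' @param group group label present in the fitted data
#' @return the cluster index with the highest mean ancestry among the
#'   group's individuals.
#' @export
cluster_of_group <- function(fit, group) {
  idx <- which(fit$groups == group)
  if (!length(idx)) stop("group not present in fit: ", group)
  which.max(colMeans(fit$Q[idx, , drop = FALSE]))
}

#' Self-ancestry of each individual of a group
#'
#' @param fit an [run_admixture_mcmc()] result
#' @param group group label
#' @param cluster optional cluster index (default: [cluster_of_group()])
#' @return named numeric vector of ancestry proportions in that cluster.
#' @export
group_self_ancestry <- function(fit, group, cluster = NULL) {
  idx <- which(fit$groups == group)
  if (is.null(cluster)) cluster <- cluster_of_group(fit, group)
  stats::setNames(fit$Q[idx, cluster], fit$ids[idx])
}
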