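# Likelihood-based assignment and hybrid-class inference.

# internal: per-group allele count tables (list group -> list locus -> named counts)
.group_allele_counts <- function(gm, groups) {
  alleles <- gm_alleles(gm)
  out <- list()
  for (g in groups) {
    idx <- which(gm$meta$group == g)
    cl <- vector("list", n_loci(gm)); names(cl) <- gm$loci
    for (l in seq_len(n_loci(gm))) {
      al <- c(gm$a1[idx, l], gm$a2[idx, l])
      al <- al[!is.na(al)]
      cl[[l]] <- table(factor(al, levels = alleles[[l]]))
    }
    out[[g]] <- cl
  }
  attr(out, "alleles") <- alleles
  out
}

#' Rannala-Mountain assignment score
#'
#' Posterior-predictive genotype likelihood of an individual under each
#' candidate group: allele frequencies carry a Dirichlet(1/k_l) prior (k_l =
#' number of alleles observed at locus l in the dataset), so the probability
#' of drawing allele a as the next gene copy from a group with counts n is
#' (n_a + 1/k_l) / (n + 1), and the two copies of a genotype are drawn
#' sequentially. With `leave_one_out`, the individual's own copies are
#' removed from its group's counts before scoring.
#'
#' @param gm a [genotype_matrix()]
#' @param individual individual id
#' @param candidate_groups groups to score against
#' @param leave_one_out logical (default TRUE)
#' @return a list of class `assignment_score` with `log_lik` (per group),
#'   `percent` (normalised scores summing to 100), `best` (highest-scoring
#'   group), `n_loci_used`.
#' @references Rannala & Mountain (1997) PNAS 94:9197-9201.
#' @export
rannala_mountain_score <- function(gm, individual, candidate_groups,
                                   leave_one_out = TRUE) {
  i <- match(individual, gm$meta$id)
  if (is.na(i)) stop("unknown individual: ", individual)
  counts <- .group_allele_counts(gm, candidate_groups)
  own <- gm$meta$group[i]
  ll <- stats::setNames(numeric(length(candidate_groups)), candidate_groups)
  used <- 0L
  for (l in seq_len(n_loci(gm))) {
    a <- gm$a1[i, l]; b <- gm$a2[i, l]
    if (is.na(a)) next
    used <- used + 1L
    k <- length(attr(counts, "alleles")[[l]])
    for (g in candidate_groups) {
      n <- counts[[g]][[l]]
      if (leave_one_out && g == own) {
        n[as.character(a)] <- n[as.character(a)] - 1L
        n[as.character(b)] <- n[as.character(b)] - 1L
      }
      ntot <- sum(n)
      na_ <- n[[as.character(a)]]; nb_ <- n[[as.character(b)]]
      p <- (na_ + 1 / k) / (ntot + 1) *
        (nb_ + 1 / k + (a == b)) / (ntot + 2)
      if (a != b) p <- 2 * p
      ll[g] <- ll[g] + log(p)
    }
  }
  m <- max(ll)
  pct <- 100 * exp(ll - m) / sum(exp(ll - m))
  structure(list(log_lik = ll, percent = pct,
                 best = candidate_groups[which.max(ll)], n_loci_used = used),
            class = "assignment_score")
}

#' @export
print.assignment_score <- function(x, ...) {
  cat("assignment scores (percent):\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' Six-class hybrid-category posterior
#'
#' MCMC over the classes {P_W, P_D, F1, F2, BC_W, BC_D}, each defined by its
#' fixed probabilities that a locus's two gene copies originate from (W,W),
#' (W,D) or (D,D): parentals (1,0,0)/(0,0,1), F1 (0,1,0), F2 (1/4,1/2,1/4),
#' backcrosses (1/2,1/2,0)/(0,1/2,1/2). Source allele frequencies and mixing
#' proportions carry Dirichlet priors ("uniform" = 1, "jeffreys_like" = 0.5
#' per allele). Reference individuals, when given, are pinned to their
#' parental class (this also anchors the source labels W and D).
#'
#' @param gm a [genotype_matrix()]
#' @param reference_W,reference_D optional group names whose members are
#'   pinned to the parental classes
#' @param n_burnin,n_iter MCMC control (desk-scale defaults 2 000 / 20 000)
#' @param n_chains independent chains (pooled; a potential-scale-reduction
#'   factor above 1.2 on the log-likelihood traces triggers a warning)
#' @param prior_mode `"uniform"` or `"jeffreys_like"`
#' @param jeffreys_constant per-allele prior mass for `"jeffreys_like"`
#' @param seed integer RNG seed
#' @return a list of class `class_posterior` with `posterior` (individuals x
#'   6 classes, rows sum to 1), `map` (MAP class labels), `classes`, `lnL`
#'   traces, `prior_mode`.
#' @export
newhybrids_posterior <- function(gm, reference_W = NULL, reference_D = NULL,
                                 n_burnin = 2000L, n_iter = 20000L,
                                 n_chains = 2L,
                                 prior_mode = c("uniform", "jeffreys_like"),
                                 jeffreys_constant = 0.5, seed = 1L) {
  prior_mode <- match.arg(prior_mode)
  freq_prior <- if (prior_mode == "uniform") 1.0 else jeffreys_constant
  enc <- .encode_alleles(gm)
  poly <- enc$n_alleles > 1
  if (!all(poly)) {
    enc$a1 <- enc$a1[, poly, drop = FALSE]
    enc$a2 <- enc$a2[, poly, drop = FALSE]
    enc$n_alleles <- enc$n_alleles[poly]
  }
  if (!length(enc$n_alleles)) stop("no polymorphic loci")
  classes <- c("P_W", "P_D", "F1", "F2", "BC_W", "BC_D")
  phi <- genotype_origin_weights()
  fixed <- rep(0L, n_ind(gm))
  if (!is.null(reference_W)) fixed[gm$meta$group %in% reference_W] <- 1L
  if (!is.null(reference_D)) fixed[gm$meta$group %in% reference_D] <- 2L
  old <- .save_rng(); on.exit(.restore_rng(old))
  posts <- vector("list", n_chains)
  lnls <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(.chain_seed(seed, ch))
    res <- .newhybrids_gibbs_cpp(enc$a1, enc$a2, enc$n_alleles, phi, fixed,
                                 freq_prior, n_burnin, n_iter)
    posts[[ch]] <- res$posterior
    lnls[[ch]] <- res$lnL
  }
  if (n_chains >= 2) {
    gr <- .gelman_rubin(lnls)
    if (is.finite(gr) && gr > 1.2)
      warning(sprintf("chains may not have converged (potential scale reduction %.2f)", gr))
  }
  post <- Reduce(`+`, posts) / n_chains
  dimnames(post) <- list(gm$meta$id, classes)
  structure(list(posterior = post,
                 map = classes[apply(post, 1, which.max)],
                 classes = classes, lnL = lnls, prior_mode = prior_mode),
            class = "class_posterior")
}

#' Genotype-origin weights of the six hybrid classes
#'
#' @return a 6 x 3 matrix (rows P_W, P_D, F1, F2, BC_W, BC_D; columns WW,
#'   WD, DD) of the probabilities that a locus's two gene copies originate
#'   from each source combination. Each row sums to 1.
#' @export
genotype_origin_weights <- function() {
  m <- rbind(P_W = c(1, 0, 0), P_D = c(0, 0, 1), F1 = c(0, 1, 0),
             F2 = c(0.25, 0.5, 0.25), BC_W = c(0.5, 0.5, 0),
             BC_D = c(0, 0.5, 0.5))
  colnames(m) <- c("WW", "WD", "DD")
  m
}

# internal: potential scale reduction factor on scalar traces
.gelman_rubin <- function(traces) {
  m <- length(traces); n <- length(traces[[1]])
  means <- vapply(traces, mean, 0)
  vars <- vapply(traces, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Iterated-reallocation partitioning
#'
#' Non-Bayesian clustering by repeated likelihood reallocation: each run
#' starts from a random partition into k groups and repeatedly (i) computes
#' group allele counts and (ii) reassigns every individual to the group
#' maximising its leave-one-out Rannala-Mountain genotype likelihood,
#' provided the LOD against the best alternative is at least
#' `lod_threshold`. Run-to-run agreement of the final partitions gives the
#' plateau report. A group emptied during reallocation is reseeded with the
#' currently worst-fitting individual.
#'
#' @param gm a [genotype_matrix()]
#' @param k number of groups (>= 2)
#' @param n_runs independent runs (default 50)
#' @param n_reallocations reallocation sweeps per run (default 20)
#' @param lod_threshold minimum LOD for reallocation (default 0)
#' @param seed integer RNG seed
#' @return a list of class `flock_partition` with `partitions` (runs x N
#'   canonical labels), `best` (modal partition), `plateau_length` (runs
#'   identical to the modal partition), `agreement` (fraction of runs),
#'   `log` (reseeding events).
#' @export
flock_partition <- function(gm, k, n_runs = 50L, n_reallocations = 20L,
                            lod_threshold = 0, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  N <- n_ind(gm)
  enc <- .encode_alleles(gm)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  log_events <- character()

  loglik_to <- function(i, cnt, ntot, k_l, remove_self) {
    # posterior-predictive genotype log-likelihood of individual i against
    # count table cnt (matrix maxA x L)
    ll <- 0
    for (l in seq_len(ncol(enc$a1))) {
      a <- enc$a1[i, l]; b <- enc$a2[i, l]
      if (a == 0L) next
      na_ <- cnt[a, l]; nb_ <- cnt[b, l]; n <- ntot[l]
      if (remove_self) {
        n <- n - 2L
        if (a == b) { na_ <- na_ - 2L; nb_ <- na_ }
        else { na_ <- na_ - 1L; nb_ <- nb_ - 1L }
      }
      kk <- k_l[l]
      p <- (na_ + 1 / kk) / (n + 1) * (nb_ + 1 / kk + (a == b)) / (n + 2)
      if (a != b) p <- 2 * p
      ll <- ll + log(max(p, 1e-300))
    }
    ll
  }

  maxA <- max(enc$n_alleles)
  L <- ncol(enc$a1)
  count_of <- function(members) {
    cnt <- matrix(0L, maxA, L)
    for (i in members) for (l in seq_len(L)) {
      a <- enc$a1[i, l]
      if (a == 0L) next
      cnt[a, l] <- cnt[a, l] + 1L
      cnt[enc$a2[i, l], l] <- cnt[enc$a2[i, l], l] + 1L
    }
    cnt
  }

  canonical <- function(part) {
    # relabel groups by order of first appearance
    match(part, unique(part))
  }

  parts <- matrix(NA_integer_, n_runs, N)
  for (run in seq_len(n_runs)) {
    part <- sample(rep_len(seq_len(k), N))
    for (sweep in seq_len(n_reallocations)) {
      cnts <- lapply(seq_len(k), function(g) count_of(which(part == g)))
      ntots <- lapply(cnts, colSums)
      for (i in seq_len(N)) {
        lls <- vapply(seq_len(k), function(g)
          loglik_to(i, cnts[[g]], ntots[[g]], enc$n_alleles,
                    remove_self = part[i] == g), 0)
        ord <- order(lls, decreasing = TRUE)
        best <- ord[1]
        lod <- lls[ord[1]] - lls[ord[2]]
        if (best != part[i] && lod >= lod_threshold) {
          oldg <- part[i]
          part[i] <- best
          # keep counts current (sequential reallocation)
          for (l in seq_len(L)) {
            a <- enc$a1[i, l]
            if (a == 0L) next
            b <- enc$a2[i, l]
            cnts[[oldg]][a, l] <- cnts[[oldg]][a, l] - 1L
            cnts[[oldg]][b, l] <- cnts[[oldg]][b, l] - 1L
            cnts[[best]][a, l] <- cnts[[best]][a, l] + 1L
            cnts[[best]][b, l] <- cnts[[best]][b, l] + 1L
          }
          ntots[[oldg]] <- colSums(cnts[[oldg]])
          ntots[[best]] <- colSums(cnts[[best]])
          if (!any(part == oldg)) {
            # reseed the emptied group with the worst-fitting individual
            fit <- vapply(seq_len(N), function(j)
              loglik_to(j, cnts[[part[j]]], ntots[[part[j]]], enc$n_alleles, TRUE), 0)
            worst <- which.min(fit)
            part[worst] <- oldg
            cnts <- lapply(seq_len(k), function(g) count_of(which(part == g)))
            ntots <- lapply(cnts, colSums)
            log_events <- c(log_events,
                            sprintf("run %d sweep %d: group %d reseeded with %s",
                                    run, sweep, oldg, gm$meta$id[worst]))
          }
        }
      }
    }
    parts[run, ] <- canonical(part)
  }
  keys <- apply(parts, 1, paste, collapse = ",")
  modal <- names(sort(table(keys), decreasing = TRUE))[1]
  plateau <- sum(keys == modal)
  structure(list(partitions = parts,
                 best = as.integer(strsplit(modal, ",")[[1]]),
                 plateau_length = plateau,
                 agreement = plateau / n_runs,
                 ids = gm$meta$id, log = log_events, seed = seed),
            class = "flock_partition")
}

#' @export
print.flock_partition <- function(x, ...) {
  cat(sprintf("flock_partition: %d runs, plateau %d (%.0f%% agreement)\n",
              nrow(x$partitions), x$plateau_length, 100 * x$agreement))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b integer label vectors of equal length
#' @return the adjusted Rand index (1 = identical up to relabelling).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  exp_ <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == exp_) return(1)
  (sij - exp_) / (mx - exp_)
}

#' Empirical-null test for spurious admixture
#'
#' Simulates non-admixed individuals from each reference group's allele
#' frequencies, estimates their admixture coefficients with a
#' reference-anchored admixture run (K fixed at the number of reference
#' groups, popinfo with frequencies updated from flagged individuals only),
#' and takes the (1-alpha) quantile of each group's non-self ancestry as the
#' significance threshold. An observed individual is significantly admixed
#' iff its non-self ancestry exceeds the threshold of the reference cluster
#' it assigns to.
#'
#' @param gm a [genotype_matrix()]; members of `ref_groups` are used as the
#'   flagged reference panel, all other individuals are tested
#' @param ref_groups two or more reference group names
#' @param n_sim simulated non-admixed individuals per reference group
#'   (default 100; below 20 a warning is issued — p resolution is coarse)
#' @param alpha significance level (default 0.05); the threshold is the
#'   ceiling((1-alpha) n_sim)-th order statistic of the null
#' @param seed integer RNG seed
#' @param cfg an [admixture_config()] for the underlying run; K, popinfo
#'   settings and seed are overridden internally
#' @return a list of class `null_calibration` with `null` (list per group of
#'   simulated non-self ancestry values), `thresholds`, `tests` (data frame:
#'   id, group, assigned cluster, non-self ancestry, significant), `alpha`.
#' @export
admixture_null_test <- function(gm, ref_groups, n_sim = 100L, alpha = 0.05,
                                seed = 1L, cfg = admixture_config()) {
  if (n_sim < 20) warning("n_sim < 20: coarse p-value resolution")
  if (length(ref_groups) < 2) stop("need >= 2 reference groups")
  freqs <- allele_frequencies(gm, ref_groups)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.chain_seed(seed, 999L))
  # simulate non-admixed individuals per reference group under HWE
  sims <- list()
  for (g in ref_groups) {
    a1 <- a2 <- matrix(NA_integer_, n_sim, n_loci(gm))
    for (l in seq_len(n_loci(gm))) {
      f <- freqs$freq[[g]][[gm$loci[l]]]
      if (is.null(f)) next
      al <- as.integer(names(f))
      a1[, l] <- al[sample.int(length(f), n_sim, TRUE, prob = f)]
      a2[, l] <- al[sample.int(length(f), n_sim, TRUE, prob = f)]
    }
    meta <- data.frame(id = sprintf("null_%s_%03d", g, seq_len(n_sim)),
                       group = paste0("null_", g), popflag = FALSE,
                       stringsAsFactors = FALSE)
    sims[[g]] <- genotype_matrix(a1, a2, meta, gm$loci)
  }
  gm2 <- gm
  gm2$meta$popflag <- gm2$meta$group %in% ref_groups
  allgm <- do.call(gm_rbind, c(list(gm2), unname(sims)))
  cfg$K <- length(ref_groups)
  cfg$use_popinfo <- TRUE
  cfg$update_freqs_from_flagged_only <- TRUE
  cfg$ref_groups <- ref_groups
  cfg$seed <- seed
  fit <- run_admixture_mcmc(allgm, cfg)
  nullv <- list(); thr <- stats::setNames(numeric(length(ref_groups)), ref_groups)
  for (g in ref_groups) {
    idx <- which(fit$groups == paste0("null_", g))
    self_k <- match(g, fit$cluster_names)
    nullv[[g]] <- 1 - fit$Q[idx, self_k]
    thr[g] <- stats::quantile(nullv[[g]], probs = 1 - alpha, type = 1, names = FALSE)
  }
  test_idx <- which(!fit$groups %in% c(ref_groups, paste0("null_", ref_groups)))
  tests <- NULL
  if (length(test_idx)) {
    refk <- match(ref_groups, fit$cluster_names)
    qref <- fit$Q[test_idx, refk, drop = FALSE]
    assigned <- ref_groups[apply(qref, 1, which.max)]
    nonself <- 1 - qref[cbind(seq_along(test_idx), apply(qref, 1, which.max))]
    tests <- data.frame(id = fit$ids[test_idx], group = fit$groups[test_idx],
                        assigned = assigned, non_self = nonself,
                        significant = nonself > thr[assigned],
                        stringsAsFactors = FALSE)
  }
  structure(list(null = nullv, thresholds = thr, tests = tests,
                 alpha = alpha, n_sim = n_sim, seed = seed),
            class = "null_calibration")
}

#' Locus genotype likelihood under a hybrid class
#'
#' The probability of an unordered single-locus genotype under one of the
#' six hybrid classes, marginalising the origins of the two gene copies over
#' the class's origin weights ([genotype_origin_weights()]): within each
#' origin combination the copies are independent draws from the
#' corresponding source frequency vectors (Hardy-Weinberg within origin).
#' This is the per-locus likelihood the six-class MCMC uses.
#'
#' @param a,b the two allele indices of the genotype (positions in the
#'   frequency vectors)
#' @param class a class label from `rownames(genotype_origin_weights())`
#' @param pW,pD source allele-frequency vectors
#' @return the genotype probability.
#' @export
class_genotype_likelihood <- function(a, b, class, pW, pD) {
  phi <- genotype_origin_weights()
  if (!class %in% rownames(phi)) stop("unknown class: ", class)
  w <- phi[class, ]
  g_ww <- if (a == b) pW[a]^2 else 2 * pW[a] * pW[b]
  g_dd <- if (a == b) pD[a]^2 else 2 * pD[a] * pD[b]
  g_wd <- if (a == b) pW[a] * pD[a] else pW[a] * pD[b] + pW[b] * pD[a]
  unname(w["WW"] * g_ww + w["WD"] * g_wd + w["DD"] * g_dd)
}
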