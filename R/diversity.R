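# Diversity and within-population equilibrium statistics.
# All estimators are frequency-based; allele labels are never interpreted
# as repeat counts.

# internal: per-locus observed het, unbiased expected het and n for one group
.locus_div <- function(gm, idx) {
  L <- n_loci(gm)
  ho <- uhe <- rep(NA_real_, L)
  n <- integer(L)
  for (l in seq_len(L)) {
    g1 <- gm$a1[idx, l]; g2 <- gm$a2[idx, l]
    keep <- !is.na(g1)
    n[l] <- sum(keep)
    if (n[l] == 0) next
    ho[l] <- mean(g1[keep] != g2[keep])
    p <- table(c(g1[keep], g2[keep])) / (2 * n[l])
    # unbiased expected heterozygosity: (2N/(2N-1)) (1 - sum p^2)
    uhe[l] <- (2 * n[l] / (2 * n[l] - 1)) * (1 - sum(p^2))
  }
  list(ho = ho, uhe = uhe, n = n)
}

#' Per-group diversity summary
#'
#' Mean number of alleles per locus (Na), private alleles (Np, alleles absent
#' from every other group in the dataset), observed (Ho) and unbiased expected
#' (UHe) heterozygosity averaged over loci, the multilocus fixation index
#' F_IS = 1 - Ho/UHe, and multilocus probabilities of identity for unrelated
#' individuals (PID) and full sibs (PIDsibs).
#'
#' @param gm a [genotype_matrix()]
#' @param group group name (at least 2 individuals)
#' @return a list of class `diversity_summary` with fields `group`, `n`,
#'   `Na`, `Np`, `Ho`, `UHe`, `Fis`, `PID`, `PIDsibs` and the per-locus
#'   vectors in `per_locus`. Loci with no data in the group are skipped with
#'   a warning.
#' @export
diversity_summary <- function(gm, group) {
  idx <- which(gm$meta$group == group)
  if (length(idx) < 2) stop("group ", group, " has fewer than 2 individuals")
  ld <- .locus_div(gm, idx)
  if (any(ld$n == 0))
    warning(sum(ld$n == 0), " locus/loci with no data in group ", group, " skipped")
  ok <- ld$n > 0
  # allele counts and private alleles
  alleles_here <- lapply(seq_len(n_loci(gm)), function(l) {
    al <- c(gm$a1[idx, l], gm$a2[idx, l]); unique(al[!is.na(al)])
  })
  other <- which(gm$meta$group != group)
  np <- 0L
  for (l in seq_len(n_loci(gm))) {
    al_o <- c(gm$a1[other, l], gm$a2[other, l])
    al_o <- al_o[!is.na(al_o)]
    np <- np + sum(!alleles_here[[l]] %in% al_o)
  }
  freqs <- allele_frequencies(gm_subset(gm, groups = group))
  panel <- gm$loci[ok]
  structure(list(
    group = group, n = length(idx),
    Na = mean(lengths(alleles_here)[ok]),
    Np = np,
    Ho = mean(ld$ho[ok]),
    UHe = mean(ld$uhe[ok]),
    Fis = 1 - mean(ld$ho[ok]) / mean(ld$uhe[ok]),
    PID = pid_unrelated(freqs, group, panel),
    PIDsibs = pid_sibs(freqs, group, panel),
    per_locus = data.frame(locus = gm$loci, n = ld$n, Ho = ld$ho, UHe = ld$uhe)
  ), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("group %s (n = %d): Na = %.2f, Np = %d, Ho = %.3f, UHe = %.3f, Fis = %.3f\n",
              x$group, x$n, x$Na, x$Np, x$Ho, x$UHe, x$Fis))
  cat(sprintf("  PID = %.3g, PIDsibs = %.3g\n", x$PID, x$PIDsibs))
  invisible(x)
}

#' Multilocus F_IS with a Hardy-Weinberg permutation test
#'
#' F_IS = 1 - Ho/UHe (multilocus: Ho and UHe weighted over loci by the number
#' of genotyped individuals). The null distribution is generated by shuffling
#' gene copies among individuals within each locus, which enforces
#' Hardy-Weinberg proportions while preserving allele frequencies; the
#' p-value is the fraction of replicates with |F_IS| at least as large as
#' observed (with the usual +1 Monte Carlo correction).
#'
#' @param gm a [genotype_matrix()]
#' @param group group name
#' @param n_perm number of permutation replicates (>= 100)
#' @param seed integer RNG seed
#' @return list with `Fis`, `p_value`, `n_perm`.
#' @export
fis_hwe_test <- function(gm, group, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  idx <- which(gm$meta$group == group)
  if (!length(idx)) stop("group not present: ", group)
  fis_of <- function(a1, a2) {
    L <- ncol(a1)
    ho_num <- uhe_num <- den <- 0
    for (l in seq_len(L)) {
      keep <- !is.na(a1[, l])
      n <- sum(keep)
      if (n == 0) next
      p <- table(c(a1[keep, l], a2[keep, l])) / (2 * n)
      uhe <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
      if (uhe <= 0) next  # monomorphic locus carries no information on F_IS
      ho_num <- ho_num + n * mean(a1[keep, l] != a2[keep, l])
      uhe_num <- uhe_num + n * uhe
      den <- den + n
    }
    if (uhe_num == 0) return(NA_real_)
    1 - ho_num / uhe_num
  }
  a1 <- gm$a1[idx, , drop = FALSE]; a2 <- gm$a2[idx, , drop = FALSE]
  obs <- fis_of(a1, a2)
  if (is.na(obs)) stop("all loci monomorphic in group ", group, "; F_IS undefined")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p1 <- a1; p2 <- a2
    for (l in seq_len(ncol(a1))) {
      keep <- which(!is.na(a1[, l]))
      if (length(keep) < 2) next
      copies <- sample(c(a1[keep, l], a2[keep, l]))
      p1[keep, l] <- copies[seq_along(keep)]
      p2[keep, l] <- copies[length(keep) + seq_along(keep)]
    }
    f <- fis_of(p1, p2)
    if (!is.na(f) && abs(f) >= abs(obs)) hits <- hits + 1L
  }
  list(Fis = obs, p_value = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

# internal: G statistic on a two-locus genotype contingency table
.g_stat <- function(x, y) {
  tab <- table(x, y)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- tab > 0
  2 * sum(tab[keep] * log(tab[keep] / E[keep]))
}

#' Pairwise linkage-equilibrium permutation tests
#'
#' For every pair of polymorphic loci within a group, tests association
#' between the two single-locus genotypes with a G statistic on the
#' two-locus genotype contingency table; significance is assessed by
#' permuting one locus's genotypes across individuals. Returns the
#' proportion of pairs significant at `alpha` after Bonferroni correction
#' over the tested pairs.
#'
#' @param gm a [genotype_matrix()]
#' @param group group name (needs >= 2 polymorphic loci)
#' @param n_perm permutation replicates per pair
#' @param alpha family significance level (Bonferroni-corrected per pair)
#' @param seed integer RNG seed
#' @param min_informative minimum individuals genotyped at both loci for a
#'   pair to be tested (default 5); excluded pairs are recorded
#' @return list with `pct_LE` (percent of tested pairs significant),
#'   `p_matrix` (upper-triangular matrix of permutation p-values),
#'   `n_tested`, `n_significant`, `excluded` (data frame of skipped pairs).
#' @export
ld_pairwise_test <- function(gm, group, n_perm = 1000L, alpha = 0.05,
                             seed = 1L, min_informative = 5L) {
  idx <- which(gm$meta$group == group)
  if (!length(idx)) stop("group not present: ", group)
  geno_str <- function(l) {
    out <- paste(gm$a1[idx, l], gm$a2[idx, l], sep = "/")
    out[is.na(gm$a1[idx, l])] <- NA
    out
  }
  gs <- lapply(seq_len(n_loci(gm)), geno_str)
  poly <- vapply(gs, function(x) length(unique(stats::na.omit(x))) > 1, TRUE)
  if (sum(poly) < 2) stop("need >= 2 polymorphic loci in group ", group)
  loci <- which(poly)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  P <- matrix(NA_real_, n_loci(gm), n_loci(gm),
              dimnames = list(gm$loci, gm$loci))
  excluded <- data.frame(locus1 = character(), locus2 = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_along(loci)) for (j in seq_along(loci)) {
    if (j <= i) next
    l1 <- loci[i]; l2 <- loci[j]
    keep <- !is.na(gs[[l1]]) & !is.na(gs[[l2]])
    if (sum(keep) < min_informative) {
      excluded <- rbind(excluded, data.frame(locus1 = gm$loci[l1],
                                             locus2 = gm$loci[l2],
                                             stringsAsFactors = FALSE))
      next
    }
    x <- gs[[l1]][keep]; y <- gs[[l2]][keep]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      excluded <- rbind(excluded, data.frame(locus1 = gm$loci[l1],
                                             locus2 = gm$loci[l2],
                                             stringsAsFactors = FALSE))
      next
    }
    g_obs <- .g_stat(x, y)
    hits <- 0L
    for (b in seq_len(n_perm))
      if (.g_stat(x, sample(y)) >= g_obs) hits <- hits + 1L
    P[l1, l2] <- (hits + 1) / (n_perm + 1)
  }
  ps <- P[!is.na(P)]
  n_tested <- length(ps)
  n_sig <- sum(ps <= alpha / n_tested)
  list(pct_LE = 100 * n_sig / n_tested, p_matrix = P,
       n_tested = n_tested, n_significant = n_sig, excluded = excluded)
}

#' Probability of identity for unrelated individuals
#'
#' Per locus \eqn{PID_l = 2 (\sum_i p_i^2)^2 - \sum_i p_i^4}; the multilocus
#' value is the product over the panel.
#'
#' @param freqs an [allele_frequencies()] table
#' @param group group name
#' @param panel character vector of locus names (all must be defined for the
#'   group)
#' @return multilocus probability of identity.
#' @export
pid_unrelated <- function(freqs, group, panel) {
  out <- 1
  for (l in panel) {
    p <- .freq_or_stop(freqs, group, l)
    out <- out * (2 * sum(p^2)^2 - sum(p^4))
  }
  out
}

#' Probability of identity for full sibs
#'
#' Per locus \eqn{0.25 + 0.5 \sum p_i^2 + 0.5 (\sum p_i^2)^2 -
#' 0.25 \sum p_i^4}; the multilocus value is the product over the panel.
#' Always at least as large as [pid_unrelated()].
#'
#' @inheritParams pid_unrelated
#' @return multilocus sib probability of identity.
#' @export
pid_sibs <- function(freqs, group, panel) {
  out <- 1
  for (l in panel) {
    p <- .freq_or_stop(freqs, group, l)
    s2 <- sum(p^2)
    out <- out * (0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * sum(p^4))
  }
  out
}

# internal RNG bookkeeping: seed-taking functions must not disturb the
# caller's RNG stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
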