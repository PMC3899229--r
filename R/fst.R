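#' Weir-Cockerham theta (F_ST)
#'
#' The 1984 variance-components estimator of F_ST. For each allele at each
#' locus the among-population (a), among-individual-within-population (b) and
#' within-individual (c) variance components are computed with the published
#' unequal-sample-size weighting; per-locus theta is
#' \eqn{\theta_l = \sum_A a / \sum_A (a+b+c)} and the multilocus estimate
#' pools components across loci (ratio of sums, not mean of ratios).
#'
#' @param gm a [genotype_matrix()]
#' @param groups two or more group names (default: all groups)
#' @param scope `"multilocus"` (default), `"per_locus"`, or
#'   `"pairwise_matrix"` (multilocus theta for every pair of groups)
#' @return For `"multilocus"`, a single number. For `"per_locus"`, a named
#'   numeric vector (NA for loci monomorphic across the included groups,
#'   which contribute nothing to the sums). For `"pairwise_matrix"`, a
#'   symmetric matrix of pairwise multilocus estimates.
#' @references Weir & Cockerham (1984) Evolution 38:1358-1370.
#' @export
weir_cockerham_theta <- function(gm, groups = gm_groups(gm),
                                 scope = c("multilocus", "per_locus",
                                           "pairwise_matrix")) {
  scope <- match.arg(scope)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (scope == "pairwise_matrix") {
    G <- length(groups)
    M <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
    for (i in seq_len(G - 1)) for (j in (i + 1):G) {
      M[i, j] <- M[j, i] <- weir_cockerham_theta(gm, groups[c(i, j)], "multilocus")
    }
    diag(M) <- 0
    return(M)
  }
  comps <- .wc_components(gm, groups)
  if (scope == "per_locus") {
    th <- comps$a_l / (comps$a_l + comps$b_l + comps$c_l)
    names(th) <- gm$loci
    return(th)
  }
  tot <- sum(comps$a_l + comps$b_l + comps$c_l, na.rm = TRUE)
  if (tot == 0) stop("no polymorphic loci among the selected groups")
  sum(comps$a_l, na.rm = TRUE) / tot
}

# internal: per-locus summed variance components a, b, c over alleles
.wc_components <- function(gm, groups) {
  r <- length(groups)
  idx <- lapply(groups, function(g) which(gm$meta$group == g))
  L <- n_loci(gm)
  a_l <- b_l <- c_l <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    n_i <- numeric(r)
    freq_i <- vector("list", r)
    het_i <- vector("list", r)
    alleles <- integer()
    for (i in seq_len(r)) {
      g1 <- gm$a1[idx[[i]], l]; g2 <- gm$a2[idx[[i]], l]
      keep <- !is.na(g1)
      g1 <- g1[keep]; g2 <- g2[keep]
      n_i[i] <- length(g1)
      freq_i[[i]] <- c(g1, g2)
      het_i[[i]] <- list(g1 = g1, g2 = g2)
      alleles <- union(alleles, unique(c(g1, g2)))
    }
    if (length(alleles) < 2 || any(n_i < 2)) next  # monomorphic or unusable
    alleles <- sort(alleles)
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    a_sum <- b_sum <- c_sum <- 0
    for (A in alleles) {
      p_i <- vapply(seq_len(r), function(i)
        mean(freq_i[[i]] == A), 0)
      h_i <- vapply(seq_len(r), function(i) {
        g1 <- het_i[[i]]$g1; g2 <- het_i[[i]]$g2
        mean((g1 != g2) & (g1 == A | g2 == A))
      }, 0)
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      a_sum <- a_sum + a; b_sum <- b_sum + b; c_sum <- c_sum + cc
    }
    a_l[l] <- a_sum; b_l[l] <- b_sum; c_l[l] <- c_sum
  }
  list(a_l = a_l, b_l = b_l, c_l = c_l)
}
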