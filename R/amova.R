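#' One-level AMOVA (PhiPT) on a pairwise distance matrix
#'
#' Partitions squared pairwise distances among and within groups and returns
#' PhiPT, the distance-based analogue of F_ST:
#' \eqn{\Phi_{PT} = \sigma^2_{among} / (\sigma^2_{among} + \sigma^2_{within})}.
#' Significance is assessed by permuting group labels.
#'
#' For microsatellite genotypes the conventional input is squared Euclidean
#' distance on per-individual allele-count vectors ([gm_allele_count_dist()]);
#' for haplotypes, a 0/1 mismatch distance.
#'
#' @param distances symmetric non-negative distance matrix with zero diagonal
#' @param groups per-individual group labels (length = nrow(distances));
#'   groups of size 1 are allowed but flagged
#' @param n_perm label permutations for the p-value (0 to skip)
#' @param seed integer RNG seed
#' @return list with `phi_pt`, `p_value`, variance components
#'   (`sigma_among`, `sigma_within`), the sums of squares, and `flags`.
#' @export
amova_phipt <- function(distances, groups, n_perm = 999L, seed = 1L) {
  d <- as.matrix(distances)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (length(groups) != nrow(d)) stop("groups must label every row of the matrix")
  groups <- as.character(groups)
  flags <- character()
  sizes <- table(groups)
  if (any(sizes == 1))
    flags <- c(flags, sprintf("group(s) of size 1: %s",
                              paste(names(sizes)[sizes == 1], collapse = ", ")))

  phi_of <- function(grp) {
    N <- length(grp)
    G <- length(unique(grp))
    d2 <- d^2
    ss_total <- sum(d2[upper.tri(d2)]) / N
    ss_within <- 0
    n_g <- integer(0)
    for (g in unique(grp)) {
      ii <- which(grp == g)
      n_g <- c(n_g, length(ii))
      if (length(ii) > 1) {
        sub <- d2[ii, ii, drop = FALSE]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(ii)
      }
    }
    ss_among <- ss_total - ss_within
    df_among <- G - 1; df_within <- N - G
    if (df_among == 0 || df_within == 0) return(c(NA, NA, NA, ss_among, ss_within))
    ms_among <- ss_among / df_among
    ms_within <- ss_within / df_within
    n0 <- (N - sum(n_g^2) / N) / df_among
    sig_within <- ms_within
    sig_among <- (ms_among - ms_within) / n0
    phi <- sig_among / (sig_among + sig_within)
    c(phi, sig_among, sig_within, ss_among, ss_within)
  }

  obs <- phi_of(groups)
  p <- NA_real_
  if (n_perm > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm))
      if (phi_of(sample(groups))[1] >= obs[1]) hits <- hits + 1L
    p <- (hits + 1) / (n_perm + 1)
  }
  list(phi_pt = obs[1], p_value = p, sigma_among = obs[2], sigma_within = obs[3],
       ss_among = obs[4], ss_within = obs[5], flags = flags)
}

#' Squared-Euclidean genotype distance on allele-count vectors
#'
#' Encodes each individual as its vector of per-allele copy counts (0/1/2 at
#' each autosomal locus) and returns the pairwise Euclidean distance matrix;
#' its square is the conventional AMOVA input for microsatellite genotypes.
#' Loci missing in either member of a pair are dropped for that pair and the
#' remaining sum is rescaled to the full locus count.
#'
#' @param gm a [genotype_matrix()]
#' @return an N x N distance matrix (Euclidean; square it for AMOVA sums).
#' @export
gm_allele_count_dist <- function(gm) {
  alleles <- gm_alleles(gm)
  N <- n_ind(gm); L <- n_loci(gm)
  # per-locus count blocks
  blocks <- vector("list", L)
  for (l in seq_len(L)) {
    B <- matrix(0, N, length(alleles[[l]]))
    miss <- is.na(gm$a1[, l])
    for (i in seq_len(N)) {
      if (miss[i]) { B[i, ] <- NA; next }
      j1 <- match(gm$a1[i, l], alleles[[l]]); j2 <- match(gm$a2[i, l], alleles[[l]])
      B[i, j1] <- B[i, j1] + 1; B[i, j2] <- B[i, j2] + 1
    }
    blocks[[l]] <- B
  }
  D <- matrix(0, N, N, dimnames = list(gm$meta$id, gm$meta$id))
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    tot <- 0; used <- 0L
    for (l in seq_len(L)) {
      bi <- blocks[[l]][i, ]; bj <- blocks[[l]][j, ]
      if (anyNA(bi) || anyNA(bj)) next
      tot <- tot + sum((bi - bj)^2)
      used <- used + 1L
    }
    if (used > 0) tot <- tot * L / used
    D[i, j] <- D[j, i] <- sqrt(tot)
  }
  D
}

#' 0/1 haplotype mismatch distance
#'
#' @param haplotypes character vector of haplotype labels (one per
#'   individual)
#' @return an N x N matrix with 0 for identical haplotypes, 1 otherwise.
#' @export
haplotype_mismatch_dist <- function(haplotypes) {
  D <- outer(haplotypes, haplotypes, FUN = `!=`) * 1
  dimnames(D) <- list(names(haplotypes), names(haplotypes))
  D
}
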