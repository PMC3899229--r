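# Shared builders and independent oracles used across the suite.

# build a genotype_matrix from two allele matrices and a group vector
toy_gm <- function(a1, a2, groups, loci = NULL, popflag = FALSE, ids = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  if (is.null(ids)) ids <- sprintf("i%03d", seq_len(nrow(a1)))
  genotype_matrix(a1, a2,
                  data.frame(id = ids, group = groups, popflag = popflag,
                             stringsAsFactors = FALSE),
                  loci)
}

# random population under Hardy-Weinberg equilibrium from given frequencies
hwe_gm <- function(n, freqs, group = "A", seed = 1, popflag = FALSE) {
  # freqs: list per locus of frequency vectors (alleles are 1..k)
  withr::with_seed(seed, {
    L <- length(freqs)
    a1 <- a2 <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) {
      a1[, l] <- sample.int(length(freqs[[l]]), n, TRUE, prob = freqs[[l]])
      a2[, l] <- sample.int(length(freqs[[l]]), n, TRUE, prob = freqs[[l]])
    }
    toy_gm(a1, a2, rep(group, n), popflag = popflag,
           ids = sprintf("%s_%03d", group, seq_len(n)))
  })
}

# independent Weir-Cockerham oracle: classic ANOVA on gene-copy indicator
# variables (distinct algebra path from the package's direct a/b/c formulas)
wc_theta_oracle <- function(gm, groups) {
  pops <- lapply(groups, function(g) {
    idx <- which(gm$meta$group == g)
    lapply(seq_len(n_loci(gm)), function(l) {
      keep <- idx[!is.na(gm$a1[idx, l])]
      cbind(gm$a1[keep, l], gm$a2[keep, l])
    })
  })
  num <- den <- 0
  for (l in seq_len(n_loci(gm))) {
    mats <- lapply(pops, `[[`, l)
    n_i <- vapply(mats, nrow, 0)
    alleles <- sort(unique(unlist(mats)))
    if (length(alleles) < 2 || any(n_i < 2)) next
    r <- length(mats)
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (a in alleles) {
      SS_G <- SS_I <- SS_P <- 0
      xbar <- sum(vapply(mats, function(g) sum(g == a), 0)) / (2 * sum(n_i))
      for (p in seq_len(r)) {
        x <- (mats[[p]] == a) * 1
        xi <- rowMeans(x)
        xp <- mean(x)
        SS_G <- SS_G + sum((x - xi)^2)
        SS_I <- SS_I + 2 * sum((xi - xp)^2)
        SS_P <- SS_P + 2 * nrow(x) * (xp - xbar)^2
      }
      MS_G <- SS_G / sum(n_i)
      MS_I <- SS_I / sum(n_i - 1)
      MS_P <- SS_P / (r - 1)
      s2_G <- MS_G
      s2_I <- (MS_I - MS_G) / 2
      s2_P <- (MS_P - MS_I) / (2 * nc)
      num <- num + s2_P
      den <- den + s2_P + s2_I + s2_G
    }
  }
  num / den
}

# enumeration oracle for the six-class locus likelihood: sum over ordered
# origin assignments of the two gene copies
class_lik_oracle <- function(a, b, class, pW, pD) {
  phi <- genotype_origin_weights()[class, ]
  ordered <- list(c("W", "W"), c("W", "D"), c("D", "W"), c("D", "D"))
  wts <- c(phi[["WW"]], phi[["WD"]] / 2, phi[["WD"]] / 2, phi[["DD"]])
  src <- list(W = pW, D = pD)
  tot <- 0
  for (j in seq_along(ordered)) {
    s1 <- src[[ordered[[j]][1]]]; s2 <- src[[ordered[[j]][2]]]
    g <- if (a == b) s1[a] * s2[a] else s1[a] * s2[b] + s1[b] * s2[a]
    tot <- tot + wts[j] * g
  }
  tot
}

# two well-separated populations sharing no alleles (diagnostic loci)
diagnostic_pair <- function(n = 10, L = 5) {
  gmA <- toy_gm(matrix(1L, n, L), matrix(1L, n, L), rep("A", n),
                ids = sprintf("A%02d", 1:n))
  gmB <- toy_gm(matrix(2L, n, L), matrix(2L, n, L), rep("B", n),
                ids = sprintf("B%02d", 1:n))
  gm_rbind(gmA, gmB)
}
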