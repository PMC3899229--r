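#' Queller-Goodnight relatedness
#'
#' The symmetric multilocus relatedness estimator: per-locus numerators and
#' denominators are computed with each member of the pair as focal
#' individual, summed over loci before taking the ratio, and the two focal
#' directions are pooled. Reference allele frequencies are supplied
#' externally (e.g., from the population the pair belongs to).
#'
#' @param gm a [genotype_matrix()]
#' @param individuals character vector of 2 or more individual ids; with
#'   more than 2, all pairwise values are computed
#' @param ref_freqs an [allele_frequencies()] table
#' @param ref_group group of `ref_freqs` providing the reference frequencies
#' @return for a pair, a single relatedness value; for a set, a list with
#'   the pairwise matrix `r_matrix` and `mean_r`. Pairs whose denominator is
#'   zero over all loci are returned as NA.
#' @references Queller & Goodnight (1989) Evolution 43:258-275.
#' @export
queller_goodnight_r <- function(gm, individuals, ref_freqs, ref_group) {
  ii <- match(individuals, gm$meta$id)
  if (anyNA(ii)) stop("unknown individuals: ",
                      paste(individuals[is.na(ii)], collapse = ", "))
  if (length(ii) < 2) stop("need at least 2 individuals")

  r_pair <- function(x, y) {
    num <- den <- 0
    any_locus <- FALSE
    for (l in seq_len(n_loci(gm))) {
      a <- gm$a1[x, l]; b <- gm$a2[x, l]
      c_ <- gm$a1[y, l]; d <- gm$a2[y, l]
      if (is.na(a) || is.na(c_)) next
      f <- ref_freqs$freq[[ref_group]][[gm$loci[l]]]
      if (is.null(f)) next
      pa <- f[as.character(a)]; pb <- f[as.character(b)]
      pc <- f[as.character(c_)]; pd <- f[as.character(d)]
      if (anyNA(c(pa, pb, pc, pd))) next  # allele absent from reference
      any_locus <- TRUE
      # focal x
      sim_x <- 0.5 * ((a == c_) + (a == d) + (b == c_) + (b == d))
      num <- num + (sim_x - pa - pb)
      den <- den + (1 + (a == b) - pa - pb)
      # focal y
      sim_y <- 0.5 * ((c_ == a) + (c_ == b) + (d == a) + (d == b))
      num <- num + (sim_y - pc - pd)
      den <- den + (1 + (c_ == d) - pc - pd)
    }
    if (!any_locus || den == 0) return(NA_real_)
    num / den
  }

  if (length(ii) == 2) return(r_pair(ii[1], ii[2]))
  n <- length(ii)
  R <- matrix(NA_real_, n, n, dimnames = list(individuals, individuals))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    R[i, j] <- R[j, i] <- r_pair(ii[i], ii[j])
  list(r_matrix = R, mean_r = mean(R[upper.tri(R)], na.rm = TRUE))
}
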