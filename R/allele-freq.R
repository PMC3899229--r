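#' Per-group, per-locus allele frequencies
#'
#' Estimates allele frequency vectors for each group at each locus from
#' non-missing gene copies only. A group x locus cell with zero non-missing
#' copies is flagged undefined (frequencies are `NULL`, not zero).
#'
#' @param gm a [genotype_matrix()]
#' @param groups groups to tabulate (default: all groups present)
#' @return an object of class `allele_freq_table`: a list with elements
#'   `groups`, `loci`, `alleles` (observed allele labels per locus over the
#'   whole dataset), `freq` (`freq[[group]][[locus]]` is a named numeric
#'   vector over that locus's alleles, or `NULL` when undefined) and
#'   `n_copies` (gene copies used, `n_copies[[group]][locus]`).
#' @export
allele_frequencies <- function(gm, groups = gm_groups(gm)) {
  if (!length(groups)) stop("'groups' must be nonempty")
  missing_g <- setdiff(groups, gm$meta$group)
  if (length(missing_g)) stop("groups not present: ", paste(missing_g, collapse = ", "))
  alleles <- gm_alleles(gm)
  freq <- list(); ncp <- list()
  for (g in groups) {
    idx <- which(gm$meta$group == g)
    fg <- vector("list", n_loci(gm)); names(fg) <- gm$loci
    ng <- integer(n_loci(gm)); names(ng) <- gm$loci
    for (l in seq_len(n_loci(gm))) {
      al <- c(gm$a1[idx, l], gm$a2[idx, l])
      al <- al[!is.na(al)]
      ng[l] <- length(al)
      if (length(al)) {
        tab <- table(factor(al, levels = alleles[[l]]))
        fg[[l]] <- as.numeric(tab) / length(al)
        names(fg[[l]]) <- as.character(alleles[[l]])
      } else {
        fg[[l]] <- NULL  # undefined, not zero
      }
    }
    freq[[g]] <- fg; ncp[[g]] <- ng
  }
  structure(list(groups = groups, loci = gm$loci, alleles = alleles,
                 freq = freq, n_copies = ncp),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d group(s) x %d loci\n",
              length(x$groups), length(x$loci)))
  undef <- sum(vapply(x$groups, function(g) sum(x$n_copies[[g]] == 0), 0L))
  if (undef) cat(sprintf("  %d undefined group x locus cell(s)\n", undef))
  invisible(x)
}

# internal: frequency vector or informative error
.freq_or_stop <- function(freqs, group, locus) {
  if (!group %in% freqs$groups) stop("group not in frequency table: ", group)
  f <- freqs$freq[[group]][[locus]]
  if (is.null(f)) stop(sprintf("allele frequencies undefined for group %s at locus %s",
                               group, locus))
  f
}

#' Allele frequency differential between two groups at one locus
#'
#' The absolute allele-frequency differential
#' \eqn{\delta = \tfrac12 \sum_a |p_A(a) - p_B(a)|}, a classic single-locus
#' measure of ancestry informativeness bounded in \[0, 1\].
#'
#' @param freqs an [allele_frequencies()] table
#' @param groupA,groupB group names
#' @param locus locus name
#' @return the differential \eqn{\delta} as a single number.
#' @export
allele_freq_differential <- function(freqs, groupA, groupB, locus) {
  pa <- .freq_or_stop(freqs, groupA, locus)
  pb <- .freq_or_stop(freqs, groupB, locus)
  sum(abs(pa - pb)) / 2
}
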