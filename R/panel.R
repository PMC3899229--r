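# Marker-panel ranking and nested panel construction.

#' Rank loci by between-group differentiation
#'
#' Per-locus Weir-Cockerham theta between two reference groups, in
#' descending order; ties are broken by the allele-frequency differential
#' delta, then by locus name. Loci monomorphic in both groups have undefined
#' theta and rank last.
#'
#' @param gm a [genotype_matrix()]
#' @param groupA,groupB reference group names (e.g., wolves and dogs)
#' @return a data frame of class `locus_score`: locus, theta, delta,
#'   rank_theta, rank_delta, ordered by the theta ranking.
#' @export
rank_by_fst <- function(gm, groupA, groupB) {
  theta <- weir_cockerham_theta(gm, c(groupA, groupB), "per_locus")
  freqs <- allele_frequencies(gm, c(groupA, groupB))
  delta <- vapply(gm$loci, function(l) {
    fa <- freqs$freq[[groupA]][[l]]; fb <- freqs$freq[[groupB]][[l]]
    if (is.null(fa) || is.null(fb)) return(NA_real_)
    sum(abs(fa - fb)) / 2
  }, 0)
  ord <- order(-ifelse(is.na(theta), -Inf, theta),
               -ifelse(is.na(delta), -Inf, delta), gm$loci)
  out <- data.frame(locus = gm$loci[ord], theta = unname(theta[ord]),
                    delta = unname(delta[ord]), stringsAsFactors = FALSE)
  out$rank_theta <- seq_len(nrow(out))
  out$rank_delta <- match(out$locus,
                          out$locus[order(-ifelse(is.na(out$delta), -Inf, out$delta))])
  class(out) <- c("locus_score", "data.frame")
  out
}

#' Assignment-based greedy locus selection
#'
#' Greedy forward selection: at each step the locus that most increases
#' leave-one-out self-assignment accuracy (two-group Rannala-Mountain
#' likelihood) is added; `assign_gain` records the accuracy increment at
#' inclusion. When accuracy plateaus, the remaining loci are appended in
#' theta order with zero gain.
#'
#' @param gm a [genotype_matrix()]
#' @param groupA,groupB reference group names (a warning is issued below 10
#'   individuals each)
#' @param seed integer RNG seed (used only to break exact ties randomly but
#'   reproducibly)
#' @return a data frame: locus, step, assign_gain, accuracy (cumulative),
#'   in selection order.
#' @export
assignment_based_score <- function(gm, groupA, groupB, seed = 1L) {
  idxA <- which(gm$meta$group == groupA)
  idxB <- which(gm$meta$group == groupB)
  if (length(idxA) < 10 || length(idxB) < 10)
    warning("fewer than 10 individuals in a reference group; scores will be noisy")
  ii <- c(idxA, idxB)
  own <- gm$meta$group[ii]
  enc <- .encode_alleles(gm)
  L <- n_loci(gm)
  # per-locus LOO log-likelihood of each individual under each group
  llA <- llB <- matrix(0, length(ii), L)
  for (l in seq_len(L)) {
    k <- enc$n_alleles[l]
    cntA <- tabulate(c(enc$a1[idxA, l], enc$a2[idxA, l]), nbins = k)
    cntB <- tabulate(c(enc$a1[idxB, l], enc$a2[idxB, l]), nbins = k)
    for (j in seq_along(ii)) {
      i <- ii[j]
      a <- enc$a1[i, l]; b <- enc$a2[i, l]
      if (a == 0L) next
      for (side in 1:2) {
        cnt <- if (side == 1) cntA else cntB
        n <- sum(cnt)
        na_ <- cnt[a]; nb_ <- cnt[b]
        if ((side == 1 && own[j] == groupA) || (side == 2 && own[j] == groupB)) {
          n <- n - 2L
          if (a == b) { na_ <- na_ - 2L; nb_ <- na_ } else { na_ <- na_ - 1L; nb_ <- nb_ - 1L }
        }
        p <- (na_ + 1 / k) / (n + 1) * (nb_ + 1 / k + (a == b)) / (n + 2)
        if (a != b) p <- 2 * p
        if (side == 1) llA[j, l] <- log(max(p, 1e-300)) else llB[j, l] <- log(max(p, 1e-300))
      }
    }
  }
  acc_of <- function(panel) {
    sA <- rowSums(llA[, panel, drop = FALSE])
    sB <- rowSums(llB[, panel, drop = FALSE])
    pred <- ifelse(sA > sB, groupA, ifelse(sB > sA, groupB, NA))
    mean(ifelse(is.na(pred), 0.5, pred == own))
  }
  theta_rank <- rank_by_fst(gm, groupA, groupB)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  chosen <- integer(0)
  remaining <- seq_len(L)
  acc <- 0.5
  out <- data.frame(locus = character(), step = integer(),
                    assign_gain = numeric(), accuracy = numeric(),
                    stringsAsFactors = FALSE)
  repeat {
    if (!length(remaining)) break
    accs <- vapply(remaining, function(l) acc_of(c(chosen, l)), 0)
    best_acc <- max(accs)
    if (best_acc <= acc + 1e-12 && length(chosen) > 0) {
      # plateau: append the rest in theta order with zero gain
      rest <- remaining[order(match(gm$loci[remaining], theta_rank$locus))]
      for (l in rest)
        out <- rbind(out, data.frame(locus = gm$loci[l], step = nrow(out) + 1L,
                                     assign_gain = 0, accuracy = acc,
                                     stringsAsFactors = FALSE))
      break
    }
    cand <- remaining[accs >= best_acc - 1e-12]
    pick <- if (length(cand) > 1) cand[sample.int(length(cand), 1)] else cand
    out <- rbind(out, data.frame(locus = gm$loci[pick], step = nrow(out) + 1L,
                                 assign_gain = best_acc - acc, accuracy = best_acc,
                                 stringsAsFactors = FALSE))
    acc <- best_acc
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, pick)
  }
  out
}

#' Build nested marker panels from a locus ranking
#'
#' Prefix panels of the requested sizes, plus an optional named legacy panel
#' kept verbatim (e.g., a historical monitoring panel chosen for reasons
#' other than divergence). Each panel carries its multilocus theta between
#' the two reference groups, and a consistency report flags loci whose
#' delta-rank differs from their theta-rank by more than L/4.
#'
#' @param ranking a [rank_by_fst()] result
#' @param sizes integer panel sizes (duplicates collapsed)
#' @param gm the [genotype_matrix()] the ranking came from
#' @param groupA,groupB the reference groups
#' @param legacy optional named list of character locus vectors kept verbatim
#' @return a list of class `panel_ranking`: `panels` (named list of locus
#'   vectors, including `full`), `theta` (per panel), `ranking`,
#'   `consistency` (data frame of flagged loci).
#' @export
build_panels <- function(ranking, sizes, gm, groupA, groupB, legacy = NULL) {
  L <- nrow(ranking)
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  if (any(sizes > L)) stop("panel size exceeds number of ranked loci")
  panels <- list(full = ranking$locus)
  for (s in sizes) panels[[paste0("top", s)]] <- ranking$locus[seq_len(s)]
  if (!is.null(legacy)) {
    for (nm in names(legacy)) {
      miss <- setdiff(legacy[[nm]], gm$loci)
      if (length(miss)) stop("legacy panel ", nm, " names unknown loci: ",
                             paste(miss, collapse = ", "))
      panels[[nm]] <- legacy[[nm]]
    }
  }
  theta <- vapply(panels, function(p)
    weir_cockerham_theta(gm_subset(gm, loci = p), c(groupA, groupB)), 0)
  incons <- abs(ranking$rank_theta - ranking$rank_delta) > L / 4
  structure(list(panels = panels, theta = theta, ranking = ranking,
                 consistency = ranking[incons, c("locus", "rank_theta", "rank_delta")]),
            class = "panel_ranking")
}

#' @export
print.panel_ranking <- function(x, ...) {
  cat("panel_ranking:\n")
  for (nm in names(x$panels))
    cat(sprintf("  %-8s %2d loci, theta = %.3f\n", nm, length(x$panels[[nm]]),
                x$theta[[nm]]))
  if (nrow(x$consistency))
    cat(sprintf("  %d locus/loci with inconsistent delta/theta ranks\n",
                nrow(x$consistency)))
  invisible(x)
}
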