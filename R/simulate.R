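# Synthetic parental populations and hybrid-class genotype simulation.
#
# Parental populations follow a Balding-Nichols construction: ancestral
# allele frequencies from a symmetric Dirichlet, population frequencies from
# Dirichlet(p (1-F)/F). F is calibrated by bisection so that the realized
# multilocus Weir-Cockerham theta of the sampled genotypes hits the target;
# a per-population power transform of the frequency vectors (which drives
# rare alleles toward zero, thinning effective allele richness) is calibrated
# the same way against the target heterozygosity. All random draws inside
# the calibration use inverse-CDF transforms of a fixed uniform reservoir,
# so the realized theta is a deterministic, near-monotone function of F and
# the bisection is well behaved.

#' Specification for a pair of synthetic parental populations
#'
#' Defaults reproduce the published study conditions for the Italian system:
#' 39 microsatellite loci, wolf-dog multilocus theta 0.25, observed
#' heterozygosity 0.46 (wolf) and 0.71 (dog), 60 diploid individuals per
#' population.
#'
#' @param n_loci number of autosomal loci
#' @param alleles_per_locus integer vector recycled over loci, or a single
#'   range `c(min, max)` sampled uniformly per locus
#' @param target_fst target multilocus Weir-Cockerham theta between the two
#'   populations (in (0, 1))
#' @param target_Ho length-2 named vector of target heterozygosities
#' @param target_Na length-2 vector of per-population allele richness
#'   (segregating alleles per locus); each population's frequency vectors
#'   are thinned to this many alleles before the heterozygosity calibration
#' @param n_individuals length-2 vector of diploid sample sizes (>= 2)
#' @param pop_names names of the two populations
#' @param seed integer RNG seed
#' @return a list of class `synthetic_pop_spec`.
#' @export
synthetic_pop_spec <- function(n_loci = 39L,
                               alleles_per_locus = c(6L, 14L),
                               target_fst = 0.25,
                               target_Ho = c(W = 0.46, D = 0.71),
                               target_Na = c(W = 4, D = 7),
                               n_individuals = c(60L, 60L),
                               pop_names = c("W", "D"),
                               seed = 1L) {
  if (target_fst <= 0 || target_fst >= 1) stop("target_fst must be in (0,1)")
  if (any(n_individuals < 2)) stop("n_individuals must be >= 2")
  if (length(target_Ho) != 2 || length(n_individuals) != 2)
    stop("target_Ho and n_individuals must have length 2")
  if (any(target_Na < 2)) stop("target_Na must be >= 2")
  structure(list(n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 target_fst = target_fst,
                 target_Ho = unname(target_Ho),
                 target_Na = unname(target_Na),
                 n_individuals = as.integer(n_individuals),
                 pop_names = pop_names,
                 seed = as.integer(seed)),
            class = "synthetic_pop_spec")
}

# inverse-CDF Dirichlet from a matrix of uniforms (rows = categories)
.qdirichlet <- function(u, shape) {
  g <- stats::qgamma(u, shape = shape, rate = 1)
  g[g < 1e-300] <- 1e-300
  g / sum(g)
}

# mean expected heterozygosity of a list of frequency vectors after p^t
.mean_he_pow <- function(freqs, t) {
  mean(vapply(freqs, function(p) {
    q <- p^t; q <- q / sum(q); 1 - sum(q^2)
  }, 0))
}

# apply power transform
.pow_freqs <- function(freqs, t) lapply(freqs, function(p) { q <- p^t; q / sum(q) })

#' Simulate two diverged parental populations
#'
#' Balding-Nichols construction calibrated to a target multilocus theta
#' (tolerance 0.03, bisection on F) and per-population target
#' heterozygosities (tolerance 0.05, bisection on a frequency power
#' transform). Genotypes are drawn under Hardy-Weinberg equilibrium.
#' Identical specs (including seed) give bit-identical output.
#'
#' @param spec a [synthetic_pop_spec()]
#' @return a [genotype_matrix()] with the two populations as groups and an
#'   attribute `calibration` recording the tuned F, power exponents and
#'   realized theta/Ho.
#' @export
simulate_parental_pops <- function(spec) {
  stopifnot(inherits(spec, "synthetic_pop_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  L <- spec$n_loci
  apl <- spec$alleles_per_locus
  k_l <- if (length(apl) == 2 && apl[1] < apl[2])
    sample(apl[1]:apl[2], L, replace = TRUE) else rep_len(apl, L)
  # feasibility: maximum mean He attainable given post-thinning richness
  for (i in 1:2) {
    he_max <- mean(1 - 1 / pmin(k_l, max(2L, round(spec$target_Na[i]))))
    if (spec$target_Ho[i] > he_max - 0.02)
      stop(sprintf("target Ho %.2f infeasible with mean max He %.2f; increase allele richness",
                   spec$target_Ho[i], he_max))
  }
  # ancestral frequencies (symmetric Dirichlet(1))
  anc <- lapply(k_l, function(k) .qdirichlet(stats::runif(k), rep(1, k)))
  # fixed uniform reservoirs: population frequency draws and genotype draws
  u_pop <- lapply(1:2, function(i) lapply(k_l, function(k) stats::runif(k)))
  n_ind <- spec$n_individuals
  u_geno <- lapply(1:2, function(i)
    array(stats::runif(n_ind[i] * L * 2), dim = c(n_ind[i], L, 2)))

  draw_all <- function(F) {
    pops <- vector("list", 2)
    for (i in 1:2) {
      fr <- lapply(seq_len(L), function(l) {
        p <- .qdirichlet(u_pop[[i]][[l]], anc[[l]] * (1 - F) / F)
        # thin to the population's allele richness: keep the most frequent
        # alleles, zero the rest, renormalise
        keep_n <- min(length(p), max(2L, round(spec$target_Na[i])))
        if (keep_n < length(p)) {
          drop <- order(p, decreasing = TRUE)[-seq_len(keep_n)]
          p[drop] <- 0
          p <- p / sum(p)
        }
        p
      })
      # He calibration by power transform
      t_lo <- 0.05; t_hi <- 30
      target <- spec$target_Ho[i]
      for (it in 1:60) {
        t_mid <- sqrt(t_lo * t_hi)
        if (.mean_he_pow(fr, t_mid) > target) t_lo <- t_mid else t_hi <- t_mid
      }
      pops[[i]] <- list(freqs = .pow_freqs(fr, t_lo), exponent = t_lo)
    }
    # genotypes by inverse CDF from the fixed uniforms
    gms <- vector("list", 2)
    for (i in 1:2) {
      a1 <- a2 <- matrix(NA_integer_, n_ind[i], L)
      for (l in seq_len(L)) {
        cp <- cumsum(pops[[i]]$freqs[[l]])
        a1[, l] <- findInterval(u_geno[[i]][, l, 1], cp) + 1L
        a2[, l] <- findInterval(u_geno[[i]][, l, 2], cp) + 1L
      }
      meta <- data.frame(id = sprintf("%s_%03d", spec$pop_names[i], seq_len(n_ind[i])),
                         group = spec$pop_names[i], popflag = TRUE,
                         stringsAsFactors = FALSE)
      gms[[i]] <- genotype_matrix(a1, a2, meta, paste0("L", seq_len(L)))
    }
    gm <- gm_rbind(gms[[1]], gms[[2]])
    list(gm = gm, exponents = vapply(pops, `[[`, 0, "exponent"))
  }

  # bisection on F against realized multilocus theta
  f_lo <- 0.01; f_hi <- 0.9
  res <- NULL
  for (it in 1:40) {
    f_mid <- (f_lo + f_hi) / 2
    res <- draw_all(f_mid)
    th <- weir_cockerham_theta(res$gm, spec$pop_names)
    if (abs(th - spec$target_fst) <= 0.005) break
    if (th > spec$target_fst) f_hi <- f_mid else f_lo <- f_mid
  }
  th <- weir_cockerham_theta(res$gm, spec$pop_names)
  if (abs(th - spec$target_fst) > 0.03)
    warning(sprintf("calibration stopped at realized theta %.3f (target %.3f)",
                    th, spec$target_fst))
  gm <- res$gm
  div <- vapply(spec$pop_names, function(g) {
    idx <- which(gm$meta$group == g)
    ld <- .locus_div(gm, idx)
    mean(ld$ho, na.rm = TRUE)
  }, 0)
  attr(gm, "calibration") <- list(F = (f_lo + f_hi) / 2,
                                  exponents = res$exponents,
                                  realized_theta = th, realized_Ho = div,
                                  seed = spec$seed)
  gm
}

#' Simulate offspring by frequency-pool crossing
#'
#' HybridLab-style crossing: at each locus, every offspring receives one
#' allele drawn from pool A's allele-frequency distribution and one from
#' pool B's, independently across loci. Family structure within pools is
#' deliberately ignored (the pools act as gamete urns).
#'
#' @param poolA,poolB [genotype_matrix()] objects sharing the same loci
#' @param n number of offspring
#' @param seed integer RNG seed
#' @param group group label for the offspring
#' @return a [genotype_matrix()] of `n` offspring.
#' @export
simulate_cross <- function(poolA, poolB, n, seed = 1L, group = "cross") {
  if (!identical(poolA$loci, poolB$loci)) stop("pools must share the same loci")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  L <- n_loci(poolA)
  freq_of <- function(pool, l) {
    al <- c(pool$a1[, l], pool$a2[, l])
    al <- al[!is.na(al)]
    if (!length(al)) stop("locus ", pool$loci[l], " has no alleles in a parental pool")
    tab <- table(al)
    list(alleles = as.integer(names(tab)), p = as.numeric(tab) / length(al))
  }
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    fa <- freq_of(poolA, l); fb <- freq_of(poolB, l)
    a1[, l] <- fa$alleles[sample.int(length(fa$p), n, replace = TRUE, prob = fa$p)]
    a2[, l] <- fb$alleles[sample.int(length(fb$p), n, replace = TRUE, prob = fb$p)]
  }
  meta <- data.frame(id = sprintf("%s_%03d", group, seq_len(n)), group = group,
                     popflag = FALSE, stringsAsFactors = FALSE)
  genotype_matrix(a1, a2, meta, poolA$loci)
}

#' Hybrid genotype classes
#'
#' @return character vector of the supported class labels: parentals,
#'   first- and second-generation hybrids, and first to third generation
#'   backcrosses toward each parental population.
#' @export
hybrid_classes <- function() {
  c("P_W", "P_D", "F1", "F2", "BC1W", "BC1D", "BC2W", "BC2D", "BC3W", "BC3D")
}

#' Expected ancestry fraction of a hybrid class
#'
#' Closed-form pedigree expectation of the fraction of the genome derived
#' from population W: 1 for P_W, 0.5 for F1 and F2, 0.75/0.875/0.9375 for
#' successive backcrosses into W, and the mirrored values toward D.
#'
#' @param class a class label from [hybrid_classes()]
#' @return expected W-ancestry fraction.
#' @export
expected_ancestry <- function(class) {
  vals <- c(P_W = 1, P_D = 0, F1 = 0.5, F2 = 0.5,
            BC1W = 0.75, BC1D = 0.25, BC2W = 0.875, BC2D = 0.125,
            BC3W = 0.9375, BC3D = 0.0625)
  if (!all(class %in% names(vals))) stop("unknown class: ",
                                         paste(setdiff(class, names(vals)), collapse = ", "))
  unname(vals[class])
}

#' Simulate a labeled panel of hybrid genotype classes
#'
#' Builds the pedigree chain F1 = W x D, F2 = F1 x F1, BC1W = F1 x W,
#' BC2W = BC1W x W, BC3W = BC2W x W (mirrored toward D), with every
#' intermediate pool of size `n_per_class`, and assembles the requested
#' classes into one labeled genotype matrix. Simulated parental classes
#' (P_W, P_D) are drawn from the parental pools' allele frequencies
#' (W x W, D x D), matching the treatment of all other classes.
#'
#' @param parents_W,parents_D parental [genotype_matrix()] pools
#' @param classes class labels from [hybrid_classes()]
#' @param n_per_class simulated individuals per class (a warning below 10:
#'   intermediate pool frequencies become noisy)
#' @param seed integer RNG seed
#' @param bc3_from_f2 alternative third-backcross pedigree (F2 x parental
#'   instead of BC2 x parental)
#' @return a list of class `sim_panel`: `gm` (the labeled genotype matrix,
#'   group = class), `classes`, `n_per_class`, `seed`, `pedigree` (text
#'   description per class).
#' @export
simulate_class_panel <- function(parents_W, parents_D, classes = hybrid_classes(),
                                 n_per_class = 60L, seed = 1L,
                                 bc3_from_f2 = FALSE) {
  bad <- setdiff(classes, hybrid_classes())
  if (length(bad)) stop("unknown classes: ", paste(bad, collapse = ", "))
  if (n_per_class < 10)
    warning("n_per_class < 10: intermediate pool allele frequencies will be noisy")
  n <- n_per_class
  pools <- list()
  ped <- c()
  need <- function(cl) cl %in% classes ||
    (cl == "F1" && any(c("F2", "BC1W", "BC1D", "BC2W", "BC2D", "BC3W", "BC3D") %in% classes)) ||
    (cl == "BC1W" && any(c("BC2W", "BC3W") %in% classes) && !bc3_from_f2) ||
    (cl == "BC1D" && any(c("BC2D", "BC3D") %in% classes) && !bc3_from_f2) ||
    (cl == "BC1W" && "BC2W" %in% classes) || (cl == "BC1D" && "BC2D" %in% classes) ||
    (cl == "BC2W" && "BC3W" %in% classes && !bc3_from_f2) ||
    (cl == "BC2D" && "BC3D" %in% classes && !bc3_from_f2) ||
    (cl == "F2" && any(c("BC3W", "BC3D") %in% classes) && bc3_from_f2)
  sub_seed <- function(k) as.integer((as.double(seed) * 131 + k) %% 2147483647)
  if (need("F1")) pools$F1 <- simulate_cross(parents_W, parents_D, n, sub_seed(3L), "F1")
  if (need("F2")) pools$F2 <- simulate_cross(pools$F1, pools$F1, n, sub_seed(4L), "F2")
  if (need("BC1W")) pools$BC1W <- simulate_cross(pools$F1, parents_W, n, sub_seed(5L), "BC1W")
  if (need("BC1D")) pools$BC1D <- simulate_cross(pools$F1, parents_D, n, sub_seed(6L), "BC1D")
  if (need("BC2W")) pools$BC2W <- simulate_cross(pools$BC1W, parents_W, n, sub_seed(7L), "BC2W")
  if (need("BC2D")) pools$BC2D <- simulate_cross(pools$BC1D, parents_D, n, sub_seed(8L), "BC2D")
  if ("BC3W" %in% classes)
    pools$BC3W <- simulate_cross(if (bc3_from_f2) pools$F2 else pools$BC2W,
                                 parents_W, n, sub_seed(9L), "BC3W")
  if ("BC3D" %in% classes)
    pools$BC3D <- simulate_cross(if (bc3_from_f2) pools$F2 else pools$BC2D,
                                 parents_D, n, sub_seed(10L), "BC3D")
  if ("P_W" %in% classes) pools$P_W <- simulate_cross(parents_W, parents_W, n, sub_seed(1L), "P_W")
  if ("P_D" %in% classes) pools$P_D <- simulate_cross(parents_D, parents_D, n, sub_seed(2L), "P_D")
  out <- do.call(gm_rbind, unname(pools[classes]))
  ped <- vapply(classes, function(cl) switch(cl,
    P_W = "W x W", P_D = "D x D", F1 = "W x D", F2 = "F1 x F1",
    BC1W = "F1 x W", BC1D = "F1 x D", BC2W = "BC1W x W", BC2D = "BC1D x D",
    BC3W = if (bc3_from_f2) "F2 x W" else "BC2W x W",
    BC3D = if (bc3_from_f2) "F2 x D" else "BC2D x D"), "")
  structure(list(gm = out, classes = classes, n_per_class = n, seed = seed,
                 pedigree = ped),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("sim_panel: %d classes x %d individuals (%d loci)\n",
              length(x$classes), x$n_per_class, n_loci(x$gm)))
  cat("  ", paste(sprintf("%s (%s)", x$classes, x$pedigree), collapse = ", "), "\n")
  invisible(x)
}
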