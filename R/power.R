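# Threshold calibration and detection-power analysis across panel sizes.

#' Calibrate an ancestry threshold from simulated parentals
#'
#' The admixture-detection threshold t is taken from the self-ancestry
#' distribution of simulated non-admixed parentals: either the minimum
#' (`min_parental`, the default: every simulated parental sits above t, so
#' an observed individual below t cannot be explained as a pure parental) or
#' a lower quantile (`quantile`, gamma-quantile with gamma < 0.5;
#' gamma = 0 coincides with the minimum rule).
#'
#' @param parental_q numeric vector of simulated parental self-ancestry
#'   values (a warning is issued below 50 values per source)
#' @param rule `"min_parental"` or `"quantile"`
#' @param gamma quantile level for the quantile rule (default 0.01)
#' @param panel optional panel label stored for provenance
#' @return a list of class `threshold_calibration`: `threshold`, `rule`,
#'   `gamma`, `n`, `panel`.
#' @export
calibrate_threshold <- function(parental_q, rule = c("min_parental", "quantile"),
                                gamma = 0.01, panel = NULL) {
  rule <- match.arg(rule)
  parental_q <- parental_q[!is.na(parental_q)]
  if (length(parental_q) < 50)
    warning("fewer than 50 simulated parentals; threshold will be noisy")
  if (rule == "quantile" && gamma >= 0.5) stop("gamma must be < 0.5")
  t <- if (rule == "min_parental" || gamma == 0) min(parental_q)
  else stats::quantile(parental_q, probs = gamma, type = 1, names = FALSE)
  if (t <= 0.5)
    warning(sprintf("calibrated threshold %.3f is not above 0.5; parentals poorly resolved", t))
  structure(list(threshold = t, rule = rule, gamma = gamma,
                 n = length(parental_q), panel = panel),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("threshold_calibration: t = %.4f (%s rule, n = %d%s)\n",
              x$threshold, x$rule, x$n,
              if (!is.null(x$panel)) paste0(", panel ", x$panel) else ""))
  invisible(x)
}

#' Detection power per simulated hybrid class
#'
#' For each simulated class, the fraction of individuals detected as admixed
#' under a two-cluster admixture fit: an individual is detected when its
#' ancestry in its nearer parental cluster falls below the calibrated
#' threshold. A credible-interval variant (90% CI upper bound below 1) is
#' reported alongside. Exact binomial confidence intervals accompany every
#' proportion.
#'
#' @param sim a [simulate_class_panel()] result (its classes label the
#'   groups of the fitted individuals)
#' @param fit an [run_admixture_mcmc()] result on (at least) the panel's
#'   individuals, K = 2
#' @param threshold a [calibrate_threshold()] object, a bare number, or a
#'   named vector/list with per-cluster thresholds `W` and `D`
#' @param wolf_class,dog_class group labels of the simulated parental
#'   classes used to orient the two clusters
#' @return a data frame of class `power_table`: class, n, n_detected,
#'   power, ci_lo, ci_hi, n_detected_ci (credible-interval criterion),
#'   power_ci_criterion, expected_ancestry.
#' @export
evaluate_power <- function(sim, fit, threshold,
                           wolf_class = "P_W", dog_class = "P_D") {
  if (fit$K != 2) stop("power evaluation expects a K = 2 admixture fit")
  thr <- threshold
  if (inherits(thr, "threshold_calibration")) thr <- thr$threshold
  if (length(thr) == 1) thr <- c(W = unname(thr), D = unname(thr))
  kW <- cluster_of_group(fit, wolf_class)
  kD <- if (kW == 1) 2L else 1L
  classes <- sim$classes
  rows <- list()
  for (cl in classes) {
    idx <- which(fit$groups == cl)
    if (!length(idx)) next
    qW <- fit$Q[idx, kW]; qD <- fit$Q[idx, kD]
    nearer_is_W <- qW >= qD
    q_par <- ifelse(nearer_is_W, qW, qD)
    t_par <- ifelse(nearer_is_W, thr["W"], thr["D"])
    detected <- q_par < t_par
    # CI criterion: 90% credible interval of the nearer parental ancestry
    # excludes 1 is always true in practice; use upper bound < threshold-free
    # criterion "upper bound < 1 - epsilon" replaced by upper < 1
    upW <- fit$CI90$upper[idx, kW]; upD <- fit$CI90$upper[idx, kD]
    up_par <- ifelse(nearer_is_W, upW, upD)
    detected_ci <- up_par < 1
    n <- length(idx)
    bt <- stats::binom.test(sum(detected), n)
    rows[[cl]] <- data.frame(class = cl, n = n, n_detected = sum(detected),
                             power = mean(detected),
                             ci_lo = bt$conf.int[1], ci_hi = bt$conf.int[2],
                             n_detected_ci = sum(detected_ci),
                             power_ci_criterion = mean(detected_ci),
                             expected_ancestry = expected_ancestry(cl),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("power_table", "data.frame")
  out
}

#' False-positive rates across marker panels
#'
#' For each panel, simulates held-out non-admixed parentals from the
#' reference groups' allele frequencies and runs the empirical-null
#' admixture significance test ([admixture_null_test()]) restricted to that
#' panel; the false-positive rate is the fraction of held-out parentals
#' called significantly admixed, with an exact binomial confidence interval.
#'
#' @param gm reference [genotype_matrix()] containing the parental groups
#' @param ref_groups the two (or more) parental group names
#' @param panels named list of character locus vectors
#' @param n_sim simulated individuals per group for the null (and the same
#'   number held out per group as test parentals)
#' @param alpha significance level
#' @param seed integer RNG seed
#' @param cfg an [admixture_config()] for the underlying runs
#' @return a data frame of class `fp_table`: panel, n_loci, n_test, n_fp,
#'   fp_rate, ci_lo, ci_hi, alpha, seed; 1-locus panels are flagged in a
#'   `note` column (binomial CI necessarily wide).
#' @export
false_positive_sweep <- function(gm, ref_groups, panels, n_sim = 100L,
                                 alpha = 0.05, seed = 1L,
                                 cfg = admixture_config()) {
  rows <- list()
  for (nm in names(panels)) {
    panel <- panels[[nm]]
    sub <- gm_subset(gm, loci = panel)
    freqs <- allele_frequencies(sub, ref_groups)
    old <- .save_rng()
    set.seed(.chain_seed(seed, match(nm, names(panels))))
    tests <- list()
    for (g in ref_groups) {
      a1 <- a2 <- matrix(NA_integer_, n_sim, n_loci(sub))
      for (l in seq_len(n_loci(sub))) {
        f <- freqs$freq[[g]][[sub$loci[l]]]
        if (is.null(f)) next
        al <- as.integer(names(f))
        a1[, l] <- al[sample.int(length(f), n_sim, TRUE, prob = f)]
        a2[, l] <- al[sample.int(length(f), n_sim, TRUE, prob = f)]
      }
      meta <- data.frame(id = sprintf("ho_%s_%03d", g, seq_len(n_sim)),
                         group = paste0("heldout_", g), popflag = FALSE,
                         stringsAsFactors = FALSE)
      tests[[g]] <- genotype_matrix(a1, a2, meta, sub$loci)
    }
    .restore_rng(old)
    allgm <- do.call(gm_rbind, c(list(sub), unname(tests)))
    nt <- admixture_null_test(allgm, ref_groups, n_sim = n_sim, alpha = alpha,
                              seed = .chain_seed(seed, 100L + match(nm, names(panels))),
                              cfg = cfg)
    held <- nt$tests[grepl("^heldout_", nt$tests$group), , drop = FALSE]
    n_test <- nrow(held); n_fp <- sum(held$significant)
    bt <- stats::binom.test(n_fp, n_test)
    rows[[nm]] <- data.frame(panel = nm, n_loci = length(panel),
                             n_test = n_test, n_fp = n_fp,
                             fp_rate = n_fp / n_test,
                             ci_lo = bt$conf.int[1], ci_hi = bt$conf.int[2],
                             alpha = alpha, seed = seed,
                             note = if (length(panel) == 1)
                               "single-locus panel: CI wide" else "",
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fp_table", "data.frame")
  out
}

#' Cross-panel comparison report
#'
#' Tabulates, per panel: multilocus theta, calibrated threshold, per-class
#' detection power, false-positive rate and mean parental credible-interval
#' width, and flags the smallest panel whose F1 + BC1 power is within 2
#' percentage points of the best panel.
#'
#' @param power_tables named list of [evaluate_power()] results (one per
#'   panel)
#' @param thresholds named list of [calibrate_threshold()] objects
#' @param theta named numeric vector of per-panel multilocus theta
#' @param fp_table optional [false_positive_sweep()] result
#' @param ci_width optional named numeric vector of mean parental 90% CI
#'   widths per panel
#' @param panel_sizes optional named integer vector of loci per panel, used
#'   to pick the smallest qualifying panel
#' @return a data frame of class `panel_report`, one row per panel, with
#'   attribute `recommended` naming the flagged panel.
#' @export
panel_comparison_report <- function(power_tables, thresholds, theta,
                                    fp_table = NULL, ci_width = NULL,
                                    panel_sizes = NULL) {
  if (length(power_tables) < 1) stop("no panels supplied")
  nms <- names(power_tables)
  rows <- list()
  for (nm in nms) {
    pt <- power_tables[[nm]]
    f1bc1 <- pt$power[pt$class %in% c("F1", "BC1W", "BC1D")]
    rows[[nm]] <- data.frame(
      panel = nm,
      theta = unname(theta[nm]),
      threshold = thresholds[[nm]]$threshold,
      power_F1 = if ("F1" %in% pt$class) pt$power[pt$class == "F1"] else NA,
      power_BC1 = if (any(c("BC1W", "BC1D") %in% pt$class))
        mean(pt$power[pt$class %in% c("BC1W", "BC1D")]) else NA,
      power_BC2 = if (any(c("BC2W", "BC2D") %in% pt$class))
        mean(pt$power[pt$class %in% c("BC2W", "BC2D")]) else NA,
      power_F1_BC1 = mean(f1bc1),
      fp_rate = if (!is.null(fp_table) && nm %in% fp_table$panel)
        fp_table$fp_rate[fp_table$panel == nm] else NA,
      mean_parental_ci_width = if (!is.null(ci_width)) unname(ci_width[nm]) else NA,
      n_loci = if (!is.null(panel_sizes)) unname(panel_sizes[nm]) else NA,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- max(out$power_F1_BC1, na.rm = TRUE)
  ok <- which(out$power_F1_BC1 >= best - 0.02)
  recommended <- if (!is.null(panel_sizes))
    out$panel[ok[which.min(out$n_loci[ok])]] else utils::tail(out$panel[ok], 1)
  attr(out, "recommended") <- recommended
  class(out) <- c("panel_report", "data.frame")
  out
}

#' Second-backcross misassignment study
#'
#' The panel-power headline experiment: simulate two parental populations
#' calibrated to the study conditions (39 loci, theta 0.25, Ho 0.46/0.71,
#' 60 + 60 parents), simulate 60 individuals in each hybrid class, run a
#' two-cluster admixture analysis on the reference parents and the
#' simulated classes jointly, calibrate per-source thresholds on the
#' simulated parental classes (minimum rule), and report the pooled
#' percentage of second-generation backcrosses whose parental-cluster
#' ancestry is at or above the threshold (i.e., confused with parentals).
#' The percentage is averaged over independent replicate seeds.
#'
#' @param seed master integer seed
#' @param n_seeds replicate simulations to average over (default 5)
#' @param n_loci,target_fst,target_Ho study conditions
#' @param n_per_class simulated individuals per class
#' @param classes simulated classes (must include P_W, P_D, BC2W, BC2D);
#'   the default is the full published design, parentals plus F1/F2 and
#'   three backcross generations toward each parental population
#' @param n_iter,n_burnin,n_chains admixture MCMC control
#' @param verbose print per-seed progress
#' @return a list: `percent_misassigned` (average), `per_seed` (data frame
#'   with per-seed thresholds and counts), `n` (BC2 individuals per seed).
#' @export
bc2_misassignment_study <- function(seed = 1L, n_seeds = 5L, n_loci = 39L,
                                    target_fst = 0.25,
                                    target_Ho = c(W = 0.46, D = 0.71),
                                    n_per_class = 60L,
                                    classes = c("P_W", "P_D", "F1", "F2",
                                                "BC1W", "BC1D", "BC2W", "BC2D",
                                                "BC3W", "BC3D"),
                                    n_iter = 6000L, n_burnin = 1000L,
                                    n_chains = 2L, verbose = FALSE) {
  stopifnot(all(c("P_W", "P_D", "BC2W", "BC2D") %in% classes))
  rows <- list()
  for (r in seq_len(n_seeds)) {
    s <- .chain_seed(seed, 1000L + r)
    par <- simulate_parental_pops(synthetic_pop_spec(
      n_loci = n_loci, target_fst = target_fst, target_Ho = target_Ho,
      n_individuals = c(n_per_class, n_per_class), seed = s))
    sim <- simulate_class_panel(gm_subset(par, groups = "W"),
                                gm_subset(par, groups = "D"),
                                classes = classes, n_per_class = n_per_class,
                                seed = .chain_seed(s, 1L))
    allgm <- gm_rbind(par, sim$gm)
    cfg <- admixture_config(K = 2, n_burnin = n_burnin, n_iter = n_iter,
                            n_chains = n_chains, seed = .chain_seed(s, 2L))
    fit <- run_admixture_mcmc(allgm, cfg)
    kW <- cluster_of_group(fit, "P_W"); kD <- if (kW == 1) 2L else 1L
    tW <- calibrate_threshold(group_self_ancestry(fit, "P_W", kW))$threshold
    tD <- calibrate_threshold(group_self_ancestry(fit, "P_D", kD))$threshold
    bc2W <- fit$Q[fit$groups == "BC2W", kW]
    bc2D <- fit$Q[fit$groups == "BC2D", kD]
    n_mis <- sum(bc2W >= tW) + sum(bc2D >= tD)
    rows[[r]] <- data.frame(seed = s, threshold_W = tW, threshold_D = tD,
                            n_bc2 = length(bc2W) + length(bc2D),
                            n_misassigned = n_mis,
                            pct = 100 * n_mis / (length(bc2W) + length(bc2D)))
    if (verbose)
      message(sprintf("replicate %d/%d: %.1f%% misassigned", r, n_seeds,
                      rows[[r]]$pct))
  }
  per_seed <- do.call(rbind, rows)
  list(percent_misassigned = mean(per_seed$pct), per_seed = per_seed,
       n = per_seed$n_bc2[1])
}
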