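# End-to-end orchestration: simulate -> select panels -> admixture ->
# classify -> calibrate -> consensus -> report.

#' Build a pipeline run configuration
#'
#' All stochastic stages receive explicit seeds derived from the single
#' `seed` field. The configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param seed master integer seed
#' @param out_dir output directory for stage reports
#' @param n_loci,target_fst,target_Ho,n_parents synthetic parental
#'   population settings (defaults: the study conditions - 39 loci, theta
#'   0.25, Ho 0.46/0.71, 60 + 60 parents)
#' @param panel_sizes nested panel sizes built from the locus ranking
#' @param classes simulated hybrid classes
#' @param n_per_class simulated individuals per class
#' @param mcmc_sweeps,mcmc_burnin,mcmc_chains admixture MCMC control
#' @param null_n_sim simulated individuals per group for the empirical-null
#'   false-positive stage
#' @param alpha significance level for the null test
#' @param verbose print stage progress
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("hybridkit_run_"),
                       n_loci = 39L, target_fst = 0.25,
                       target_Ho = c(W = 0.46, D = 0.71),
                       n_parents = c(60L, 60L),
                       panel_sizes = c(24L, 12L),
                       classes = c("P_W", "P_D", "F1", "F2", "BC1W", "BC1D",
                                   "BC2W", "BC2D"),
                       n_per_class = 60L,
                       mcmc_sweeps = 6000L, mcmc_burnin = 1000L,
                       mcmc_chains = 2L,
                       null_n_sim = 60L, alpha = 0.05, verbose = TRUE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_loci = as.integer(n_loci), target_fst = target_fst,
                 target_Ho = as.list(target_Ho),
                 n_parents = as.integer(n_parents),
                 panel_sizes = as.integer(panel_sizes),
                 classes = classes, n_per_class = as.integer(n_per_class),
                 mcmc_sweeps = as.integer(mcmc_sweeps),
                 mcmc_burnin = as.integer(mcmc_burnin),
                 mcmc_chains = as.integer(mcmc_chains),
                 null_n_sim = as.integer(null_n_sim), alpha = alpha,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path YAML file path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, list())
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full hybrid-detection pipeline on synthetic data
#'
#' Executes, in order: parental-population simulation calibrated to the
#' study conditions; locus ranking and nested panel construction; hybrid
#' class simulation; per-panel admixture inference with threshold
#' calibration and power evaluation; per-panel empirical-null
#' false-positive estimation; consensus classification of the packaged
#' 30-individual evidence table; and a cross-panel report. Every stage
#' writes a CSV/JSON artifact into `config$out_dir` and the run closes with
#' a manifest (seeds, stage wall-clock, file hashes). A failed stage aborts
#' with the stage name; earlier outputs are preserved.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage_times <- c()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    say("[%s] starting", name)
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    stage_times[[name]] <<- dt
    say("[%s] done in %.1fs", name, dt)
    res
  }
  seed <- config$seed
  out <- list()

  out$parents <- run_stage("simulate_parents", {
    spec <- synthetic_pop_spec(n_loci = config$n_loci,
                               target_fst = config$target_fst,
                               target_Ho = unlist(config$target_Ho),
                               n_individuals = config$n_parents,
                               seed = seed)
    simulate_parental_pops(spec)
  })
  parents <- out$parents
  write_structure_file(parents, file.path(config$out_dir, "parents.str"))

  out$ranking <- run_stage("rank_loci", rank_by_fst(parents, "W", "D"))
  out$panels <- run_stage("build_panels",
    build_panels(out$ranking, config$panel_sizes, parents, "W", "D"))
  utils::write.csv(out$ranking, file.path(config$out_dir, "locus_ranking.csv"),
                   row.names = FALSE)

  out$sim <- run_stage("simulate_classes",
    simulate_class_panel(gm_subset(parents, groups = "W"),
                         gm_subset(parents, groups = "D"),
                         classes = config$classes,
                         n_per_class = config$n_per_class,
                         seed = .chain_seed(seed, 11L)))

  panel_list <- out$panels$panels
  out$power <- list(); out$thresholds <- list(); ci_width <- c()
  for (nm in names(panel_list)) {
    res <- run_stage(paste0("admixture_", nm), {
      sub <- gm_subset(out$sim$gm, loci = panel_list[[nm]])
      cfg <- admixture_config(K = 2, n_burnin = config$mcmc_burnin,
                              n_iter = config$mcmc_sweeps,
                              n_chains = config$mcmc_chains,
                              seed = .chain_seed(seed, 20L + match(nm, names(panel_list))))
      fit <- run_admixture_mcmc(sub, cfg)
      kW <- cluster_of_group(fit, "P_W")
      kD <- if (kW == 1) 2L else 1L
      qW <- group_self_ancestry(fit, "P_W", kW)
      qD <- group_self_ancestry(fit, "P_D", kD)
      thr <- list(W = calibrate_threshold(qW, panel = nm),
                  D = calibrate_threshold(qD, panel = nm))
      pw <- evaluate_power(out$sim, fit,
                           c(W = thr$W$threshold, D = thr$D$threshold))
      idxP <- which(fit$groups %in% c("P_W", "P_D"))
      ciw <- mean(fit$CI90$upper[idxP, ] - fit$CI90$lower[idxP, ])
      list(fit = fit, thr = thr, power = pw, ci_width = ciw)
    })
    out$power[[nm]] <- res$power
    out$thresholds[[nm]] <- calibrate_threshold(
      c(group_self_ancestry(res$fit, "P_W", cluster_of_group(res$fit, "P_W")),
        group_self_ancestry(res$fit, "P_D", cluster_of_group(res$fit, "P_D"))),
      panel = nm)
    ci_width[nm] <- res$ci_width
    utils::write.csv(res$power,
                     file.path(config$out_dir, paste0("power_", nm, ".csv")),
                     row.names = FALSE)
  }

  out$fp <- run_stage("false_positive_sweep", {
    cfg <- admixture_config(K = 2, n_burnin = config$mcmc_burnin,
                            n_iter = config$mcmc_sweeps, n_chains = 1L)
    false_positive_sweep(parents, c("W", "D"), panel_list,
                         n_sim = config$null_n_sim, alpha = config$alpha,
                         seed = .chain_seed(seed, 31L), cfg = cfg)
  })
  utils::write.csv(out$fp, file.path(config$out_dir, "false_positives.csv"),
                   row.names = FALSE)

  out$consensus <- run_stage("consensus", {
    t4 <- load_fixture_tables("table4")
    cc <- consensus_classify_all(t4)
    utils::write.csv(cc, file.path(config$out_dir, "consensus.csv"),
                     row.names = FALSE)
    list(calls = cc, tally = consensus_tally(t4$final_id))
  })

  out$report <- run_stage("panel_report", {
    sizes <- vapply(panel_list, length, 0L)
    rep <- panel_comparison_report(out$power, out$thresholds,
                                   out$panels$theta, out$fp, ci_width, sizes)
    utils::write.csv(rep, file.path(config$out_dir, "panel_report.csv"),
                     row.names = FALSE)
    rep
  })

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hybridkit")),
    seed = seed,
    stage_seconds = as.list(stage_times),
    files = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  say("pipeline complete: %s", config$out_dir)
  invisible(out)
}
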