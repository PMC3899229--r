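# Multi-evidence consensus classification of putative hybrids.
#
# Integrates the probabilistic admixture analyses (Bayesian admixture at
# several panel sizes, assignment scores, reallocation partitioning,
# empirical-null significance, six-class posteriors) with the uniparental
# and K-locus diagnostic markers and phenotype notes into a single final
# identification per individual, through an explicit, configurable scored
# rule system. The published consensus was qualitative; the default ruleset
# formalises it and every decision carries a rule trace.

#' Load a marker-state dictionary
#'
#' Dictionaries map uniparental haplotype labels to diagnostic states. The
#' packaged defaults cover the Italian wolf x dog system: mtDNA W14 is the
#' diagnostic local-wolf haplotype, W16 a non-local wolf haplotype,
#' D-prefixed haplotypes are dog-derived; Y-STR YH17/YH26 are local-wolf,
#' YH05 is shared with dogs, YH32 private. Supply a CSV with columns
#' `haplotype,state` to use other populations' dictionaries.
#'
#' @param type `"mtdna"` or `"ystr"`
#' @param path optional CSV path overriding the packaged dictionary
#' @return named character vector, haplotype -> state.
#' @export
load_marker_dictionary <- function(type = c("mtdna", "ystr"), path = NULL) {
  type <- match.arg(type)
  if (is.null(path))
    path <- system.file("extdata",
                        if (type == "mtdna") "mtdna_states.csv" else "ystr_states.csv",
                        package = "hybridkit", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  states <- if (type == "mtdna") c("local_wolf", "nonlocal_wolf", "dog")
  else c("local_wolf", "dog_shared", "private", "none")
  bad <- setdiff(d$state, states)
  if (length(bad)) stop("unknown ", type, " states: ", paste(bad, collapse = ", "))
  stats::setNames(d$state, d$haplotype)
}

#' Consensus ruleset parameters
#'
#' @param min_signals_f1f2 minimum admixture signals for accepting the
#'   six-class F1/F2 call as final
#' @param min_signals_bc minimum admixture signals for a backcross call
#' @param geneclass_cutoff percent assignment score counting as an
#'   admixture signal
#' @param thresholds named ancestry thresholds for the three panel sizes
#'   (`t39`, `t24`, `t12`)
#' @return a list of class `consensus_ruleset`.
#' @export
consensus_ruleset <- function(min_signals_f1f2 = 4L, min_signals_bc = 2L,
                              geneclass_cutoff = 90,
                              thresholds = c(t39 = 0.985, t24 = 0.980, t12 = 0.960)) {
  structure(list(min_signals_f1f2 = min_signals_f1f2,
                 min_signals_bc = min_signals_bc,
                 geneclass_cutoff = geneclass_cutoff,
                 thresholds = thresholds),
            class = "consensus_ruleset")
}

#' Derive per-individual evidence flags from a multi-method evidence table
#'
#' Converts the raw per-method outputs (as in the packaged `table4`
#' fixture) into boolean evidence flags: Structure-style ancestry below the
#' per-panel threshold in either popinfo mode counts as admixed; assignment
#' percent scores at or above the cutoff count as admixed (39- or 24-locus
#' panel); uniparental haplotypes are translated through the marker
#' dictionaries; the K-locus flag marks KB carriers; phenotype notes other
#' than wild-type/unknown are anomalous.
#'
#' @param evidence data frame in the layout of `load_fixture_tables("table4")`
#' @param ruleset a [consensus_ruleset()]
#' @param mtdna_dict,ystr_dict marker dictionaries
#'   (see [load_marker_dictionary()])
#' @return a data frame of evidence flags, one row per individual.
#' @export
derive_evidence_flags <- function(evidence, ruleset = consensus_ruleset(),
                                  mtdna_dict = load_marker_dictionary("mtdna"),
                                  ystr_dict = load_marker_dictionary("ystr")) {
  t <- ruleset$thresholds
  nh_first <- vapply(strsplit(as.character(evidence$nh), "-"), `[`, "", 1)
  data.frame(
    id = evidence$id,
    structure_admixed_39 = evidence$q39_p0 < t["t39"] | evidence$q39_p1 < t["t39"],
    structure_admixed_24 = evidence$q24_p0 < t["t24"] | evidence$q24_p1 < t["t24"],
    structure_admixed_12 = evidence$q12_p0 < t["t12"] | evidence$q12_p1 < t["t12"],
    geneclass_admixed = evidence$gc39 >= ruleset$geneclass_cutoff |
      evidence$gc24 >= ruleset$geneclass_cutoff,
    flock_hy = evidence$flock == "HY",
    null_test_significant = evidence$baps == "HY",
    nh_class = nh_first,
    mtdna_state = unname(mtdna_dict[as.character(evidence$cr_hap)]),
    y_state = ifelse(is.na(evidence$y_hap), "none",
                     unname(ystr_dict[as.character(evidence$y_hap)])),
    k_melanistic = evidence$k_genotype %in% c("B", "KB_wt", "KB_KB"),
    phenotype_anomalous = !tolower(evidence$phenotype) %in% c("wild-type", "unknown"),
    majority_ancestry = ifelse(evidence$q39_p0 >= 0.5, "W", "D"),
    stringsAsFactors = FALSE)
}

#' Classify one individual from its evidence flags
#'
#' The default scored ruleset counts admixture-indicating signals S among:
#' Structure admixed at 39 and at 24 loci, assignment-score admixed (39 or
#' 24), reallocation call HY, empirical-null significance, and a six-class
#' call in {F1, F2, BC}; a dog-derived uniparental marker (dog mtDNA or
#' dog-shared Y) adds one. Decision: a six-class F1/F2 call with S >= 4 is
#' accepted as is; S >= 2 gives BC, provided at least one signal comes from
#' a method other than the Bayesian-ancestry thresholds (assignment score,
#' reallocation, empirical null, six-class call, or a dog-derived
#' uniparental marker) - marginal threshold crossings alone do not make a
#' backcross; otherwise melanism, anomalous phenotype, non-local wolf
#' mtDNA or a private Y haplotype gives IG (introgressed); a
#' Bayesian-threshold signal (any panel) without corroboration gives FP
#' (false positive); anything else is parental (W or D by majority
#' ancestry). Missing analyses count as abstentions. The rule trace records
#' every fired rule, including contradictions (e.g., a six-class hybrid
#' call with no supporting signal).
#'
#' @param flags one row of [derive_evidence_flags()] output (or an
#'   equivalent named list)
#' @param ruleset a [consensus_ruleset()]
#' @return a list of class `consensus_record`: `id`, `final_id` in
#'   {W, D, F1, F2, BC, IG, FP}, `signals` (S), `rule_trace`.
#' @export
consensus_classify <- function(flags, ruleset = consensus_ruleset()) {
  f <- as.list(flags)
  tr <- character()
  tt <- function(x) isTRUE(as.logical(x))
  sig <- c(structure39 = tt(f$structure_admixed_39),
           structure24 = tt(f$structure_admixed_24),
           geneclass = tt(f$geneclass_admixed),
           flock = tt(f$flock_hy),
           null_test = tt(f$null_test_significant),
           nh = isTRUE(f$nh_class %in% c("F1", "F2", "BC")))
  S <- sum(sig)
  if (any(sig)) tr <- c(tr, paste0("signals: ", paste(names(sig)[sig], collapse = ", ")))
  uni_dog <- isTRUE(f$mtdna_state == "dog") || isTRUE(f$y_state == "dog_shared")
  if (uni_dog) {
    S <- S + 1L
    tr <- c(tr, "dog-derived uniparental marker: +1 signal")
  }
  tr <- c(tr, sprintf("S = %d", S))
  corroborated <- sig["geneclass"] || sig["flock"] || sig["null_test"] ||
    sig["nh"] || uni_dog
  ig_evidence <- tt(f$k_melanistic) || tt(f$phenotype_anomalous) ||
    isTRUE(f$mtdna_state == "nonlocal_wolf") || isTRUE(f$y_state == "private")
  if (isTRUE(f$nh_class %in% c("F1", "F2", "BC")) && S - uni_dog <= 1)
    tr <- c(tr, sprintf("contradiction: six-class call %s with weak signal support", f$nh_class))
  final <- NULL
  if (isTRUE(f$nh_class %in% c("F1", "F2")) && S >= ruleset$min_signals_f1f2) {
    final <- f$nh_class
    tr <- c(tr, sprintf("six-class %s call with S >= %d: final %s",
                        f$nh_class, ruleset$min_signals_f1f2, final))
  } else if (S >= ruleset$min_signals_bc && corroborated) {
    final <- "BC"
    tr <- c(tr, sprintf("S >= %d with non-threshold corroboration: final BC",
                        ruleset$min_signals_bc))
  } else if (ig_evidence) {
    final <- "IG"
    tr <- c(tr, "weak multilocus signal with diagnostic-marker/phenotype evidence: final IG")
  } else if (tt(f$structure_admixed_39) || tt(f$structure_admixed_24) ||
             tt(f$structure_admixed_12)) {
    final <- "FP"
    tr <- c(tr, "Bayesian-threshold signal without corroboration: final FP")
  } else {
    final <- if (identical(f$majority_ancestry, "D")) "D" else "W"
    tr <- c(tr, paste0("no consistent evidence: final parental ", final))
  }
  structure(list(id = f$id, final_id = final, signals = S, rule_trace = tr),
            class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("consensus_record %s: %s (S = %d)\n", x$id, x$final_id, x$signals))
  for (r in x$rule_trace) cat("  -", r, "\n")
  invisible(x)
}

#' Classify every row of an evidence table
#'
#' @param evidence data frame in the `table4` layout
#' @param ruleset a [consensus_ruleset()]
#' @param ... passed to [derive_evidence_flags()]
#' @return data frame: id, final_id, signals, plus `published` (the
#'   fixture's final-ID column) when present, with records in attribute
#'   `records`.
#' @export
consensus_classify_all <- function(evidence, ruleset = consensus_ruleset(), ...) {
  flags <- derive_evidence_flags(evidence, ruleset, ...)
  recs <- lapply(seq_len(nrow(flags)), function(i)
    consensus_classify(flags[i, ], ruleset))
  out <- data.frame(id = flags$id,
                    final_id = vapply(recs, `[[`, "", "final_id"),
                    signals = vapply(recs, `[[`, 0L, "signals"),
                    stringsAsFactors = FALSE)
  if ("final_id" %in% names(evidence)) out$published <- evidence$final_id
  attr(out, "records") <- recs
  out
}

#' Tally consensus classes
#'
#' Counts final identifications and derives the composition of the
#' hybrid/introgressed pool: (BC+IG) and (F1+F2) as percentages of all
#' individuals classified F1, F2, BC or IG. False positives and parentals
#' are counted separately and excluded from those denominators.
#'
#' @param final_ids character vector of final identifications (or a
#'   [consensus_classify_all()] result, whose `final_id` column is used)
#' @return a list of class `consensus_tally`: `counts`, `n_admixed`
#'   (F1+F2+BC+IG), `pct_backcross_introgressed`, `pct_f1_f2` (both NA when
#'   no admixed individuals are present).
#' @export
consensus_tally <- function(final_ids) {
  if (is.data.frame(final_ids)) final_ids <- final_ids$final_id
  lev <- c("W", "D", "F1", "F2", "BC", "IG", "FP")
  bad <- setdiff(unique(final_ids), lev)
  if (length(bad)) stop("unknown final ids: ", paste(bad, collapse = ", "))
  counts <- table(factor(final_ids, levels = lev))
  n_adm <- sum(counts[c("F1", "F2", "BC", "IG")])
  structure(list(
    counts = counts,
    n_admixed = n_adm,
    pct_backcross_introgressed = if (n_adm > 0)
      100 * sum(counts[c("BC", "IG")]) / n_adm else NA_real_,
    pct_f1_f2 = if (n_adm > 0) 100 * sum(counts[c("F1", "F2")]) / n_adm else NA_real_
  ), class = "consensus_tally")
}

#' @export
print.consensus_tally <- function(x, ...) {
  cat("consensus_tally:\n")
  print(x$counts)
  if (!is.na(x$pct_f1_f2))
    cat(sprintf("  BC+IG: %.1f%%, F1+F2: %.1f%% of admixed/introgressed\n",
                x$pct_backcross_introgressed, x$pct_f1_f2))
  else cat("  no admixed individuals: percentages undefined\n")
  invisible(x)
}
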