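# hybridkit

Multilocus detection of hybridization and introgression between wild
canids and free-ranging dogs.

Wolf populations recolonising human-dominated landscapes meet large
numbers of free-ranging dogs, and wolf x dog hybridization threatens the
genetic integrity of the wild populations. Detecting hybrids from
molecular data is routine for first-generation crosses but rapidly
degrades for backcrosses: a second-generation backcross carries only
12.5% of its genome from the minority parent, which a panel of ~40
microsatellites can barely distinguish from a pure parental. hybridkit
is an R toolkit for conservation geneticists facing exactly this
problem: it implements the full analysis chain from genotype files to
final per-individual identifications, together with the simulation
machinery needed to calibrate detection thresholds and quantify power
and false-positive risk for a given marker panel.

## What it implements

* **Data model and I/O** — a `genotype_matrix` container for diploid STR
  calls with per-individual metadata (group, sex, mtDNA and Y-STR
  haplotype labels, K-locus genotype, reference popflag); readers and
  writers for Structure- and Genepop-format text files; dataset
  validation (missingness, monomorphic loci, duplicate genotypes).
* **Population-genetic statistics** — observed/unbiased expected
  heterozygosity, allele counts and private alleles; multilocus
  F<sub>IS</sub> with an allele-permutation Hardy-Weinberg test;
  pairwise linkage-equilibrium G-tests by permutation with Bonferroni
  control; probabilities of identity (PID, PIDsibs); the Weir-Cockerham
  (1984) variance-components F<sub>ST</sub> estimator (per-locus,
  multilocus, pairwise); one-level distance AMOVA (PhiPT) with
  label-permutation significance; Queller-Goodnight relatedness.
* **Marker-panel selection** — per-locus theta ranking, allele-frequency
  differentials, greedy assignment-based selection, and nested panel
  construction with verbatim legacy panels (the 39 -> 24 -> 12 design).
* **Simulation** — a Balding-Nichols generator calibrated to target
  F<sub>ST</sub>, heterozygosity and allele richness, and
  frequency-pool crossing of hybrid classes (F1, F2, BC1-BC3 toward
  either parent), reproducing the behaviour of the HybridLab-style
  tools.
* **Admixture and classification** — a Bayesian admixture Gibbs sampler
  (independent-frequency model, inferred alpha, popflag-anchored
  reference clusters, Ln P(D) and Delta-K model choice, credible
  intervals); Rannala-Mountain leave-one-out assignment; a six-class
  genotype-frequency MCMC (NewHybrids-style); iterated-reallocation
  partitioning (Flock-style); and an empirical-null significance test
  for spurious admixture (Baps-style).
* **Power and thresholds** — threshold calibration from simulated
  parentals, per-class detection power with exact binomial CIs,
  false-positive sweeps across panels, and the packaged
  second-backcross misassignment study.
* **Consensus** — packaged transcriptions of the published Y-STR, mtDNA
  and 30-hybrid evidence tables, marker-state dictionaries, and a
  rule-based consensus classifier with full rule traces that integrates
  every line of evidence into a final identification
  (W/D/F1/F2/BC/IG/FP).

## Worked example

Simulate two reference populations matching a typical wolf/dog contrast
(39 STRs, multilocus theta 0.25, Ho 0.46 vs 0.71), build hybrid classes,
run the admixture sampler, and calibrate a detection threshold:

```r
library(hybridkit)

par <- simulate_parental_pops(synthetic_pop_spec(seed = 42))
diversity_summary(par, "W")
#> group W (n = 60): Na = 3.72, Np = 27, Ho = 0.445, UHe = 0.451, Fis = 0.014
#>   PID = 2.19e-19, PIDsibs = 3.19e-09
diversity_summary(par, "D")
#> group D (n = 60): Na = 5.90, Np = 112, Ho = 0.691, UHe = 0.702, Fis = 0.017
#>   PID = 6.26e-36, PIDsibs = 6.08e-15
weir_cockerham_theta(par, c("W", "D"))
#> [1] 0.2531...

sim <- simulate_class_panel(gm_subset(par, groups = "W"),
                            gm_subset(par, groups = "D"),
                            classes = c("P_W", "P_D", "F1", "BC1W", "BC2W"),
                            n_per_class = 60, seed = 43)
fit <- run_admixture_mcmc(gm_rbind(par, sim$gm),
                          admixture_config(K = 2, n_burnin = 1000,
                                           n_iter = 6000, seed = 44))
kW  <- cluster_of_group(fit, "P_W")
thr <- calibrate_threshold(group_self_ancestry(fit, "P_W", kW))
thr
#> threshold_calibration: t = 0.9863 (min_parental rule, n = 60)
evaluate_power(sim, fit,
               c(W = thr$threshold,
                 D = calibrate_threshold(group_self_ancestry(fit, "P_D", 3 - kW))$threshold))
#>   class  n n_detected power expected_ancestry
#> 1   P_W 60          0   0.0             1.000
#> 2   P_D 60          0   0.0             0.000
#> 3    F1 60         60   1.0             0.500
#> 4  BC1W 60         60   1.0             0.750
#> 5  BC2W 60         54   0.9             0.875
```

Reading the output: both simulated parental classes sit entirely above
the calibrated threshold (detection 0 on the calibration set, by
construction of the minimum rule); every F1 and first-generation
backcross is detected as admixed; 6 of 60 second-generation backcrosses
(10% in this replicate) are confused with parentals — the class whose
12.5% minority genome overlaps the parental noise floor.

The packaged evidence tables work the same way:

```r
ht <- haplotype_table(load_fixture_tables("table3")$counts)
diagnostic_frequency(ht, "W14", "HYIT")
#> $count   26
#> $total   30
#> $percent 87
consensus_tally(load_fixture_tables("table4")$final_id)
#>  W  D F1 F2 BC IG FP
#>  0  0  1  2 13  8  6
#>   BC+IG: 87.5%, F1+F2: 12.5% of admixed/introgressed
```

87% of the putative hybrids carry the diagnostic local-wolf mtDNA
haplotype, and among the individuals with evidence of mixed ancestry the
vast majority are backcrosses or introgressed rather than recent (F1/F2)
hybrids — the signature of hybridization events several generations in
the past.

A full pipeline (`run_pipeline()`, or
`Rscript inst/scripts/hybridkit.R --seed 1 --out run/`) chains
simulation, panel selection, per-panel admixture, threshold/power
calibration, false-positive estimation and the consensus stage, writing
per-stage CSVs and a manifest.

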