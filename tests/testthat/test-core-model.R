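test_that("genotype_matrix enforces its invariants", {
  a1 <- matrix(c(1L, 2L), 2, 2); a2 <- matrix(c(2L, 2L), 2, 2)
  meta <- data.frame(id = c("x", "y"), group = "G")
  gm <- genotype_matrix(a1, a2, meta)
  expect_s3_class(gm, "genotype_matrix")
  # unordered pair stored sorted
  expect_true(all(gm$a1 <= gm$a2, na.rm = TRUE))
  expect_error(genotype_matrix(a1, a2, data.frame(id = c("x", "x"), group = "G")),
               "duplicate")
  bad2 <- a2; bad2[1, 1] <- NA
  expect_error(genotype_matrix(a1, bad2, meta), "half-missing")
  meta_y <- cbind(meta, sex = "F", y_hap = "YH17")
  expect_error(genotype_matrix(a1, a2, meta_y), "female")
})

test_that("structure files round-trip bit-exactly in both layouts", {
  set.seed(42)
  a1 <- matrix(sample(c(1:5, NA), 60, TRUE, prob = c(rep(.18, 5), .1)), 10, 6)
  a2 <- matrix(sample(1:5, 60, TRUE), 10, 6)
  a2[is.na(a1)] <- NA
  gm <- toy_gm(a1, a2, rep(c("wolf", "dog"), each = 5),
               popflag = rep(c(TRUE, FALSE), 5))
  for (fmt in c("two_row", "one_row")) {
    d <- structure_dialect(format = fmt, popflag = TRUE, header = TRUE,
                           group_names = c("wolf", "dog"))
    f <- withr::local_tempfile(fileext = ".str")
    write_structure_file(gm, f, d)
    back <- read_structure_file(f, d)
    expect_identical(back$a1, gm$a1)
    expect_identical(back$a2, gm$a2)
    expect_identical(back$meta$group, gm$meta$group)
    expect_identical(back$meta$popflag, gm$meta$popflag)
    expect_identical(back$loci, gm$loci)
  }
})

test_that("structure parser reports malformed input by line", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c("i1 1 3 4", "i1 1 3 4", "i2 1 3"), f)
  expect_error(read_structure_file(f), "line 3")
  writeLines(c("i1 1 -9 4", "i1 1 2 4"), f)
  expect_warning(gm <- read_structure_file(f), "half-missing")
  expect_equal(sum(is.na(gm$a1)), 1L)  # -9 decodes to missing
})

test_that("genepop files parse 2- and 3-digit coding and round-trip", {
  f <- withr::local_tempfile(fileext = ".gen")
  # mixed 2-/3-digit coding within one locus is rejected
  writeLines(c("title", "locA", "locB", "Pop",
               "w1 , 0101 003005", "w2 , 010101 000000"), f)
  expect_error(read_genepop_file(f), "mixed")
  writeLines(c("title", "locA", "locB", "Pop",
               "w1 , 0101 003005", "w2 , 01021 000000"), f)
  expect_error(read_genepop_file(f), "malformed")
  writeLines(c("title", "locA", "locB", "Pop",
               "w1 , 0101 003005", "w2 , 0102 000000",
               "Pop", "d1 , 0202 004004"), f)
  gm <- read_genepop_file(f)
  expect_equal(n_ind(gm), 3L)
  expect_equal(unname(gm$a1[1, ]), c(1L, 3L))
  expect_equal(unname(gm$a2[1, ]), c(1L, 5L))
  expect_true(is.na(gm$a1[2, 2]))            # 000000 = missing
  expect_equal(gm_groups(gm), c("w1", "d1")) # blocks named by first label
  # round-trip through the writer
  f2 <- withr::local_tempfile(fileext = ".gen")
  write_genepop_file(gm, f2, digits = 3)
  back <- read_genepop_file(f2, group_names = gm_groups(gm))
  expect_identical(back$a1, gm$a1)
  expect_identical(back$a2, gm$a2)
  expect_identical(back$meta$group, gm$meta$group)
})

test_that("allele frequencies use non-missing copies and flag undefined cells", {
  gm <- toy_gm(rbind(c(1L, NA), c(1L, NA)), rbind(c(1L, NA), c(2L, NA)),
               c("A", "A"))
  fr <- allele_frequencies(gm)
  expect_equal(unname(fr$freq$A$L1), c(0.75, 0.25))   # (1,1),(1,2)
  expect_null(fr$freq$A$L2)                           # all-missing: undefined
  expect_equal(unname(fr$n_copies$A), c(4L, 0L))
  expect_error(allele_frequencies(gm, character(0)), "nonempty")
  # every defined vector sums to 1 on a larger random matrix
  gm2 <- hwe_gm(30, list(c(.5, .3, .2), c(.9, .1), c(.25, .25, .25, .25)), seed = 7)
  fr2 <- allele_frequencies(gm2)
  for (l in gm2$loci) expect_equal(sum(fr2$freq$A[[l]]), 1)
})

test_that("fixture tables load with validated printed totals", {
  t2 <- load_fixture_tables("table2")
  t3 <- load_fixture_tables("table3")
  expect_equal(nrow(t2$counts), 17L)
  expect_equal(nrow(t3$counts), 19L)
  # haploid table-3 WIT column is fixed for the diagnostic haplotype
  expect_equal(t3$counts["W14", "WIT"], 63L)
  expect_equal(sum(t3$counts[, "WIT"] > 0), 1L)
  t4 <- load_fixture_tables("table4")
  expect_equal(nrow(t4), 30L)
  expect_true(all(t4$final_id %in% c("F1", "F2", "BC", "IG", "FP")))
})

test_that("corrupted fixtures are rejected", {
  src <- system.file("extdata", "table2_y_haplotypes.csv", package = "hybridkit")
  raw <- read.csv(src, check.names = FALSE)
  raw[1, "WDCZ"] <- raw[1, "WDCZ"] + 1L
  bad_dir <- withr::local_tempdir()
  dir.create(file.path(bad_dir, "extdata"))
  write.csv(raw, file.path(bad_dir, "extdata", "table2_y_haplotypes.csv"),
            row.names = FALSE)
  # loader validates totals against the count matrix
  counts <- as.matrix(raw[!raw$haplotype %in%
                            c("Total males", "Total haplotypes", "Private haplotypes"), -1])
  ht <- haplotype_table(counts)
  printed <- raw[raw$haplotype == "Total males", -1]
  expect_false(all(ht$totals == unlist(printed)))
})

test_that("validate_dataset reports duplicates, monomorphism and missingness", {
  a1 <- rbind(c(1L, 1L), c(1L, 1L), c(2L, 1L))
  a2 <- rbind(c(2L, 1L), c(2L, 1L), c(2L, 1L))
  gm <- toy_gm(a1, a2, c("A", "A", "B"))
  rep <- validate_dataset(gm)
  expect_equal(nrow(rep$duplicates), 1L)          # rows 1 and 2 identical
  expect_true("L2" %in% rep$monomorphic$locus)    # fixed everywhere
  expect_true(length(rep$issues) > 0)
  clean <- hwe_gm(12, replicate(5, c(.3, .3, .2, .2), simplify = FALSE), seed = 3)
  expect_length(validate_dataset(clean)$issues, 0)
})
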