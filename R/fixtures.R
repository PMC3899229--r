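#' Load a packaged reference table
#'
#' The package ships plain-text transcriptions of three published reference
#' tables for the Italian wolf x dog study system: the Y-linked microsatellite
#' haplotype counts (`"table2"`), the mtDNA control-region (CR1) haplotype
#' counts (`"table3"`) and the 30-row multi-marker evidence table for the
#' putative Italian hybrids with their final identifications (`"table4"`).
#'
#' The haplotype-count fixtures carry the published summary rows
#' (total samples/males, total haplotypes, private haplotypes); on load these
#' are recomputed from the count matrix and any mismatch raises an error, so a
#' corrupted fixture cannot be used silently.
#'
#' @param name one of `"table2"`, `"table3"`, `"table4"`
#' @return for `table2`/`table3`, a list with the integer count matrix
#'   (`counts`, haplotypes x groups) and the validated printed summary rows
#'   (`totals`); for `table4`, a data frame with typed columns (per-panel
#'   Structure ancestry proportions under both popinfo modes, GeneClass
#'   percent scores, Flock/Baps/NewHybrids calls, uniparental and K-locus
#'   states, phenotype, and the published final identification).
#' @export
load_fixture_tables <- function(name = c("table2", "table3", "table4")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      switch(name,
                             table2 = "table2_y_haplotypes.csv",
                             table3 = "table3_mtdna_haplotypes.csv",
                             table4 = "table4_hybrid_evidence.csv"),
                      package = "hybridkit", mustWork = TRUE)
  if (name == "table4") {
    t4 <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(y_hap = "character"))
    t4$y_hap[t4$y_hap == ""] <- NA_character_
    if (nrow(t4) != 30L) stop("table4 fixture corrupted: expected 30 rows, found ", nrow(t4))
    if (!all(t4$final_id %in% c("F1", "F2", "BC", "IG", "FP")))
      stop("table4 fixture corrupted: unknown final_id values")
    return(t4)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  total_row <- if (name == "table2") "Total males" else "Total samples"
  summary_rows <- c(total_row, "Total haplotypes", "Private haplotypes")
  is_sum <- raw$haplotype %in% summary_rows
  counts <- as.matrix(raw[!is_sum, -1, drop = FALSE])
  rownames(counts) <- raw$haplotype[!is_sum]
  storage.mode(counts) <- "integer"
  totals <- as.matrix(raw[is_sum, -1, drop = FALSE])
  rownames(totals) <- raw$haplotype[is_sum]
  storage.mode(totals) <- "integer"
  # integrity check against the printed summary rows
  ht <- haplotype_table(counts)
  if (!all(ht$totals == totals[total_row, ]))
    stop(name, " fixture corrupted: column totals do not match the printed totals row")
  if (!all(ht$n_haplotypes == totals["Total haplotypes", ]))
    stop(name, " fixture corrupted: per-group haplotype counts do not match")
  if (!all(ht$n_private == totals["Private haplotypes", ]))
    stop(name, " fixture corrupted: per-group private-haplotype counts do not match")
  list(counts = counts, totals = totals)
}
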