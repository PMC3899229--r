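#' Build a haplotype count table with summary statistics
#'
#' @param counts integer matrix of counts, haplotypes in rows, groups in
#'   columns
#' @return an object of class `haplotype_table`: the count matrix plus
#'   per-group totals, per-group haplotype counts, per-group private-haplotype
#'   counts (haplotypes observed in exactly one group) and the overall number
#'   of distinct haplotypes.
#' @export
haplotype_table <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("negative haplotype counts")
  present <- counts > 0
  private_hap <- rowSums(present) == 1L
  structure(list(
    counts = counts,
    totals = colSums(counts),
    n_haplotypes = colSums(present),
    n_private = colSums(present & private_hap),
    n_distinct = sum(rowSums(counts) > 0)
  ), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d distinct haplotype(s) x %d group(s)\n",
              x$n_distinct, ncol(x$counts)))
  print(rbind(x$counts, Total = x$totals, Haplotypes = x$n_haplotypes,
              Private = x$n_private))
  invisible(x)
}

#' Collapse identical aligned sequences into haplotypes
#'
#' Exact-identity grouping of equal-length aligned sequences (the alignment
#' itself is out of scope). Haplotypes are named in order of first occurrence
#' (`H1`, `H2`, ...) unless a name dictionary mapping sequences to labels is
#' supplied.
#'
#' @param sequences character vector of aligned sequences, optionally named
#'   by individual
#' @param name_map optional named character vector, `names(name_map)` being
#'   sequences and values the haplotype labels to use
#' @return a list with `haplotype` (per-input haplotype label, same order and
#'   names as `sequences`) and `representatives` (named character vector of
#'   one sequence per haplotype).
#' @export
collapse_haplotypes <- function(sequences, name_map = NULL) {
  sequences <- as.character(sequences)
  if (!length(sequences)) stop("no sequences supplied")
  if (length(unique(nchar(sequences))) != 1L)
    stop("sequences have unequal lengths; supply aligned sequences")
  uniq <- unique(sequences)
  labels <- paste0("H", seq_along(uniq))
  names(labels) <- uniq
  if (!is.null(name_map)) {
    hit <- uniq %in% names(name_map)
    labels[uniq[hit]] <- name_map[uniq[hit]]
  }
  hap <- unname(labels[sequences])
  names(hap) <- names(sequences)
  reps <- uniq
  names(reps) <- labels[uniq]
  list(haplotype = hap, representatives = reps)
}

#' Tabulate haplotype assignments by group
#'
#' @param assignments per-individual haplotype labels (`NA` = no haplotype;
#'   such individuals are counted in an attached `missing` vector, not in the
#'   table)
#' @param groups per-individual group labels, same length
#' @return a [haplotype_table()] with an extra `missing` element (per-group
#'   count of individuals without a haplotype).
#' @export
tabulate_haplotypes <- function(assignments, groups) {
  if (length(assignments) != length(groups))
    stop("assignments and groups must have the same length")
  groups <- factor(groups, levels = unique(groups))
  miss <- is.na(assignments)
  tab <- table(factor(assignments[!miss]), groups[!miss])
  ht <- haplotype_table(unclass(as.matrix(tab)))
  ht$missing <- as.integer(table(groups[miss]))
  names(ht$missing) <- levels(groups)
  ht
}

#' Count and percent of a haplotype within a group
#'
#' @param table a [haplotype_table()]
#' @param haplotype haplotype label (absent labels yield count 0)
#' @param group group (column) name
#' @return list with `count`, `total` (group total), and `percent` (rounded
#'   to the nearest integer).
#' @export
diagnostic_frequency <- function(table, haplotype, group) {
  if (!group %in% colnames(table$counts)) stop("group not in table: ", group)
  cnt <- if (haplotype %in% rownames(table$counts))
    table$counts[haplotype, group] else 0L
  tot <- table$totals[[group]]
  list(count = as.integer(cnt), total = as.integer(tot),
       percent = if (tot > 0) as.integer(round(100 * cnt / tot)) else NA_integer_)
}

#' K-locus (CBD103 beta-defensin) genotype counts and frequencies
#'
#' The dominant 3-bp K^B deletion causes melanism; the marker is scored as a
#' three-state genotype (`wt_wt`, `KB_wt`, `KB_KB`), never as an allele
#' frequency, since carriers are distinguishable by assay.
#'
#' @param meta a metadata data frame with columns `group` and `k_genotype`,
#'   or a [genotype_matrix()] (its `$meta` is used)
#' @param group group to tabulate
#' @return list with integer `counts` and `frequencies` over the three
#'   genotype states (missing genotypes excluded from the denominator) and
#'   `n` (individuals with a recorded genotype).
#' @export
klocus_frequencies <- function(meta, group) {
  if (inherits(meta, "genotype_matrix")) meta <- meta$meta
  if (!"k_genotype" %in% names(meta)) stop("no k_genotype column in metadata")
  kg <- meta$k_genotype[meta$group == group]
  kg <- kg[!is.na(kg)]
  lev <- c("wt_wt", "KB_wt", "KB_KB")
  counts <- table(factor(kg, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  n <- sum(counts)
  list(counts = counts,
       frequencies = if (n > 0) counts / n else stats::setNames(rep(NA_real_, 3), lev),
       n = n)
}
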