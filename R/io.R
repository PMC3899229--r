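#' Read a Structure-format genotype file
#'
#' Parses the plain-text genotype format used by the Structure clustering
#' program, in either the two-rows-per-individual layout (default: each
#' individual contributes two lines holding one allele copy per locus) or the
#' one-row layout (two adjacent columns per locus).
#'
#' @param path path to the text file
#' @param dialect a list of parsing options, see [structure_dialect()]
#' @return a [genotype_matrix()]
#' @seealso [write_structure_file()]
#' @export
read_structure_file <- function(path, dialect = structure_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- utils::modifyList(structure_dialect(), dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  offset <- 0L
  loci <- NULL
  if (isTRUE(dialect$header)) {
    loci <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
    offset <- 1L
  }
  rows <- strsplit(trimws(lines[(offset + 1):length(lines)]), "[ \t]+")
  nfix <- 2L + as.integer(isTRUE(dialect$popflag))
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1])[1]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad + offset, ncols[bad], ncols[1]))
  }
  nl_expected <- if (dialect$format == "two_row") ncols[1] - nfix else (ncols[1] - nfix) / 2
  if (!is.null(loci) && length(loci) != nl_expected)
    stop(sprintf("header names %d loci but rows imply %d", length(loci), nl_expected))
  if (dialect$format == "one_row" && (ncols[1] - nfix) %% 2 != 0)
    stop(sprintf("one-row format in %s: %d genotype columns are not an even number",
                 path, ncols[1] - nfix))
  L <- as.integer(nl_expected)
  if (is.null(loci)) loci <- paste0("L", seq_len(L))

  parse_alleles <- function(v, line_no) {
    a <- suppressWarnings(as.integer(v))
    if (anyNA(a))
      stop(sprintf("non-integer allele code on line %d of %s", line_no, path))
    a[a == dialect$missing] <- NA_integer_
    a
  }

  if (dialect$format == "two_row") {
    if (length(rows) %% 2 != 0)
      stop("two-row format requires an even number of data rows, got ", length(rows))
    N <- length(rows) / 2
    a1 <- matrix(NA_integer_, N, L); a2 <- matrix(NA_integer_, N, L)
    ids <- character(N); pops <- character(N); flags <- logical(N)
    for (i in seq_len(N)) {
      r1 <- rows[[2 * i - 1]]; r2 <- rows[[2 * i]]
      if (!identical(r1[seq_len(nfix)], r2[seq_len(nfix)]))
        stop(sprintf("mismatched label/pop fields for individual on lines %d-%d of %s",
                     2 * i - 1 + offset, 2 * i + offset, path))
      ids[i] <- r1[1]; pops[i] <- r1[2]
      flags[i] <- isTRUE(dialect$popflag) && r1[3] == "1"
      a1[i, ] <- parse_alleles(r1[-seq_len(nfix)], 2 * i - 1 + offset)
      a2[i, ] <- parse_alleles(r2[-seq_len(nfix)], 2 * i + offset)
    }
  } else {
    N <- length(rows)
    a1 <- matrix(NA_integer_, N, L); a2 <- matrix(NA_integer_, N, L)
    ids <- character(N); pops <- character(N); flags <- logical(N)
    for (i in seq_len(N)) {
      r <- rows[[i]]
      ids[i] <- r[1]; pops[i] <- r[2]
      flags[i] <- isTRUE(dialect$popflag) && r[3] == "1"
      al <- parse_alleles(r[-seq_len(nfix)], i + offset)
      a1[i, ] <- al[seq(1, 2 * L, by = 2)]
      a2[i, ] <- al[seq(2, 2 * L, by = 2)]
    }
  }
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
    warning(sum(half), " half-missing call(s) set to fully missing")
  }
  groups <- pops
  if (!is.null(dialect$group_names)) {
    gi <- suppressWarnings(as.integer(pops))
    if (anyNA(gi) || any(gi < 1) || any(gi > length(dialect$group_names)))
      stop("pop column values outside the supplied group_names range")
    groups <- dialect$group_names[gi]
  }
  genotype_matrix(a1, a2,
                  data.frame(id = ids, group = groups, popflag = flags,
                             stringsAsFactors = FALSE),
                  loci)
}

#' Structure-format parsing options
#'
#' @param format `"two_row"` (two lines per individual, one allele copy per
#'   line) or `"one_row"` (two adjacent columns per locus)
#' @param missing integer missing-data code (Structure convention: -9)
#' @param popflag logical; is a popflag column present after the pop column?
#' @param header logical; is the first line a whitespace-separated list of
#'   locus names?
#' @param group_names optional character vector translating integer pop codes
#'   (1-based) into group labels
#' @return a named list of options.
#' @export
structure_dialect <- function(format = c("two_row", "one_row"), missing = -9L,
                              popflag = FALSE, header = FALSE,
                              group_names = NULL) {
  list(format = match.arg(format), missing = as.integer(missing),
       popflag = popflag, header = header, group_names = group_names)
}

#' Write a genotype matrix as a Structure-format file
#'
#' @param gm a [genotype_matrix()]
#' @param path output path
#' @param dialect see [structure_dialect()]; `group_names` is ignored (groups
#'   are written as 1-based integers in order of first appearance)
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(gm, path, dialect = structure_dialect()) {
  dialect <- utils::modifyList(structure_dialect(), dialect)
  groups <- gm_groups(gm)
  pop <- match(gm$meta$group, groups)
  con <- file(path, "w")
  on.exit(close(con))
  if (isTRUE(dialect$header)) writeLines(paste(gm$loci, collapse = "\t"), con)
  enc <- function(a) ifelse(is.na(a), dialect$missing, a)
  for (i in seq_len(n_ind(gm))) {
    fix <- c(gm$meta$id[i], pop[i],
             if (isTRUE(dialect$popflag)) as.integer(gm$meta$popflag[i]))
    if (dialect$format == "two_row") {
      writeLines(paste(c(fix, enc(gm$a1[i, ])), collapse = "\t"), con)
      writeLines(paste(c(fix, enc(gm$a2[i, ])), collapse = "\t"), con)
    } else {
      inter <- as.vector(rbind(enc(gm$a1[i, ]), enc(gm$a2[i, ])))
      writeLines(paste(c(fix, inter), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a Genepop-format genotype file
#'
#' Parses the classic Genepop text format: a title line, one locus name per
#' line (or a single comma-separated line), and `Pop`-delimited blocks of
#' individuals with 2- or 3-digit allele coding. `00`/`000` codes mark
#' missing alleles.
#'
#' @param path path to the text file
#' @param group_names optional character vector naming the Pop blocks; by
#'   default each block is named after its first individual label (Genepop
#'   convention)
#' @return a [genotype_matrix()]
#' @export
read_genepop_file <- function(path, group_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a Genepop file (too short): ", path)
  body <- lines[-1]  # drop title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no 'Pop' separator found in ", path)
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  block_of <- findInterval(seq_along(body), pop_idx)
  data_rows <- setdiff(which(block_of >= 1), pop_idx)
  ids <- character(); pops <- integer()
  a1 <- NULL; a2 <- NULL
  digits_by_locus <- rep(NA_integer_, L)
  rows_a1 <- list(); rows_a2 <- list()
  for (r in data_rows) {
    ln <- body[r]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("line %d of %s: expected 'label , genotypes'", r + 1, path))
    id <- trimws(paste(parts[-length(parts)], collapse = ","))
    gts <- strsplit(trimws(parts[length(parts)]), "[ \t]+")[[1]]
    if (length(gts) != L)
      stop(sprintf("line %d of %s: %d genotypes found, %d loci declared",
                   r + 1, path, length(gts), L))
    v1 <- integer(L); v2 <- integer(L)
    for (l in seq_len(L)) {
      g <- gts[l]
      if (!grepl("^[0-9]+$", g) || !(nchar(g) %in% c(4L, 6L)))
        stop(sprintf("line %d of %s: malformed genotype '%s' at locus %s",
                     r + 1, path, g, loci[l]))
      d <- nchar(g) / 2L
      if (is.na(digits_by_locus[l])) digits_by_locus[l] <- d
      else if (digits_by_locus[l] != d)
        stop(sprintf("mixed %d- and %d-digit allele coding at locus %s in %s",
                     2 * digits_by_locus[l], 2 * d, loci[l], path))
      x1 <- as.integer(substr(g, 1, d)); x2 <- as.integer(substr(g, d + 1, 2 * d))
      v1[l] <- if (x1 == 0L) NA_integer_ else x1
      v2[l] <- if (x2 == 0L) NA_integer_ else x2
    }
    rows_a1[[length(rows_a1) + 1]] <- v1
    rows_a2[[length(rows_a2) + 1]] <- v2
    ids <- c(ids, id); pops <- c(pops, block_of[r])
  }
  a1 <- do.call(rbind, rows_a1); a2 <- do.call(rbind, rows_a2)
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) { a1[half] <- NA_integer_; a2[half] <- NA_integer_ }
  if (is.null(group_names)) {
    group_names <- vapply(seq_along(pop_idx), function(b) ids[pops == b][1], "")
  }
  if (length(group_names) != length(pop_idx))
    stop("group_names must name each of the ", length(pop_idx), " Pop blocks")
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_matrix(a1, a2,
                  data.frame(id = ids, group = group_names[pops],
                             stringsAsFactors = FALSE),
                  loci)
}

#' Write a genotype matrix as a Genepop-format file
#'
#' @param gm a [genotype_matrix()]
#' @param path output path
#' @param digits 2 or 3 digits per allele; allele labels must fit
#' @param title title line content
#' @return `path`, invisibly.
#' @export
write_genepop_file <- function(gm, path, digits = 3L, title = "hybridkit export") {
  digits <- as.integer(digits)
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  mx <- suppressWarnings(max(c(gm$a1, gm$a2), na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^digits)
    stop("allele label ", mx, " does not fit ", digits, "-digit coding")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(gm$loci, con)
  fmt <- function(a) sprintf(paste0("%0", digits, "d"), ifelse(is.na(a), 0L, a))
  for (g in gm_groups(gm)) {
    writeLines("Pop", con)
    for (i in which(gm$meta$group == g)) {
      gts <- paste0(fmt(gm$a1[i, ]), fmt(gm$a2[i, ]))
      writeLines(paste0(gm$meta$id[i], " ,  ", paste(gts, collapse = " ")), con)
    }
  }
  invisible(path)
}
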