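#' Construct a diploid multilocus genotype matrix
#'
#' The central data container of hybridkit: diploid microsatellite calls for
#' N individuals at L autosomal loci, together with per-individual metadata
#' (group label, sex, uniparental haplotypes, K-locus genotype, popflag).
#' Allele labels are opaque integers (typically fragment sizes); no
#' repeat-unit arithmetic is ever performed on them.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   copies of each call; `NA` marks a missing call. The pair is unordered and
#'   is stored sorted so that `a1 <= a2` wherever both are present.
#' @param meta data frame of individual metadata with at least columns `id`
#'   and `group`. Optional columns: `sex` ("M", "F" or "unknown"),
#'   `phenotype` (semicolon-separated flag string), `mtdna_hap`, `y_hap`,
#'   `k_genotype` ("wt_wt", "KB_wt" or "KB_KB") and logical `popflag` marking
#'   reference (learning) individuals.
#' @param loci character vector of locus names (defaults to the column names
#'   of `a1`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, meta, loci = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices 'a1' and 'a2' must have identical dimensions")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop("half-missing calls: each call must have both or neither allele")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(meta)))
    stop("'meta' must contain columns 'id' and 'group'")
  if (nrow(meta) != nrow(a1))
    stop("nrow(meta) must equal nrow(a1)")
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id))
    stop("duplicate individual ids: ", paste(meta$id[duplicated(meta$id)], collapse = ", "))
  meta$group <- as.character(meta$group)
  if (is.null(meta$sex)) meta$sex <- "unknown"
  if (is.null(meta$phenotype)) meta$phenotype <- "unknown"
  if (is.null(meta$mtdna_hap)) meta$mtdna_hap <- NA_character_
  if (is.null(meta$y_hap)) meta$y_hap <- NA_character_
  if (is.null(meta$k_genotype)) meta$k_genotype <- NA_character_
  if (is.null(meta$popflag)) meta$popflag <- FALSE
  meta$popflag <- as.logical(meta$popflag)
  bad_k <- !is.na(meta$k_genotype) & !meta$k_genotype %in% c("wt_wt", "KB_wt", "KB_KB")
  if (any(bad_k)) stop("invalid k_genotype values: ", paste(unique(meta$k_genotype[bad_k]), collapse = ", "))
  if (any(!is.na(meta$y_hap) & meta$sex == "F"))
    stop("y_hap recorded for female individuals")
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  if (length(loci) != ncol(a1)) stop("length(loci) must equal ncol(a1)")
  # store the unordered pair in sorted order
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(meta$id, loci)
  structure(list(a1 = a1, a2 = a2, meta = meta, loci = as.character(loci)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci\n", n_ind(x), n_loci(x)))
  tab <- table(x$meta$group)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return integer count.
#' @export
n_ind <- function(gm) nrow(gm$a1)

#' @rdname n_ind
#' @export
n_loci <- function(gm) ncol(gm$a1)

#' Distinct groups present in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return character vector of group labels in order of first appearance.
#' @export
gm_groups <- function(gm) unique(gm$meta$group)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param gm a `genotype_matrix`
#' @param individuals indices, ids or logical mask of individuals to keep
#' @param loci indices, names or logical mask of loci to keep
#' @param groups character vector of group labels to keep (applied after
#'   `individuals`)
#' @return a `genotype_matrix` restricted to the selection.
#' @export
gm_subset <- function(gm, individuals = NULL, loci = NULL, groups = NULL) {
  ii <- seq_len(n_ind(gm))
  if (!is.null(individuals)) {
    if (is.character(individuals)) individuals <- match(individuals, gm$meta$id)
    ii <- ii[individuals]
  }
  if (!is.null(groups)) ii <- ii[gm$meta$group[ii] %in% groups]
  ll <- seq_len(n_loci(gm))
  if (!is.null(loci)) {
    if (is.character(loci)) {
      miss <- setdiff(loci, gm$loci)
      if (length(miss)) stop("unknown loci: ", paste(miss, collapse = ", "))
      loci <- match(loci, gm$loci)
    }
    ll <- ll[loci]
  }
  genotype_matrix(gm$a1[ii, ll, drop = FALSE], gm$a2[ii, ll, drop = FALSE],
                  gm$meta[ii, , drop = FALSE], gm$loci[ll])
}

#' Combine genotype matrices sharing the same loci
#' @param ... `genotype_matrix` objects with identical locus vectors
#' @return a single `genotype_matrix` with individuals stacked.
#' @export
gm_rbind <- function(...) {
  gms <- list(...)
  loci <- gms[[1]]$loci
  for (g in gms) if (!identical(g$loci, loci)) stop("loci differ between matrices")
  genotype_matrix(do.call(rbind, lapply(gms, `[[`, "a1")),
                  do.call(rbind, lapply(gms, `[[`, "a2")),
                  do.call(rbind, lapply(gms, `[[`, "meta")), loci)
}

#' Sorted allele labels observed at each locus
#' @param gm a `genotype_matrix`
#' @return named list of integer vectors, one per locus.
#' @export
gm_alleles <- function(gm) {
  out <- lapply(seq_len(n_loci(gm)), function(l)
    sort(unique(c(gm$a1[, l], gm$a2[, l])[!is.na(c(gm$a1[, l], gm$a2[, l]))])))
  names(out) <- gm$loci
  out
}

#' Validate a genotype dataset
#'
#' Report-only screening of a genotype matrix: per-locus and per-individual
#' missingness, loci monomorphic overall or within a group, and duplicated
#' multilocus genotypes (identical non-missing calls at every locus).
#'
#' @param gm a `genotype_matrix`
#' @return a list of class `gm_validation` with elements `locus_missingness`,
#'   `individual_missingness`, `monomorphic` (data frame of group x locus),
#'   `duplicates` (data frame of id pairs) and `issues` (character summary,
#'   empty when the dataset is clean).
#' @export
validate_dataset <- function(gm) {
  lm <- colMeans(is.na(gm$a1))
  im <- rowMeans(is.na(gm$a1))
  groups <- gm_groups(gm)
  mono <- list()
  for (g in c("<all>", groups)) {
    idx <- if (g == "<all>") seq_len(n_ind(gm)) else which(gm$meta$group == g)
    for (l in seq_len(n_loci(gm))) {
      al <- c(gm$a1[idx, l], gm$a2[idx, l])
      al <- al[!is.na(al)]
      if (length(al) > 0 && length(unique(al)) == 1)
        mono[[length(mono) + 1]] <- data.frame(group = g, locus = gm$loci[l],
                                               stringsAsFactors = FALSE)
    }
  }
  mono <- if (length(mono)) do.call(rbind, mono) else
    data.frame(group = character(), locus = character(), stringsAsFactors = FALSE)
  # duplicate multilocus genotypes: compare full call strings
  key <- apply(cbind(gm$a1, gm$a2), 1L, paste, collapse = "/")
  dup <- data.frame(id1 = character(), id2 = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      ids <- gm$meta$id[key == k]
      prs <- utils::combn(ids, 2)
      dup <- rbind(dup, data.frame(id1 = prs[1, ], id2 = prs[2, ],
                                   stringsAsFactors = FALSE))
    }
  }
  issues <- character()
  if (nrow(dup)) issues <- c(issues, sprintf("%d duplicated multilocus genotype pair(s)", nrow(dup)))
  mono_grp <- mono[mono$group != "<all>", , drop = FALSE]
  if (nrow(mono_grp))
    issues <- c(issues, sprintf("%d monomorphic group x locus combination(s)", nrow(mono_grp)))
  if (any(lm > 0.5)) issues <- c(issues, sprintf("%d locus/loci with >50%% missing data", sum(lm > 0.5)))
  structure(list(locus_missingness = lm, individual_missingness = im,
                 monomorphic = mono, duplicates = dup, issues = issues),
            class = "gm_validation")
}

#' @export
print.gm_validation <- function(x, ...) {
  cat("dataset validation report\n")
  if (!length(x$issues)) cat("  no issues found\n")
  else for (i in x$issues) cat("  -", i, "\n")
  invisible(x)
}
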