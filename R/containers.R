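#' Genotype matrix container
#'
#' Bundles an individuals-by-variants dosage matrix (minor-allele counts,
#' entries 0/1/2, possibly fractional after mean imputation) with a variant
#' map. "R" denotes the reference/major allele and "M" the minor allele, so
#' genotype strata are written RR / RM / MM throughout the package.
#'
#' @param dosage Numeric matrix, individuals in rows (rownames = individual
#'   ids), variants in columns (colnames = variant ids).
#' @param map Data frame with one row per variant: `variant_id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `maf`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map) {
  map <- tibble::as_tibble(map)
  stopifnot(is.matrix(dosage), is.numeric(dosage))
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "maf")
  missing_cols <- setdiff(req, names(map))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("variant map lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- map$variant_id
  if (!identical(colnames(dosage), as.character(map$variant_id))) {
    rlang::abort("dosage column names must equal map$variant_id, in order")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind_%03d", seq_len(nrow(dosage)))
  }
  if (anyDuplicated(map$variant_id) > 0) rlang::abort("duplicate variant ids")
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  chrom(s): %s; MAF range [%.3f, %.3f]\n",
              paste(unique(x$map$chrom), collapse = ","),
              min(x$map$maf), max(x$map$maf)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Molecular phenotype matrix container
#'
#' Individuals-by-phenotypes matrix of molecular measurements (gene counts,
#' transcript abundances, or CpG methylation betas) plus a position map.
#' `group_id` groups transcripts under their gene (and equals
#' `phenotype_id` for genes and CpGs); `pos` is the strand-aware TSS for
#' expression phenotypes or the CpG coordinate for methylation.
#'
#' @param values Numeric matrix, individuals in rows, phenotypes in columns.
#' @param map Data frame with one row per phenotype: `phenotype_id`,
#'   `chrom`, `pos`, `strand`, `group_id`.
#' @return An object of class `pheno_matrix`.
#' @export
pheno_matrix <- function(values, map) {
  map <- tibble::as_tibble(map)
  stopifnot(is.matrix(values), is.numeric(values))
  req <- c("phenotype_id", "chrom", "pos", "strand", "group_id")
  missing_cols <- setdiff(req, names(map))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("phenotype map lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (is.null(colnames(values))) colnames(values) <- map$phenotype_id
  if (!identical(colnames(values), as.character(map$phenotype_id))) {
    rlang::abort("values column names must equal map$phenotype_id, in order")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("ind_%03d", seq_len(nrow(values)))
  }
  if (anyDuplicated(map$phenotype_id) > 0) rlang::abort("duplicate phenotype ids")
  structure(list(values = values, map = map), class = "pheno_matrix")
}

#' @export
print.pheno_matrix <- function(x, ...) {
  cat(sprintf("<pheno_matrix> %d individuals x %d phenotypes (%d group(s))\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$map$group_id))))
  invisible(x)
}

#' @export
dim.pheno_matrix <- function(x) dim(x$values)

# Align two containers on shared individuals (row order of the first).
# Errors listing offenders when the id sets differ.
align_individuals <- function(a_mat, b_mat, a_name = "a", b_name = "b") {
  ia <- rownames(a_mat)
  ib <- rownames(b_mat)
  if (!setequal(ia, ib)) {
    only_a <- setdiff(ia, ib)
    only_b <- setdiff(ib, ia)
    rlang::abort(paste0(
      "individual ids differ between ", a_name, " and ", b_name, ": ",
      if (length(only_a)) paste0("only in ", a_name, ": ",
                                 paste(utils::head(only_a, 5), collapse = ","),
                                 "; ") else "",
      if (length(only_b)) paste0("only in ", b_name, ": ",
                                 paste(utils::head(only_b, 5), collapse = ","))
      else ""))
  }
  b_mat[ia, , drop = FALSE]
}
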