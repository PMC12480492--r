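#' Filter and normalise a molecular phenotype matrix
#'
#' Applies the expression filters and a log + rank-inverse-normal
#' transform. Genes (counts) with fewer than `min_total` total reads are
#' removed; transcripts (fpkm) are kept only when abundance is at least
#' `min_fpkm` in every individual (apply [fpkm_keep_set()] first to
#' implement the "all individuals of at least one condition" rule across
#' conditions); methylation betas are not filtered. Retained phenotypes
#' are log2(x+1)-transformed (counts/fpkm) and then rank-inverse-normal
#' transformed per phenotype, so each column is mean 0, SD ~1.
#'
#' Zero-variance phenotypes are dropped with a warning.
#'
#' @param pheno A [pheno_matrix()] of raw values.
#' @param kind One of `"counts"`, `"fpkm"`, `"beta"`.
#' @param min_total Minimum total read count for a gene (counts).
#' @param min_fpkm Minimum abundance required in all individuals (fpkm).
#' @return A filtered, transformed [pheno_matrix()].
#' @export
normalize_phenotypes <- function(pheno, kind = c("counts", "fpkm", "beta"),
                                 min_total = 50, min_fpkm = 0.5) {
  kind <- match.arg(kind)
  vals <- pheno$values
  if (kind %in% c("counts", "fpkm") && any(vals < 0)) {
    rlang::abort("counts/fpkm input must be nonnegative")
  }
  if (all(vals == 0)) rlang::abort("all-zero phenotype matrix")
  keep <- switch(kind,
    counts = colSums(vals) >= min_total,
    fpkm = apply(vals, 2, min) >= min_fpkm,
    beta = rep(TRUE, ncol(vals)))
  vals <- vals[, keep, drop = FALSE]
  if (ncol(vals) == 0) rlang::abort("no phenotypes pass the filter")
  if (kind %in% c("counts", "fpkm")) vals <- log2(vals + 1)
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(paste0("dropping ", sum(sds == 0),
                       " zero-variance phenotype(s)"))
    vals <- vals[, sds > 0, drop = FALSE]
  }
  vals <- apply(vals, 2, rank_inverse_normal)
  rownames(vals) <- rownames(pheno$values)
  pheno_matrix(vals, pheno$map[match(colnames(vals),
                                     pheno$map$phenotype_id), ])
}

#' Rank-based inverse normal transform
#'
#' `qnorm((rank - 0.5) / n)`; ties share the mean rank.
#'
#' @param x Numeric vector.
#' @return Transformed vector with mean ~0 and SD ~1.
#' @export
rank_inverse_normal <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Transcript ids passing the cross-condition abundance filter
#'
#' Keeps a transcript when its abundance is at least `min_fpkm` in every
#' individual of at least one condition.
#'
#' @param pheno_list Named list of [pheno_matrix()], one per condition,
#'   sharing phenotype ids.
#' @param min_fpkm Minimum abundance.
#' @return Character vector of retained phenotype ids.
#' @export
fpkm_keep_set <- function(pheno_list, min_fpkm = 0.5) {
  ids <- colnames(pheno_list[[1]]$values)
  pass <- vapply(pheno_list, function(pm) {
    apply(pm$values[, ids, drop = FALSE], 2, min) >= min_fpkm
  }, logical(length(ids)))
  ids[rowSums(as.matrix(pass)) > 0]
}

#' Choose the number of expression PCs to use as mapping covariates
#'
#' For each candidate k, the phenotypes are residualised on the top-k
#' expression principal components and the cis scan is rerun; the yield
#' is the number of phenotypes whose best nominal p falls below
#' `p_threshold`. The returned k is the first local maximum of the yield
#' curve (ties break to the smallest k); a monotone-increasing curve
#' returns the grid maximum with a warning. The full curve is returned
#' for audit and plotting.
#'
#' @param pheno Normalised [pheno_matrix()].
#' @param geno [geno_matrix()].
#' @param k_grid Integer grid of PC counts (must stay below
#'   `min(n_individuals, n_phenotypes)`).
#' @param window_bp Cis window half-width.
#' @param p_threshold Nominal significance threshold defining the yield.
#' @param maf_min MAF floor for tested variants.
#' @return List of class `pc_selection`: `k`, `yield` (tibble k, n_hits).
#' @export
select_pc_count <- function(pheno, geno, k_grid = 0:20, window_bp = 1e6,
                            p_threshold = 0.001, maf_min = 0) {
  if (length(k_grid) == 0) rlang::abort("empty k grid")
  k_grid <- sort(unique(as.integer(k_grid)))
  n <- nrow(pheno$values)
  if (max(k_grid) >= min(n, ncol(pheno$values))) {
    rlang::abort("k_grid max must be < min(n_individuals, n_phenotypes)")
  }
  pcs <- stats::prcomp(pheno$values, center = TRUE, scale. = FALSE)$x
  yield <- vapply(k_grid, function(k) {
    cov_k <- if (k > 0) pcs[, seq_len(k), drop = FALSE] else NULL
    hits <- map_cis_nominal(pheno, geno, window_bp = window_bp,
                            covariates = cov_k, maf_min = maf_min)
    if (nrow(hits) == 0) return(0L)
    best <- dplyr::summarise(dplyr::group_by(hits, .data$phenotype_id),
                             p = min(.data$p_nominal), .groups = "drop")
    sum(best$p < p_threshold)
  }, integer(1))
  # first local maximum; monotone increasing -> grid max with warning
  k_chosen <- NA_integer_
  if (length(k_grid) > 1 && all(diff(yield) > 0)) {
    rlang::warn("yield curve monotone increasing; returning grid maximum")
    k_chosen <- k_grid[length(k_grid)]
  } else for (i in seq_along(k_grid)) {
    left_ok <- i == 1 || yield[i] > yield[i - 1]
    right_ok <- i == length(k_grid) || yield[i] >= yield[i + 1]
    if (left_ok && right_ok) { k_chosen <- k_grid[i]; break }
  }
  if (is.na(k_chosen)) {
    rlang::warn("yield curve monotone increasing; returning grid maximum")
    k_chosen <- k_grid[length(k_grid)]
  }
  structure(list(k = k_chosen,
                 yield = tibble::tibble(k = k_grid, n_hits = yield)),
            class = "pc_selection")
}

#' @export
print.pc_selection <- function(x, ...) {
  cat(sprintf("<pc_selection> chosen k = %d (grid %d..%d)\n", x$k,
              min(x$yield$k), max(x$yield$k)))
  invisible(x)
}
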