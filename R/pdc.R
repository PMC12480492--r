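# Pathway-based differential co-expression: hypergeometric
# over-representation of coExQTL partner sets, and the module
# differential connectivity (MDC) permutation test between genotype
# strata.

#' Over-representation analysis against gene sets
#'
#' One-sided hypergeometric tail p per pathway on the 2x2 overlap of the
#' query set with each gene set, restricted to the background universe;
#' BH adjustment across pathways.
#'
#' @param query Character vector of genes (must be a subset of
#'   `background`).
#' @param background Character vector, the gene universe.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param min_set_size Sets with fewer in-background members are skipped.
#' @return Tibble: `pathway`, `n_set`, `n_query`, `n_overlap`, `p`,
#'   `fdr`.
#' @export
ora <- function(query, background, gene_sets, min_set_size = 1) {
  if (length(background) == 0) rlang::abort("empty background")
  if (!all(query %in% background)) {
    rlang::abort("query must be a subset of background")
  }
  query <- unique(query)
  background <- unique(background)
  rows <- purrr::imap_dfr(gene_sets, function(members, nm) {
    set_bg <- intersect(unique(members), background)
    if (length(set_bg) < min_set_size) return(NULL)
    x <- length(intersect(query, set_bg))
    tibble::tibble(
      pathway = nm, n_set = length(set_bg), n_query = length(query),
      n_overlap = x,
      p = stats::phyper(x - 1, length(set_bg),
                        length(background) - length(set_bg),
                        length(query), lower.tail = FALSE))
  })
  if (nrow(rows) == 0) rlang::abort("no usable gene sets")
  rows$fdr <- fdr_bh(rows$p)
  dplyr::arrange(rows, .data$p)
}

# median pairwise |dz| between two strata for an expression submatrix
mdc_stat <- function(X, idx1, idx2, method = "spearman") {
  r1 <- suppressWarnings(stats::cor(X[idx1, , drop = FALSE],
                                    method = method))
  r2 <- suppressWarnings(stats::cor(X[idx2, , drop = FALSE],
                                    method = method))
  clip <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z1 <- atanh(clip(r1))
  z2 <- atanh(clip(r2))
  denom <- sqrt(1 / (length(idx1) - 3) + 1 / (length(idx2) - 3))
  dz <- (z1 - z2) / denom
  stats::median(abs(dz[upper.tri(dz)]))
}

# per-gene connectivity change: median |dz| over that gene's pairs
gene_mdc_stat <- function(X, idx1, idx2, method = "spearman") {
  r1 <- suppressWarnings(stats::cor(X[idx1, , drop = FALSE],
                                    method = method))
  r2 <- suppressWarnings(stats::cor(X[idx2, , drop = FALSE],
                                    method = method))
  clip <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  dz <- (atanh(clip(r1)) - atanh(clip(r2))) /
    sqrt(1 / (length(idx1) - 3) + 1 / (length(idx2) - 3))
  diag(dz) <- NA
  apply(abs(dz), 1, stats::median, na.rm = TRUE)
}

#' Per-gene connectivity change between genotype strata
#'
#' A gene's connectivity within a pathway is its correlation profile to
#' the other members; the change between the two strata is summarised as
#' the median |dz| over the gene's pairs, with a p-value from permuting
#' genotype labels.
#'
#' @param expr [pheno_matrix()] or numeric matrix (individuals x genes).
#' @param strata [stratify()] output (MM vs RR compared by default).
#' @param pathway_genes Genes to analyse (>= 3 required).
#' @param n_perm Label permutations.
#' @param method Correlation estimator.
#' @param compare Which two strata to compare.
#' @param seed Optional seed.
#' @return Tibble: `gene`, `connectivity_change`, `p`.
#' @export
gene_connectivity_change <- function(expr, strata, pathway_genes,
                                     n_perm = 200, method = "spearman",
                                     compare = c("MM", "RR"), seed = NULL) {
  X <- if (inherits(expr, "pheno_matrix")) expr$values else expr
  pathway_genes <- intersect(pathway_genes, colnames(X))
  if (length(pathway_genes) < 3) {
    rlang::abort("pathway needs >= 3 usable genes")
  }
  if (!is.null(seed)) set.seed(seed)
  X <- X[, pathway_genes, drop = FALSE]
  idx1 <- strata[[compare[1]]]
  idx2 <- strata[[compare[2]]]
  obs <- gene_mdc_stat(X, idx1, idx2, method)
  pool <- c(idx1, idx2)
  n1 <- length(idx1)
  exceed <- rep(0L, length(obs))
  for (i in seq_len(n_perm)) {
    sh <- sample(pool)
    perm <- gene_mdc_stat(X, sh[seq_len(n1)], sh[-seq_len(n1)], method)
    exceed <- exceed + (perm >= obs)
  }
  tibble::tibble(gene = pathway_genes, connectivity_change = obs,
                 p = (1 + exceed) / (n_perm + 1))
}

#' Module differential connectivity (MDC) permutation test
#'
#' MDC is the median over all unordered gene pairs of the absolute dz
#' statistic between two genotype strata (Fisher-z difference with the
#' standard sum-of-variances denominator). Only genes passing the
#' gene-level connectivity-change filter (p < `gene_filter_alpha`)
#' contribute; at least 3 passing genes are required. Significance comes
#' from permuting genotype labels: two-sided by default, on the distance
#' of MDC from the permutation-null median, with the `(1 + k)/(1 + N)`
#' estimator so p is never 0.
#'
#' @inheritParams gene_connectivity_change
#' @param n_perm Permutations for the MDC null (>= 100).
#' @param gene_filter Apply the per-gene filter before MDC.
#' @param gene_filter_alpha Per-gene significance threshold.
#' @param gene_filter_perm Permutations for the gene-level filter.
#' @param two_sided Two-tailed on `|MDC - median(null)|`; otherwise the
#'   upper tail.
#' @return One-row tibble (a pathway score): `n_genes_used`,
#'   `genes_used`, `mdc`, `p`.
#' @export
mdc_test <- function(expr, strata, pathway_genes, n_perm = 1000,
                     method = "spearman", compare = c("MM", "RR"),
                     gene_filter = TRUE, gene_filter_alpha = 0.05,
                     gene_filter_perm = 200, two_sided = TRUE,
                     seed = NULL) {
  if (n_perm < 100) rlang::abort("n_perm must be >= 100")
  X <- if (inherits(expr, "pheno_matrix")) expr$values else expr
  pathway_genes <- intersect(pathway_genes, colnames(X))
  if (length(pathway_genes) < 3) {
    rlang::abort("pathway needs >= 3 usable genes")
  }
  if (!is.null(seed)) set.seed(seed)
  used <- pathway_genes
  if (gene_filter) {
    gf <- gene_connectivity_change(X, strata, pathway_genes,
                                   n_perm = gene_filter_perm,
                                   method = method, compare = compare)
    used <- gf$gene[gf$p < gene_filter_alpha]
    if (length(used) < 3) {
      return(tibble::tibble(n_genes_used = length(used),
                            genes_used = list(used),
                            mdc = NA_real_, p = NA_real_))
    }
  }
  Xu <- X[, used, drop = FALSE]
  idx1 <- strata[[compare[1]]]
  idx2 <- strata[[compare[2]]]
  obs <- mdc_stat(Xu, idx1, idx2, method)
  pool <- c(idx1, idx2)
  n1 <- length(idx1)
  null_mdc <- vapply(seq_len(n_perm), function(i) {
    sh <- sample(pool)
    mdc_stat(Xu, sh[seq_len(n1)], sh[-seq_len(n1)], method)
  }, numeric(1))
  if (two_sided) {
    centre <- stats::median(null_mdc)
    k <- sum(abs(null_mdc - centre) >= abs(obs - centre))
  } else {
    k <- sum(null_mdc >= obs)
  }
  tibble::tibble(n_genes_used = length(used), genes_used = list(used),
                 mdc = obs, p = (1 + k) / (n_perm + 1))
}

#' Pathway differential co-expression over a gene-set collection
#'
#' Runs [mdc_test()] for every gene set with at least `min_set_size`
#' members present in the expression matrix, and BH-adjusts across
#' pathways.
#'
#' @inheritParams mdc_test
#' @param gene_sets Named list of gene vectors.
#' @param min_set_size Minimum members present in the matrix.
#' @return Tibble of pathway scores with `pathway` and `fdr`.
#' @export
pdc_test <- function(expr, strata, gene_sets, n_perm = 1000,
                     method = "spearman", compare = c("MM", "RR"),
                     gene_filter = TRUE, gene_filter_alpha = 0.05,
                     min_set_size = 3, seed = NULL, ...) {
  X <- if (inherits(expr, "pheno_matrix")) expr$values else expr
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::imap_dfr(gene_sets, function(members, nm) {
    present <- intersect(members, colnames(X))
    if (length(present) < min_set_size) return(NULL)
    res <- mdc_test(X, strata, present, n_perm = n_perm, method = method,
                    compare = compare, gene_filter = gene_filter,
                    gene_filter_alpha = gene_filter_alpha, ...)
    dplyr::mutate(res, pathway = nm, .before = 1)
  })
  if (nrow(rows) == 0) rlang::abort("no gene set meets min_set_size")
  rows$fdr <- NA_real_
  ok <- !is.na(rows$p)
  rows$fdr[ok] <- fdr_bh(rows$p[ok])
  rows
}
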