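#' Nominal cis association scan
#'
#' Tests every variant within `window_bp` of each phenotype's position
#' (strand-aware TSS for expression, CpG coordinate for methylation;
#' closed interval, so a variant exactly at the window edge is included)
#' by least squares of phenotype on genotype dosage plus covariates.
#' Returns one row per tested pair with the slope per minor allele, its
#' standard error, the two-sided nominal p, and the signed distance to
#' the TSS (positive = downstream of the TSS in the direction of
#' transcription).
#'
#' Variants with zero dosage variance in the tested subset are skipped
#' with a log message.
#'
#' @param pheno Normalised [pheno_matrix()].
#' @param geno [geno_matrix()] sharing individuals with `pheno`.
#' @param window_bp Cis window half-width in bp (genes/CpGs 1e6,
#'   transcripts 1e5 by convention).
#' @param covariates Optional numeric matrix of covariates (e.g.
#'   expression PCs), individuals in rows.
#' @param maf_min MAF floor; variants below it are not tested.
#' @param condition Optional condition label copied into the output.
#' @param verbose Emit log messages for skipped variants.
#' @return Tibble of QTL records: `phenotype_id`, `group_id`,
#'   `variant_id`, `condition`, `b`, `se`, `p_nominal`,
#'   `distance_to_tss`, `n`.
#' @export
map_cis_nominal <- function(pheno, geno, window_bp = 1e6,
                            covariates = NULL, maf_min = 0,
                            condition = NA_character_, verbose = FALSE) {
  if (window_bp <= 0) rlang::abort("window_bp must be > 0")
  dosage <- align_individuals(pheno$values, geno$dosage,
                              "phenotypes", "genotypes")
  n <- nrow(dosage)
  k <- n_covariates(covariates)
  df <- n - 2L - k
  Yr <- residualize(pheno$values, covariates)
  Gr <- residualize(dosage, covariates)
  vm <- geno$map
  testable <- vm$maf >= maf_min
  out <- vector("list", ncol(Yr))
  for (j in seq_len(ncol(Yr))) {
    tss <- pheno$map$pos[j]
    chrom <- pheno$map$chrom[j]
    idx <- which(testable & vm$chrom == chrom &
                   abs(vm$pos - tss) <= window_bp)
    if (length(idx) == 0) next
    fit <- assoc_from_residuals(Yr[, j], Gr[, idx, drop = FALSE], df)
    if (verbose && any(!fit$ok)) {
      message("skipping ", sum(!fit$ok),
              " zero-variance variant(s) for ", pheno$map$phenotype_id[j])
    }
    keep <- fit$ok
    strand_sign <- if (identical(pheno$map$strand[j], "-")) -1 else 1
    out[[j]] <- tibble::tibble(
      phenotype_id = pheno$map$phenotype_id[j],
      group_id = pheno$map$group_id[j],
      variant_id = vm$variant_id[idx][keep],
      condition = condition,
      b = fit$b[keep], se = fit$se[keep], p_nominal = fit$p[keep],
      distance_to_tss = strand_sign * (vm$pos[idx][keep] - tss),
      n = n)
  }
  dplyr::bind_rows(out)
}

#' Permutation pass for phenotype-level empirical p-values
#'
#' For each phenotype (or phenotype group, when `grouping` maps
#' transcripts to genes), individual labels of the phenotype are permuted
#' `n_perm` times and the best cis association per permutation is
#' recorded; the empirical p is `(1 + #{perm best <= observed best}) /
#' (n_perm + 1)`, so it is never exactly zero. With grouping, the best
#' statistic is taken across the group's phenotypes within each
#' permutation (group-best correction for multiple transcripts per
#' gene). A beta distribution fitted to the permutation null refines
#' small p-values (`p_beta`); the direct empirical p is always reported
#' alongside.
#'
#' @inheritParams map_cis_nominal
#' @param n_perm Number of permutations (>= 100).
#' @param grouping `"group"` to take the best statistic across each
#'   `group_id`, `"phenotype"` for per-phenotype permutation p.
#' @param beta_fit Also fit a beta null and report `p_beta`.
#' @param seed Optional seed for the permutations.
#' @param exhaustive Enumerate all `n!` permutations instead of sampling
#'   (only for tiny cohorts, `n! <= 40320`); the empirical p is then the
#'   exact fraction of permutations at least as extreme (identity
#'   included), with no `+1` correction.
#' @return Tibble: one row per group with the best phenotype/variant,
#'   `p_nominal_best`, `p_empirical`, `p_beta`.
#' @export
permutation_pass <- function(pheno, geno, window_bp = 1e6,
                             covariates = NULL, n_perm = 1000,
                             grouping = c("phenotype", "group"),
                             maf_min = 0, beta_fit = TRUE, seed = NULL,
                             exhaustive = FALSE) {
  grouping <- match.arg(grouping)
  if (!exhaustive && n_perm < 100) {
    rlang::abort("n_perm must be >= 100 (unstable tail)")
  }
  if (!is.null(seed)) set.seed(seed)
  dosage <- align_individuals(pheno$values, geno$dosage,
                              "phenotypes", "genotypes")
  n <- nrow(dosage)
  k <- n_covariates(covariates)
  df <- n - 2L - k
  Yr <- residualize(pheno$values, covariates)
  Gr <- residualize(dosage, covariates)
  # unit-normalise genotype residual columns once: |r| = |t(Gr) yr| / |yr|
  ss_g <- colSums(Gr^2)
  vm <- geno$map
  testable <- ss_g > 1e-12 & vm$maf >= maf_min
  Gn <- sweep(Gr, 2, sqrt(pmax(ss_g, 1e-300)), "/")
  cis_idx <- lapply(seq_len(ncol(Yr)), function(j) {
    which(testable & vm$chrom == pheno$map$chrom[j] &
            abs(vm$pos - pheno$map$pos[j]) <= window_bp)
  })
  groups <- if (grouping == "group") pheno$map$group_id else
    pheno$map$phenotype_id
  if (exhaustive) {
    if (factorial(n) > 40320) {
      rlang::abort("exhaustive enumeration only for n! <= 40320")
    }
    perm_mat <- all_permutations(n)
    n_perm <- ncol(perm_mat)
  } else {
    perm_mat <- replicate(n_perm, sample.int(n))
  }
  out <- list()
  for (grp in unique(groups)) {
    js <- which(groups == grp & lengths(cis_idx) > 0)
    if (length(js) == 0) next
    # observed best |r| across the group's phenotypes
    best_r <- -Inf; best_j <- NA_integer_; best_v <- NA_integer_
    for (j in js) {
      yr <- Yr[, j] / sqrt(sum(Yr[, j]^2))
      rj <- abs(drop(crossprod(Gn[, cis_idx[[j]], drop = FALSE], yr)))
      if (max(rj) > best_r) {
        best_r <- max(rj); best_j <- j
        best_v <- cis_idx[[j]][which.max(rj)]
      }
    }
    perm_best <- vapply(seq_len(n_perm), function(i) {
      pi <- perm_mat[, i]
      max(vapply(js, function(j) {
        yp <- Yr[pi, j]
        yp <- yp / sqrt(sum(yp^2))
        max(abs(drop(crossprod(Gn[, cis_idx[[j]], drop = FALSE], yp))))
      }, numeric(1)))
    }, numeric(1))
    p_emp <- if (exhaustive) {
      mean(perm_best >= best_r - 1e-12)
    } else {
      (1 + sum(perm_best >= best_r)) / (n_perm + 1)
    }
    r2p <- function(r) {
      r <- pmin(r, 1 - 1e-15)
      2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
    }
    p_obs <- r2p(best_r)
    p_beta <- NA_real_
    if (beta_fit) {
      pp <- pmin(pmax(r2p(perm_best), 1e-300), 1 - 1e-12)
      fit <- try(stats::optim(c(0, 0), function(par) {
        -sum(stats::dbeta(pp, exp(par[1]), exp(par[2]), log = TRUE))
      }), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        p_beta <- stats::pbeta(p_obs, exp(fit$par[1]), exp(fit$par[2]))
      }
    }
    out[[grp]] <- tibble::tibble(
      group_id = grp,
      phenotype_id = pheno$map$phenotype_id[best_j],
      variant_id = vm$variant_id[best_v],
      p_nominal_best = p_obs, p_empirical = p_emp, p_beta = p_beta)
  }
  dplyr::bind_rows(out)
}

#' Forward-backward conditional pass for independent signals
#'
#' Per phenotype: the forward step adds the best remaining cis variant
#' while its p conditional on the already-selected variants (and
#' covariates) stays below `p_threshold`; the backward step re-tests each
#' selected variant conditional on the others and drops failures. Each
#' retained signal is then assigned its best hit by rescanning the window
#' conditional on the other signals. Signals are ranked by conditional
#' significance (`signal_rank` 1 = primary). Collinear selections are
#' dropped with a log message. Phenotypes with no significant primary
#' return no rows (not an error).
#'
#' @inheritParams map_cis_nominal
#' @param p_threshold Conditional significance threshold.
#' @param max_signals Safety cap on signals per phenotype.
#' @return Tibble of independent QTL records with `signal_rank`.
#' @export
conditional_pass <- function(pheno, geno, window_bp = 1e6,
                             covariates = NULL, p_threshold = 1e-4,
                             maf_min = 0, max_signals = 10,
                             verbose = FALSE) {
  dosage <- align_individuals(pheno$values, geno$dosage,
                              "phenotypes", "genotypes")
  n <- nrow(dosage)
  k <- n_covariates(covariates)
  vm <- geno$map
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  scan_conditional <- function(y, idx, sel) {
    # p of each candidate conditional on selected variants + covariates
    Xc <- cbind(covm, dosage[, sel, drop = FALSE])
    df <- n - 2L - n_covariates(Xc)
    yr <- residualize(cbind(y), Xc)[, 1]
    Gr <- residualize(dosage[, idx, drop = FALSE], Xc)
    assoc_from_residuals(yr, Gr, df)
  }
  out <- list()
  for (j in seq_len(ncol(pheno$values))) {
    tss <- pheno$map$pos[j]
    idx <- which(vm$maf >= maf_min & vm$chrom == pheno$map$chrom[j] &
                   abs(vm$pos - tss) <= window_bp)
    if (length(idx) == 0) next
    y <- pheno$values[, j]
    sel <- integer(0)
    # forward
    repeat {
      fit <- scan_conditional(y, idx, sel)
      if (all(!fit$ok)) break
      best <- which.min(fit$p)
      if (is.na(fit$p[best]) || fit$p[best] >= p_threshold) break
      cand <- idx[best]
      if (cand %in% sel) break
      sel <- c(sel, cand)
      if (length(sel) >= max_signals) break
    }
    if (length(sel) == 0) next
    # backward: re-test each selected conditional on the others
    repeat {
      drop_one <- NA_integer_
      for (s in seq_along(sel)) {
        fit <- scan_conditional(y, sel[s], sel[-s])
        if (!fit$ok[1] || is.na(fit$p[1]) || fit$p[1] >= p_threshold) {
          drop_one <- s
          if (verbose && !fit$ok[1]) {
            message("dropping collinear variant ", vm$variant_id[sel[s]])
          }
          break
        }
      }
      if (is.na(drop_one)) break
      sel <- sel[-drop_one]
      if (length(sel) == 0) break
    }
    if (length(sel) == 0) next
    # best hit per signal, conditional on the other signals
    recs <- lapply(seq_along(sel), function(s) {
      fit <- scan_conditional(y, idx, sel[-s])
      best <- which.min(fit$p)
      tibble::tibble(
        phenotype_id = pheno$map$phenotype_id[j],
        group_id = pheno$map$group_id[j],
        variant_id = vm$variant_id[idx[best]],
        b = fit$b[best], se = fit$se[best], p_nominal = fit$p[best],
        distance_to_tss = vm$pos[idx[best]] - tss, n = n)
    })
    recs <- dplyr::distinct(dplyr::bind_rows(recs), .data$variant_id,
                            .keep_all = TRUE)
    recs <- dplyr::arrange(recs, .data$p_nominal)
    recs$signal_rank <- seq_len(nrow(recs))
    out[[length(out) + 1]] <- recs
  }
  dplyr::bind_rows(out)
}

#' Greedy LD clumping of association records
#'
#' Sorts records by p ascending (ties break to the smaller genomic
#' position) and accepts a variant as a lead SNP when its r-squared to
#' every previously accepted variant, computed from genotype dosage
#' correlation on the provided panel, is below `r2_threshold`.
#'
#' @param records Tibble with `variant_id` and `p_nominal` (positions
#'   taken from the genotype map).
#' @param geno [geno_matrix()] providing the LD panel.
#' @param r2_threshold Maximum r-squared between accepted leads.
#' @return The lead-SNP subset of `records`, with a `lead` column.
#' @export
ld_clump <- function(records, geno, r2_threshold = 1e-3) {
  if (nrow(records) == 0) return(records)
  pos <- geno$map$pos[match(records$variant_id, geno$map$variant_id)]
  ord <- order(records$p_nominal, pos)
  recs <- records[ord, , drop = FALSE]
  ids <- unique(recs$variant_id)
  G <- geno$dosage[, ids, drop = FALSE]
  accepted <- character(0)
  lead_rows <- logical(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    v <- recs$variant_id[i]
    if (v %in% accepted) next
    if (length(accepted) == 0) {
      accepted <- v; lead_rows[i] <- TRUE; next
    }
    r2 <- stats::cor(G[, v], G[, accepted, drop = FALSE])^2
    if (all(r2 < r2_threshold, na.rm = TRUE)) {
      accepted <- c(accepted, v); lead_rows[i] <- TRUE
    }
  }
  recs[lead_rows, , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` kept as the single
#' FDR entry point for the pipeline.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (monotone, <= 1).
#' @export
fdr_bh <- function(p) {
  if (length(p) == 0) rlang::abort("empty p-value list")
  if (any(p < 0 | p > 1, na.rm = TRUE)) rlang::abort("p outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Estimate pi1, the proportion of true positives
#'
#' Storey-style estimate: `pi0(lambda) = mean(p > lambda) / (1 - lambda)`
#' over a lambda grid, smoothed with a cubic spline and evaluated at the
#' largest lambda; `pi1 = 1 - pi0`, clamped to `[0, 1]`.
#'
#' @param p Numeric p-values.
#' @param lambda Grid of lambda values in (0, 1).
#' @return Estimated pi1.
#' @export
estimate_pi1 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) == 0) rlang::abort("empty p-value list")
  if (any(p < 0 | p > 1)) rlang::abort("p outside [0, 1]")
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (length(lambda) >= 4) {
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  } else pi0_l[length(lambda)]
  1 - min(max(pi0, 0), 1)
}

#' Analytic power for cis-QTL detection by simple linear regression
#'
#' Power of the two-sided t-test for the genotype slope in a simple
#' linear regression, with genotype variance `2 * maf * (1 - maf)` under
#' HWE. `sigma_y` is the marginal SD of the outcome; when unset it
#' defaults to `slope / sqrt(2 * maf * (1 - maf))`. The residual SD is
#' derived as `sqrt(sigma_y^2 - slope^2 * 2 * maf * (1 - maf))`, which
#' must be positive.
#'
#' @param n Sample size.
#' @param slope Detectable slope per minor allele.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param sigma_y Marginal SD of the outcome (default per above).
#' @param alpha Family-wise significance level.
#' @return Power in `[0, 1]`.
#' @export
eqtl_power_slr <- function(n, slope, maf, sigma_y = NULL, alpha = 0.01) {
  if (maf <= 0 || maf > 0.5) rlang::abort("maf must be in (0, 0.5]")
  if (n < 4) rlang::abort("n too small")
  var_g <- 2 * maf * (1 - maf)
  if (is.null(sigma_y)) {
    if (slope == 0) rlang::abort("sigma_y must be given when slope = 0")
    sigma_y <- abs(slope) / sqrt(var_g)
  }
  var_e <- sigma_y^2 - slope^2 * var_g
  if (var_e <= 0) {
    rlang::abort("non-positive residual variance: sigma_y^2 <= slope^2 * 2*maf*(1-maf)")
  }
  df <- n - 2
  ncp <- slope * sqrt(n * var_g) / sqrt(var_e)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}
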