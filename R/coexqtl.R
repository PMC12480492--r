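# Allele-specific co-expression QTL machinery: genotype-stratified
# correlation, Fisher z, the dz statistic, differential-correlation
# classes and the interaction test.

#' Partition individuals by genotype at a variant
#'
#' Genotype strata are RR (homozygous reference/major), RM
#' (heterozygous) and MM (homozygous minor). A stratification is
#' eligible for differential-correlation analysis only when the
#' homozygous-minor count strictly exceeds `min_hom_minor`.
#'
#' @param geno [geno_matrix()].
#' @param variant_id Variant to stratify on.
#' @param min_hom_minor Required MM count (strict `>`).
#' @return Object of class `genotype_strata`: index lists `RR`, `RM`,
#'   `MM`, per-group `n`, and `eligible`.
#' @export
stratify <- function(geno, variant_id, min_hom_minor = 5) {
  if (!variant_id %in% geno$map$variant_id) {
    rlang::abort(paste0("unknown variant: ", variant_id))
  }
  g <- round(geno$dosage[, variant_id])
  idx <- list(RR = which(g == 0), RM = which(g == 1), MM = which(g == 2))
  structure(list(variant_id = variant_id, RR = idx$RR, RM = idx$RM,
                 MM = idx$MM, n = lengths(idx),
                 eligible = length(idx$MM) > min_hom_minor),
            class = "genotype_strata")
}

#' @export
print.genotype_strata <- function(x, ...) {
  cat(sprintf("<genotype_strata> %s: RR=%d RM=%d MM=%d (%seligible)\n",
              x$variant_id, x$n[["RR"]], x$n[["RM"]], x$n[["MM"]],
              if (x$eligible) "" else "not "))
  invisible(x)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = 0.5 * ln((1 + r) / (1 - r))`, the variance-stabilising transform
#' for (rank) correlation coefficients.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) rlang::abort("|r| must be < 1")
  0.5 * log((1 + r) / (1 - r))
}

#' Inverse Fisher z-transform
#' @param z Numeric.
#' @return Correlation in (-1, 1).
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Standardised difference of correlations between two strata
#'
#' `dz = (z1 - z2) / denom` with `z = fisher_z(r)` and
#' `var(z_i) = 1/(n_i - 3)`. In `"standard"` mode the denominator is
#' `sqrt(var(z1) + var(z2))`, the usual two-sample correlation z-test;
#' the `"literal"` mode uses `sqrt(|var(z1) - var(z2)|)` exactly as
#' sometimes typeset, which is singular for equal group sizes and then
#' errors explicitly. Two-sided p from the standard normal.
#'
#' @param r1,r2 Stratum correlations, `|r| < 1`.
#' @param n1,n2 Stratum sizes (> 3).
#' @param mode `"standard"` or `"literal"`.
#' @return Tibble: `dz`, `p`.
#' @export
dz_statistic <- function(r1, n1, r2, n2,
                         mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (any(c(n1, n2) <= 3)) rlang::abort("each n must be > 3")
  v1 <- 1 / (n1 - 3)
  v2 <- 1 / (n2 - 3)
  denom <- if (mode == "standard") sqrt(v1 + v2) else {
    if (any(n1 == n2)) {
      rlang::abort(paste0("literal denominator sqrt(|var(z1)-var(z2)|)",
                          " is zero for equal group sizes"))
    }
    sqrt(abs(v1 - v2))
  }
  dz <- (fisher_z(r1) - fisher_z(r2)) / denom
  tibble::tibble(dz = dz, p = 2 * stats::pnorm(-abs(dz)))
}

#' Label a stratum correlation
#'
#' `"pos"` if significantly positive (p < alpha, r > 0), `"neg"` if
#' significantly negative, `"ns"` otherwise.
#' @param r Correlation.
#' @param p Two-sided p of the correlation.
#' @param alpha Significance threshold.
#' @return Character label(s).
#' @export
correlation_label <- function(r, p, alpha = 0.05) {
  dplyr::case_when(p < alpha & r > 0 ~ "pos",
                   p < alpha & r < 0 ~ "neg",
                   TRUE ~ "ns")
}

#' Differential-correlation class of a stratum pair
#'
#' Each stratum's correlation is labelled significant-positive,
#' non-significant, or significant-negative; the ordered label pair
#' across the two compared genotype classes gives one of the 3 x 3 = 9
#' classes, written e.g. `"pos/neg"` (a sign-flip candidate).
#'
#' @param r1,p1 Correlation and p in the first stratum.
#' @param r2,p2 Correlation and p in the second stratum.
#' @param alpha Per-stratum significance threshold.
#' @return Character class label(s), `"<label1>/<label2>"`.
#' @export
classify_dc <- function(r1, p1, r2, p2, alpha = 0.05) {
  paste(correlation_label(r1, p1, alpha),
        correlation_label(r2, p2, alpha), sep = "/")
}

#' Consistency of the three pairwise differential-correlation calls
#'
#' With propositions p = (MM vs RR differentially correlated), q = (MM vs
#' RM differentially correlated) and d = (RM vs RR differentially
#' correlated), the rule `p & q -> d` and `!p & q -> !d` is checked: when
#' q holds, d is expected to equal p. Returns `TRUE` when consistent (or
#' when q does not hold, where the rule is silent).
#'
#' @param dc_mm_rr,dc_mm_rm,dc_rm_rr Logicals: is the pair differentially
#'   correlated (e.g. dz p below threshold)?
#' @return Logical consistency flag(s).
#' @export
dc_consistent <- function(dc_mm_rr, dc_mm_rm, dc_rm_rr) {
  ifelse(dc_mm_rm, dc_rm_rr == dc_mm_rr, TRUE)
}

# Stratified correlations of one anchor vector against partner columns.
stratified_cor <- function(anchor, partners, strata,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  out <- lapply(c("RR", "RM", "MM"), function(grp) {
    idx <- strata[[grp]]
    r <- suppressWarnings(
      stats::cor(anchor[idx], partners[idx, , drop = FALSE],
                 method = method))
    drop(r)
  })
  names(out) <- c("RR", "RM", "MM")
  out
}

# p of a correlation via the t approximation (Spearman: same approximation
# on the rank correlation).
cor_p <- function(r, n) {
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  2 * stats::pt(-abs(tstat), n - 2)
}

#' Detect allele-specific co-expression QTL for an anchor gene
#'
#' For every candidate partner phenotype, computes genotype-stratified
#' correlations with the anchor (Spearman by default), Fisher-z dz
#' statistics for MM vs RR and MM vs RM, and the interaction p-value.
#' The primary `p_interaction` comes from the linear model
#' `partner ~ anchor + genotype + anchor:genotype` (two-sided test of the
#' interaction slope, genotype coded additively); the dz-based normal p
#' is reported alongside. BH adjustment is applied across partners
#' within the anchor. Partners with zero variance in any stratum are
#' skipped with a log message; the anchor itself is excluded.
#'
#' @param anchor_id Anchor phenotype (typically a cis-regulated eGene).
#' @param variant_id The anchor's QTL variant.
#' @param expr [pheno_matrix()] of candidate partners (may include the
#'   anchor).
#' @param geno [geno_matrix()].
#' @param anchor_expr Optional numeric vector overriding the anchor
#'   values (used when the anchor lives in a different matrix).
#' @param min_hom_minor Eligibility threshold for [stratify()].
#' @param alpha Retention threshold on the BH-adjusted interaction p.
#' @param method Correlation estimator.
#' @param dz_mode Passed to [dz_statistic()].
#' @param dc_alpha Per-stratum significance for the class labels.
#' @param verbose Log skipped partners.
#' @return Tibble of differential-correlation records: stratified r and
#'   n, `z_rr`/`z_rm`/`z_mm`, `dz_mm_rr`, `dz_mm_rm`, `p_dz`,
#'   `p_interaction`, `fdr_interaction`, `dc_class`, `pass`.
#' @export
detect_coexqtl <- function(anchor_id, variant_id, expr, geno,
                           anchor_expr = NULL, min_hom_minor = 5,
                           alpha = 1e-6, method = "spearman",
                           dz_mode = "standard", dc_alpha = 0.05,
                           verbose = FALSE) {
  strata <- stratify(geno, variant_id, min_hom_minor)
  if (!strata$eligible) {
    rlang::abort(paste0("variant ", variant_id,
                        " ineligible: homozygous-minor count <= ",
                        min_hom_minor))
  }
  vals <- align_individuals(geno$dosage, expr$values, "genotypes",
                            "phenotypes")
  anchor <- if (!is.null(anchor_expr)) anchor_expr else vals[, anchor_id]
  partner_ids <- setdiff(colnames(vals), anchor_id)
  # drop partners constant in any stratum
  usable <- vapply(partner_ids, function(pid) {
    all(vapply(c("RR", "RM", "MM"), function(grp) {
      idx <- strata[[grp]]
      length(idx) < 2 || stats::sd(vals[idx, pid]) > 0
    }, logical(1)))
  }, logical(1))
  if (verbose && any(!usable)) {
    message("skipping ", sum(!usable), " zero-variance partner(s)")
  }
  partner_ids <- partner_ids[usable]
  if (length(partner_ids) == 0) return(tibble::tibble())
  P <- vals[, partner_ids, drop = FALSE]
  rs <- stratified_cor(anchor, P, strata, method = method)
  n <- strata$n
  dz1 <- dz_statistic(rs$MM, n[["MM"]], rs$RR, n[["RR"]], mode = dz_mode)
  dz2 <- dz_statistic(rs$MM, n[["MM"]], rs$RM, n[["RM"]], mode = dz_mode)
  g <- round(geno$dosage[, variant_id])
  p_int <- vapply(partner_ids, function(pid) {
    fit <- stats::lm(P[, pid] ~ anchor * g)
    cf <- summary(fit)$coefficients
    if ("anchor:g" %in% rownames(cf)) cf["anchor:g", 4] else NA_real_
  }, numeric(1))
  out <- tibble::tibble(
    anchor = anchor_id, partner = partner_ids, variant_id = variant_id,
    r_rr = rs$RR, r_rm = rs$RM, r_mm = rs$MM,
    n_rr = n[["RR"]], n_rm = n[["RM"]], n_mm = n[["MM"]],
    z_rr = fisher_z(rs$RR), z_rm = fisher_z(rs$RM), z_mm = fisher_z(rs$MM),
    dz_mm_rr = dz1$dz, dz_mm_rm = dz2$dz, p_dz = dz1$p,
    p_interaction = p_int,
    dc_class = classify_dc(rs$RR, cor_p(rs$RR, n[["RR"]]),
                           rs$MM, cor_p(rs$MM, n[["MM"]]),
                           alpha = dc_alpha))
  out$fdr_interaction <- fdr_bh(out$p_interaction)
  out$pass <- out$fdr_interaction < alpha
  out
}

#' Flag replicated coExQTL between two datasets
#'
#' A discovery record is replicated when the replication set contains the
#' identical (anchor, partner, variant) triple with the same direction of
#' correlation change (sign of the MM-vs-RR dz).
#'
#' @param discovery,replication Tibbles from [detect_coexqtl()].
#' @return `discovery` with a `replicated` flag.
#' @export
replicate_coexqtl <- function(discovery, replication) {
  key <- function(d) paste(d$anchor, d$partner, d$variant_id)
  rep_dir <- stats::setNames(sign(replication$dz_mm_rr), key(replication))
  k <- key(discovery)
  discovery$replicated <- !is.na(rep_dir[k]) &
    sign(discovery$dz_mm_rr) == unname(rep_dir[k])
  discovery
}

#' Allele-specific methylation links for coExQTL variants
#'
#' Tests genotype x methylation interaction on network-gene expression:
#' for each coExQTL variant, CpG vectors play the role of the anchor and
#' the network genes are the partners, using exactly the
#' [detect_coexqtl()] machinery.
#'
#' @param coex Tibble of coExQTL records (uses `variant_id`, `partner`).
#' @param meth [pheno_matrix()] of CpG betas.
#' @param expr [pheno_matrix()] with the network genes.
#' @param geno [geno_matrix()].
#' @param cpg_ids CpGs to test (default all columns of `meth`).
#' @param alpha Retention threshold on the BH-adjusted interaction p.
#' @param ... Passed to [detect_coexqtl()].
#' @return Tibble of CpG-gene interaction records.
#' @export
coex_methylation_links <- function(coex, meth, expr, geno,
                                   cpg_ids = colnames(meth$values),
                                   alpha = 0.01, ...) {
  mv <- align_individuals(geno$dosage, meth$values, "genotypes",
                          "methylation")
  out <- list()
  for (v in unique(coex$variant_id)) {
    partners <- unique(coex$partner[coex$variant_id == v])
    sub <- pheno_matrix(expr$values[, partners, drop = FALSE],
                        expr$map[match(partners, expr$map$phenotype_id), ])
    for (cpg in cpg_ids) {
      if (stats::sd(mv[, cpg]) == 0) {
        message("skipping constant CpG ", cpg)
        next
      }
      rec <- detect_coexqtl(anchor_id = cpg, variant_id = v, expr = sub,
                            geno = geno, anchor_expr = mv[, cpg],
                            alpha = alpha, ...)
      rec$anchor <- cpg
      out[[length(out) + 1]] <- rec
    }
  }
  dplyr::bind_rows(out)
}
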