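#' Classify QTL context specificity across stimulation conditions
#'
#' For each variant-phenotype pair observed in several conditions, labels
#' the effect as one of:
#' \describe{
#'   \item{`differential`}{significant (fdr < `sig_fdr`) in >= 2
#'     conditions with opposite slope signs.}
#'   \item{`shared`}{significant in all conditions (same sign).}
#'   \item{`condition-specific:<c>`}{significant in exactly one condition
#'     and clearly non-significant (nominal p > `nonsig_floor`)
#'     elsewhere.}
#'   \item{`stimulated-only`}{significant in at least one stimulated
#'     condition and not in the naive condition.}
#'   \item{`none` / `ambiguous`}{no significant condition, or a pattern
#'     matching none of the above (e.g. one significant condition with a
#'     near-threshold other condition).}
#' }
#' Pairs not testable in every condition keep their label but carry
#' `complete = FALSE`.
#'
#' @param records Tibble with `phenotype_id`, `variant_id`, `condition`,
#'   `b`, `fdr`, `p_nominal` (one row per condition per pair).
#' @param sig_fdr FDR significance threshold.
#' @param nonsig_floor Nominal p floor for "non-significant elsewhere".
#' @param conditions All condition labels; first is the naive condition.
#' @return Tibble of context calls: one row per pair with `label`,
#'   per-condition significance count, and `complete`.
#' @export
classify_context <- function(records, sig_fdr = 0.01, nonsig_floor = 0.05,
                             conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(records$condition)
  naive <- conditions[1]
  dup <- dplyr::count(records, .data$phenotype_id, .data$variant_id,
                      .data$condition)
  if (any(dup$n > 1)) {
    rlang::abort("conflicting records: multiple rows for one pair/condition")
  }
  one_call <- function(d) {
    sig <- d$fdr < sig_fdr
    n_sig <- sum(sig)
    complete <- all(conditions %in% d$condition)
    label <- if (n_sig == 0) {
      "none"
    } else if (n_sig >= 2 && length(unique(sign(d$b[sig]))) > 1) {
      "differential"
    } else if (complete && n_sig == length(conditions)) {
      "shared"
    } else if (n_sig == 1 && all(d$p_nominal[!sig] > nonsig_floor)) {
      paste0("condition-specific:", d$condition[sig])
    } else if (!any(sig & d$condition == naive) &&
               any(sig & d$condition != naive)) {
      "stimulated-only"
    } else {
      "ambiguous"
    }
    tibble::tibble(label = label, n_significant = n_sig,
                   complete = complete)
  }
  out <- dplyr::group_by(records, .data$phenotype_id, .data$variant_id)
  out <- dplyr::group_modify(out, function(d, key) one_call(d))
  dplyr::ungroup(out)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

log_diff_exp <- function(a, b) {
  # log(exp(a) - exp(b)), a >= b
  if (b > a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Colocalization of two association signals by approximate Bayes factors
#'
#' Computes per-variant Wakefield approximate Bayes factors from (beta,
#' se) for each trait under a single-causal-variant assumption, then the
#' posterior probability of the five hypotheses: H0 no association, H1
#' trait 1 only, H2 trait 2 only, H3 two distinct causal variants, H4
#' one shared causal variant. Priors: `p1`/`p2` per-variant probability
#' of association with each trait, `p12` with both.
#'
#' The two summary sets are harmonised by variant id (and, when allele
#' columns are present, alleles are aligned on alt and strand-ambiguous
#' A/T and C/G variants are dropped with a log message).
#'
#' @param stats1,stats2 Tibbles with `variant_id`, `beta`, `se` (optional
#'   `ref`, `alt`).
#' @param p1,p2,p12 Prior probabilities.
#' @param W Prior variance of the effect size (conventional quantitative
#'   -trait default 0.15^2).
#' @param verbose Log dropped variants.
#' @return Object of class `coloc_abf`: posteriors `PPH0`..`PPH4`,
#'   priors, per-variant results with the shared-variant posterior, and
#'   the top shared-variant id. Use [tidy()] / [glance()].
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W = 0.15^2, verbose = FALSE) {
  shared <- dplyr::inner_join(
    dplyr::select(stats1, "variant_id", beta1 = "beta", se1 = "se",
                  dplyr::any_of(c(ref1 = "ref", alt1 = "alt"))),
    dplyr::select(stats2, "variant_id", beta2 = "beta", se2 = "se",
                  dplyr::any_of(c(ref2 = "ref", alt2 = "alt"))),
    by = "variant_id")
  if (all(c("ref1", "alt1", "ref2", "alt2") %in% names(shared))) {
    pal <- function(r, a) (r == "A" & a == "T") | (r == "T" & a == "A") |
      (r == "C" & a == "G") | (r == "G" & a == "C")
    ambiguous <- pal(shared$ref1, shared$alt1)
    flipped <- !ambiguous & shared$alt1 == shared$ref2 &
      shared$ref1 == shared$alt2
    mismatch <- !ambiguous & !flipped &
      (shared$alt1 != shared$alt2 | shared$ref1 != shared$ref2)
    shared$beta2[flipped] <- -shared$beta2[flipped]
    if (verbose && any(ambiguous | mismatch)) {
      message("dropping ", sum(ambiguous | mismatch),
              " strand-ambiguous or allele-mismatched variant(s)")
    }
    shared <- shared[!(ambiguous | mismatch), , drop = FALSE]
  }
  if (nrow(shared) < 10) {
    rlang::abort("fewer than 10 shared variants after harmonisation")
  }
  labf <- function(beta, se) {
    v <- se^2
    r <- W / (W + v)
    0.5 * (log(1 - r) + r * (beta / se)^2)
  }
  l1 <- labf(shared$beta1, shared$se1)
  l2 <- labf(shared$beta2, shared$se2)
  s1 <- log_sum_exp(l1)
  s2 <- log_sum_exp(l2)
  s12 <- log_sum_exp(l1 + l2)
  lh <- c(
    H0 = 0,
    H1 = log(p1) + s1,
    H2 = log(p2) + s2,
    H3 = log(p1) + log(p2) + log_diff_exp(s1 + s2, s12),
    H4 = log(p12) + s12)
  post <- exp(lh - log_sum_exp(lh))
  snp_pp_h4 <- exp(l1 + l2 - s12)
  res <- tibble::tibble(variant_id = shared$variant_id,
                        labf1 = l1, labf2 = l2, snp_pp_h4 = snp_pp_h4)
  structure(list(
    posteriors = stats::setNames(post, paste0("PP", names(lh))),
    priors = c(p1 = p1, p2 = p2, p12 = p12), W = W,
    n_variants = nrow(shared),
    results = res,
    top_shared_variant = res$variant_id[which.max(res$snp_pp_h4)]),
    class = "coloc_abf")
}

#' @export
print.coloc_abf <- function(x, ...) {
  cat("<coloc_abf> posteriors over", x$n_variants, "shared variants\n")
  print(round(x$posteriors, 4))
  cat("top shared variant:", x$top_shared_variant, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.coloc_abf <- function(x, ...) {
  tibble::tibble(hypothesis = names(x$posteriors),
                 posterior = unname(x$posteriors))
}

#' @export
glance.coloc_abf <- function(x, ...) {
  tibble::as_tibble(as.list(x$posteriors)) |>
    dplyr::mutate(n_variants = x$n_variants,
                  top_shared_variant = x$top_shared_variant)
}

#' Mendelian randomization from harmonised instrument effects
#'
#' Per-instrument Wald ratio `beta_outcome / beta_exposure` with
#' delta-method standard error, combined by one of: `wald` (simple mean
#' of ratios), `ivw` (inverse-variance-weighted mean), or `pwm`
#' (penalised weighted median: weights `1/se^2` penalised by
#' `min(1, 20 * p)` of each instrument's heterogeneity Q contribution,
#' standard error by parametric bootstrap). Instruments with
#' `|beta_exposure|` below `tol` are dropped with a log message.
#'
#' @param exposure,outcome Tibbles with `variant_id`, `beta`, `se`.
#' @param method `"wald"`, `"ivw"` or `"pwm"`.
#' @param tol Minimum `|beta_exposure|`.
#' @param n_boot Bootstrap replicates for the `pwm` standard error.
#' @param seed Optional seed for the bootstrap.
#' @param verbose Log dropped instruments.
#' @return Object of class `mr_result` with per-instrument ratios and
#'   the combined estimate, se and two-sided p. Use [tidy()] /
#'   [glance()].
#' @export
mr_estimate <- function(exposure, outcome, method = c("wald", "ivw", "pwm"),
                        tol = 1e-8, n_boot = 500, seed = NULL,
                        verbose = FALSE) {
  method <- match.arg(method)
  d <- dplyr::inner_join(
    dplyr::select(exposure, "variant_id", bx = "beta", sx = "se"),
    dplyr::select(outcome, "variant_id", by = "beta", sy = "se"),
    by = "variant_id")
  weak <- abs(d$bx) < tol
  if (any(weak)) {
    if (verbose) message("dropping ", sum(weak), " weak instrument(s)")
    d <- d[!weak, , drop = FALSE]
  }
  if (nrow(d) == 0) rlang::abort("no usable instruments")
  ratio <- d$by / d$bx
  se_ratio <- sqrt(d$sy^2 / d$bx^2 + d$by^2 * d$sx^2 / d$bx^4)
  w <- 1 / se_ratio^2
  weighted_median <- function(x, wt) {
    ord <- order(x)
    x <- x[ord]; wt <- wt[ord]
    cw <- cumsum(wt) - 0.5 * wt
    cw <- cw / sum(wt)
    stats::approx(cw, x, xout = 0.5, rule = 2)$y
  }
  if (method == "wald") {
    est <- mean(ratio)
    se <- if (length(ratio) > 1) stats::sd(ratio) / sqrt(length(ratio)) else
      se_ratio[1]
  } else if (method == "ivw") {
    est <- sum(w * ratio) / sum(w)
    se <- sqrt(1 / sum(w))
  } else {
    ivw_est <- sum(w * ratio) / sum(w)
    q_i <- w * (ratio - ivw_est)^2
    pen <- pmin(1, 20 * stats::pchisq(q_i, df = 1, lower.tail = FALSE))
    wpen <- w * pen
    est <- weighted_median(ratio, wpen)
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      rb <- stats::rnorm(length(ratio), ratio, se_ratio)
      ivw_b <- sum(w * rb) / sum(w)
      qb <- w * (rb - ivw_b)^2
      weighted_median(rb, w * pmin(1, 20 * stats::pchisq(qb, 1,
                                                         lower.tail = FALSE)))
    }, numeric(1))
    se <- stats::sd(boot)
  }
  p <- 2 * stats::pnorm(-abs(est / se))
  structure(list(
    method = method,
    instruments = tibble::tibble(variant_id = d$variant_id,
                                 beta_exposure = d$bx, beta_outcome = d$by,
                                 ratio = ratio, se = se_ratio),
    estimate = est, se = se, p = p), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: estimate %.4f (se %.4f, p %.3g) from %d instrument(s)\n",
              x$method, x$estimate, x$se, x$p, nrow(x$instruments)))
  invisible(x)
}

#' @export
tidy.mr_result <- function(x, ...) x$instruments

#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$estimate, se = x$se,
                 p = x$p, n_instruments = nrow(x$instruments))
}

#' Steiger directionality between two molecular traits
#'
#' Compares how much variance a variant explains in each of two traits
#' (here methylation and expression) via the Fisher-z difference of the
#' absolute SNP-trait correlations. Direction is `M->E` when the SNP
#' explains methylation significantly better, `E->M` for the reverse,
#' and `undetermined` when the difference is not significant at
#' `threshold`.
#'
#' @param r_snp_meth,r_snp_expr SNP-trait correlations in (-1, 1).
#' @param n_meth,n_expr Sample sizes (> 3).
#' @param threshold Significance threshold for a directed call.
#' @return Tibble: `r_snp_meth`, `r_snp_expr`, `direction`, `steiger_p`.
#' @export
steiger_direction <- function(r_snp_meth, r_snp_expr, n_meth, n_expr,
                              threshold = 0.05) {
  if (any(c(n_meth, n_expr) <= 3)) rlang::abort("n must be > 3")
  if (any(abs(c(r_snp_meth, r_snp_expr)) >= 1)) {
    rlang::abort("correlations must be in (-1, 1)")
  }
  z <- (atanh(abs(r_snp_meth)) - atanh(abs(r_snp_expr))) /
    sqrt(1 / (n_meth - 3) + 1 / (n_expr - 3))
  p <- 2 * stats::pnorm(-abs(z))
  direction <- dplyr::case_when(
    p >= threshold ~ "undetermined",
    z > 0 ~ "M->E",
    TRUE ~ "E->M")
  tibble::tibble(r_snp_meth = r_snp_meth, r_snp_expr = r_snp_expr,
                 n_meth = n_meth, n_expr = n_expr,
                 steiger_z = z, steiger_p = p, direction = direction)
}

#' Methylation-expression correlation with sign classification
#'
#' Pearson correlation with two-sided p for each listed CpG-gene pair,
#' BH adjustment across the tested pairs, and a sign class
#' (`positive` / `negative` / `none`) by significance (fdr < `sig_fdr`)
#' and the sign of r. When a genotype dosage is supplied, the
#' genotype-adjusted partial correlation is reported alongside.
#'
#' @param meth,expr [pheno_matrix()]es sharing individuals.
#' @param pairs Tibble with `cpg_id`, `gene_id`.
#' @param geno Optional [geno_matrix()]; with `pairs$variant_id`, the
#'   partial correlation adjusting for that variant's dosage is added.
#' @param sig_fdr FDR threshold for the sign class.
#' @return Tibble: pair ids, `r`, `p`, `fdr`, `sign_class` (and
#'   `r_partial` when genotype-adjusted).
#' @export
meth_expr_relation <- function(meth, expr, pairs, geno = NULL,
                               sig_fdr = 1e-4) {
  ev <- align_individuals(meth$values, expr$values, "methylation",
                          "expression")
  out <- purrr::pmap_dfr(pairs, function(cpg_id, gene_id, ...) {
    m <- meth$values[, cpg_id]
    e <- ev[, gene_id]
    if (stats::sd(m) == 0 || stats::sd(e) == 0) {
      rlang::abort(paste0("constant vector for pair ", cpg_id, "/", gene_id))
    }
    ct <- stats::cor.test(m, e)
    row <- tibble::tibble(cpg_id = cpg_id, gene_id = gene_id,
                          r = unname(ct$estimate), p = ct$p.value)
    dots <- list(...)
    if (!is.null(geno) && !is.null(dots$variant_id)) {
      g <- align_individuals(meth$values, geno$dosage, "methylation",
                             "genotypes")[, dots$variant_id]
      rm_ <- stats::resid(stats::lm(m ~ g))
      re_ <- stats::resid(stats::lm(e ~ g))
      row$r_partial <- stats::cor(rm_, re_)
      row$variant_id <- dots$variant_id
    }
    row
  })
  out$fdr <- fdr_bh(out$p)
  out$sign_class <- dplyr::case_when(
    out$fdr >= sig_fdr ~ "none",
    out$r > 0 ~ "positive",
    TRUE ~ "negative")
  out
}
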