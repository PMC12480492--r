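make_records <- function(fdr, b = NULL, p = NULL,
                         conds = c("UT", "LPS", "IFN")) {
  k <- length(fdr)
  tibble::tibble(phenotype_id = "g", variant_id = "v",
                 condition = conds[seq_len(k)],
                 b = if (is.null(b)) rep(1, k) else b,
                 fdr = fdr,
                 p_nominal = if (is.null(p)) fdr else p)
}

test_that("context labels cover every definitional configuration", {
  cls <- function(...) classify_context(make_records(...))$label
  # significant only post-LPS, clean elsewhere
  expect_identical(cls(fdr = c(0.5, 0.001, 0.6), p = c(0.5, 1e-5, 0.6),
                       conds = c("UT", "LPS", "IFN")),
                   "condition-specific:LPS")
  # sign-discordant significant effects in two conditions
  expect_identical(cls(fdr = c(0.005, 0.005, 0.9), b = c(0.5, -0.5, 0)),
                   "differential")
  # significant everywhere with one sign
  expect_identical(cls(fdr = c(1e-4, 1e-3, 1e-5), b = c(1, 1, 1)),
                   "shared")
  # all significant but discordant: differential wins over shared
  expect_identical(cls(fdr = c(1e-4, 1e-3, 1e-5), b = c(1, -1, 1)),
                   "differential")
  # two stimulated conditions significant, naive clean
  expect_identical(cls(fdr = c(0.8, 1e-3, 1e-3), b = c(0, 1, 1)),
                   "stimulated-only")
  # single significant condition but a near-threshold neighbour
  expect_identical(cls(fdr = c(0.5, 1e-3, 0.5), p = c(0.03, 1e-6, 0.5)),
                   "stimulated-only")
  expect_identical(cls(fdr = c(1e-3, 0.5, 0.5), p = c(1e-6, 0.03, 0.5)),
                   "ambiguous")
  expect_identical(cls(fdr = c(0.3, 0.4, 0.5)), "none")
})

test_that("context classification flags incomplete and conflicting input", {
  rec <- make_records(fdr = c(1e-4, 0.5), conds = c("UT", "LPS"))
  out <- classify_context(rec, conditions = c("UT", "LPS", "IFN"))
  expect_false(out$complete)
  expect_error(classify_context(rbind(rec, rec[1, ])), "conflicting")
})

abf_stats <- function(z, se = 0.1, ids = NULL) {
  k <- length(z)
  tibble::tibble(
    variant_id = if (is.null(ids)) sprintf("v%03d", seq_len(k)) else ids,
    beta = z * se, se = se)
}

test_that("colocalization posteriors behave across the hypothesis space", {
  set.seed(51)
  z_null <- rnorm(50, 0, 0.5)
  one_hit <- z_null; one_hit[10] <- 9
  other_hit <- z_null; other_hit[40] <- 9
  # identical strong signals: shared causal variant
  res4 <- coloc_abf(abf_stats(one_hit), abf_stats(one_hit))
  expect_gt(res4$posteriors[["PPH4"]], 0.99)
  expect_identical(res4$top_shared_variant, "v010")
  # flat traits: prior-dominated H0
  res0 <- coloc_abf(abf_stats(rnorm(50, 0, 0.3)),
                    abf_stats(rnorm(50, 0, 0.3)))
  expect_identical(names(which.max(res0$posteriors)), "PPH0")
  # strong signals at unlinked variants: two distinct causal variants
  res3 <- coloc_abf(abf_stats(one_hit), abf_stats(other_hit))
  expect_identical(names(which.max(res3$posteriors)), "PPH3")
  # one-sided association
  res1 <- coloc_abf(abf_stats(one_hit), abf_stats(rnorm(50, 0, 0.3)))
  expect_identical(names(which.max(res1$posteriors)), "PPH1")
})

test_that("coloc posteriors sum to one and respect symmetries", {
  set.seed(52)
  z1 <- rnorm(30); z1[5] <- 7
  z2 <- rnorm(30); z2[5] <- 6
  a <- coloc_abf(abf_stats(z1), abf_stats(z2))
  expect_equal(sum(a$posteriors), 1, tolerance = 1e-9)
  b <- coloc_abf(abf_stats(z2), abf_stats(z1))
  expect_equal(a$posteriors[["PPH4"]], b$posteriors[["PPH4"]],
               tolerance = 1e-12)
  expect_equal(a$posteriors[["PPH1"]], b$posteriors[["PPH2"]],
               tolerance = 1e-12)
  # rescaling the effect-size axis (beta, se and the prior SD together)
  # leaves the posteriors unchanged: the ABF depends only on z and W/V
  s1 <- abf_stats(z1); s2 <- abf_stats(z2)
  s1b <- dplyr::mutate(s1, beta = beta * 3, se = se * 3)
  s2b <- dplyr::mutate(s2, beta = beta * 3, se = se * 3)
  expect_equal(coloc_abf(s1b, s2b, W = 9 * 0.15^2)$posteriors,
               a$posteriors, tolerance = 1e-9)
  expect_error(coloc_abf(abf_stats(rnorm(5)), abf_stats(rnorm(5))),
               "10 shared")
  td <- tidy(a)
  expect_identical(td$hypothesis, paste0("PPH", 0:4))
  expect_equal(sum(td$posterior), 1, tolerance = 1e-9)
  expect_identical(glance(a)$n_variants, 30L)
})

test_that("harmonisation flips alleles and drops palindromic variants", {
  set.seed(53)
  z <- rnorm(12); z[3] <- 8
  s1 <- abf_stats(z)
  s1$ref <- "A"; s1$alt <- "G"
  s2 <- s1
  # trait 2 reports the flipped alleles for variant 3: beta must negate
  s2$ref[3] <- "G"; s2$alt[3] <- "A"; s2$beta[3] <- -s2$beta[3]
  res <- coloc_abf(s1, s2)
  expect_gt(res$posteriors[["PPH4"]], 0.9)
  # palindromic variants are removed
  s1p <- s1; s1p$ref[1] <- "A"; s1p$alt[1] <- "T"
  expect_message(res_p <- coloc_abf(s1p, s1p, verbose = TRUE),
                 "ambiguous")
  expect_identical(res_p$n_variants, 11L)
})

test_that("MR ratio estimators recover a planted causal effect", {
  expect_equal(
    mr_estimate(tibble::tibble(variant_id = "v1", beta = 0.5, se = 0.05),
                tibble::tibble(variant_id = "v1", beta = 0.25, se = 0.05),
                method = "wald")$estimate, 0.5)
  set.seed(54)
  k <- 50
  bx <- runif(k, 0.3, 1)
  sx <- rep(0.02, k); sy <- rep(0.02, k)
  exposure <- tibble::tibble(variant_id = sprintf("v%02d", 1:k),
                             beta = bx + rnorm(k, 0, sx), se = sx)
  outcome <- tibble::tibble(variant_id = sprintf("v%02d", 1:k),
                            beta = 0.8 * bx + rnorm(k, 0, sy), se = sy)
  for (m in c("wald", "ivw", "pwm")) {
    fit <- mr_estimate(exposure, outcome, method = m, seed = 1)
    expect_lt(abs(fit$estimate - 0.8), 0.02)
    expect_lt(fit$p, 1e-6)
  }
  pwm <- mr_estimate(exposure, outcome, method = "pwm", seed = 1)
  expect_gte(pwm$estimate, min(pwm$instruments$ratio))
  expect_lte(pwm$estimate, max(pwm$instruments$ratio))
  expect_identical(nrow(tidy(pwm)), 50L)
  expect_identical(glance(pwm)$method, "pwm")
})

test_that("weak instruments are dropped and an empty set errors", {
  exposure <- tibble::tibble(variant_id = c("a", "b"),
                             beta = c(0, 0.5), se = 0.1)
  outcome <- tibble::tibble(variant_id = c("a", "b"),
                            beta = c(0.2, 0.25), se = 0.1)
  expect_message(fit <- mr_estimate(exposure, outcome, method = "wald",
                                    verbose = TRUE), "weak")
  expect_identical(nrow(fit$instruments), 1L)
  exposure0 <- dplyr::mutate(exposure, beta = 0)
  expect_error(mr_estimate(exposure0, outcome), "no usable")
})

test_that("Steiger directionality is signed, symmetric and thresholded", {
  res <- steiger_direction(0.5, 0.1, 200, 200)
  expect_identical(res$direction, "M->E")
  expect_lt(res$steiger_p, 0.05)
  swapped <- steiger_direction(0.1, 0.5, 200, 200)
  expect_identical(swapped$direction, "E->M")
  expect_equal(swapped$steiger_z, -res$steiger_z)
  same <- steiger_direction(0.4, 0.4, 100, 100)
  expect_identical(same$direction, "undetermined")
  expect_equal(same$steiger_p, 1)
  # sign of r is irrelevant: magnitudes are compared
  expect_identical(steiger_direction(-0.5, 0.1, 200, 200)$direction,
                   "M->E")
  expect_error(steiger_direction(0.5, 0.1, 3, 200), "> 3")
  expect_error(steiger_direction(1, 0.1, 100, 100), "-1, 1")
})

test_that("methylation-expression relations classify sign correctly", {
  set.seed(55)
  n <- 80
  meth_v <- cbind(c1 = runif(n), c2 = runif(n), c3 = runif(n))
  expr_v <- cbind(g1 = 2 * meth_v[, 1],             # exact positive
                  g2 = rnorm(n),                    # independent
                  g3 = -1.5 * meth_v[, 3] + rnorm(n, sd = 0.1))
  meth <- make_pheno(meth_v)
  expr <- make_pheno(expr_v)
  pairs <- tibble::tibble(cpg_id = c("c1", "c2", "c3"),
                          gene_id = c("g1", "g2", "g3"))
  out <- meth_expr_relation(meth, expr, pairs)
  expect_equal(out$r[1], 1, tolerance = 1e-12)
  expect_identical(out$sign_class, c("positive", "none", "negative"))
  expect_lt(abs(out$r[2]), 0.3)
  const <- make_pheno(cbind(c1 = rep(0.5, n)))
  expect_error(meth_expr_relation(const, expr,
                                  tibble::tibble(cpg_id = "c1",
                                                 gene_id = "g1")),
               "constant")
})

test_that("genotype-adjusted partial correlation removes the shared driver", {
  set.seed(56)
  n <- 300
  g <- rbinom(n, 2, 0.4)
  m <- 0.9 * g + rnorm(n)
  e <- 0.9 * g + rnorm(n)            # correlated only through genotype
  geno <- make_geno(cbind(v1 = g))
  out <- meth_expr_relation(
    make_pheno(cbind(c1 = m)), make_pheno(cbind(g1 = e)),
    tibble::tibble(cpg_id = "c1", gene_id = "g1", variant_id = "v1"),
    geno = geno)
  # marginal correlation driven by the shared genotype ~ 0.25
  expect_gt(out$r, 0.15)
  expect_lt(abs(out$r_partial), 0.15)
})
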