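test_that("nominal cis p-values match a per-variant lm oracle", {
  set.seed(31)
  n <- 60
  geno <- make_geno(matrix(rbinom(n * 8, 2, 0.3), n, 8))
  vals <- matrix(rnorm(n * 5), n, 5,
                 dimnames = list(NULL, sprintf("p%03d", 1:5)))
  vals[, 1] <- vals[, 1] + 0.5 * geno$dosage[, 1]
  pm <- make_pheno(vals, pos = rep(4000, 5))
  covs <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("c1", "c2")))
  for (cv in list(NULL, covs)) {
    recs <- map_cis_nominal(pm, geno, window_bp = 1e5, covariates = cv)
    for (j in 1:5) {
      oracle <- oracle_lm_scan(vals[, j], geno$dosage, cv)
      got <- recs$p_nominal[recs$phenotype_id == colnames(vals)[j]]
      expect_lt(max(abs(got - oracle)), 1e-10)
    }
  }
})

test_that("a noiseless planted slope is recovered exactly", {
  set.seed(32)
  g <- make_geno(matrix(rbinom(40, 2, 0.4), 20, 2))
  y <- 2 + 1 * g$dosage[, 1]
  recs <- map_cis_nominal(make_pheno(cbind(y = y), pos = 1000), g,
                          window_bp = 1e4)
  r1 <- recs[recs$variant_id == "v001", ]
  expect_equal(r1$b, 1, tolerance = 1e-9)
  expect_lt(r1$p_nominal, 1e-20)
})

test_that("the cis window is a closed interval around the strand-aware TSS", {
  set.seed(33)
  g <- make_geno(matrix(rbinom(100, 2, 0.4), 20, 5),
                 pos = c(900, 1000, 2000, 3000, 3001))
  pm <- make_pheno(matrix(rnorm(20), 20, 1), pos = 2000)
  recs <- map_cis_nominal(pm, g, window_bp = 1000)
  # 1000 and 3000 are exactly at the edge: included; 900 and 3001 are not
  expect_setequal(recs$variant_id, c("v002", "v003", "v004"))
  # minus-strand phenotypes flip the sign of the distance
  pm_minus <- make_pheno(matrix(rnorm(20), 20, 1), pos = 2000,
                         strand = "-")
  recs_m <- map_cis_nominal(pm_minus, g, window_bp = 1000)
  expect_equal(recs_m$distance_to_tss[recs_m$variant_id == "v004"], -1000)
})

test_that("zero-variance variants are skipped, not fatal", {
  set.seed(34)
  d <- cbind(rbinom(20, 2, 0.4), rep(1, 20))
  pm <- make_pheno(matrix(rnorm(20), 20, 1), pos = 1000)
  expect_message(
    recs <- map_cis_nominal(pm, make_geno(d), window_bp = 1e4,
                            verbose = TRUE),
    "zero-variance")
  expect_identical(recs$variant_id, "v001")
})

test_that("exhaustive permutation p equals full enumeration", {
  set.seed(35)
  n <- 6
  d <- matrix(rbinom(n * 3, 2, 0.5), n, 3)
  d[, 1] <- c(0, 0, 1, 1, 2, 2)
  y <- 0.9 * d[, 1] + rnorm(n, sd = 0.5)
  g <- make_geno(d)
  pm <- make_pheno(cbind(y = y), pos = 2000)
  got <- permutation_pass(pm, g, window_bp = 1e4, exhaustive = TRUE,
                          beta_fit = FALSE)
  oracle <- oracle_perm_exhaustive(y, d)
  expect_equal(got$p_empirical, oracle)
  # an observed best that is the worst over all permutations gives p = 1
  stats_all <- vapply(all_perms_list(n), function(p) {
    max(abs(stats::cor(y[p], d)))
  }, numeric(1))
  worst <- all_perms_list(n)[[which.min(stats_all)]]
  got_worst <- permutation_pass(make_pheno(cbind(y = y[worst]),
                                           pos = 2000),
                                g, window_bp = 1e4, exhaustive = TRUE,
                                beta_fit = FALSE)
  expect_equal(got_worst$p_empirical, 1)
})

test_that("sampled permutation p tracks enumeration within binomial error", {
  set.seed(36)
  n <- 6
  d <- matrix(rbinom(n * 4, 2, 0.5), n, 4)
  d[, 2] <- c(0, 1, 0, 1, 2, 2)
  y <- 0.8 * d[, 2] + rnorm(n, sd = 0.7)
  exact <- oracle_perm_exhaustive(y, d)
  got <- permutation_pass(make_pheno(cbind(y = y), pos = 2000),
                          make_geno(d), window_bp = 1e4, n_perm = 2000,
                          beta_fit = FALSE, seed = 1)
  expect_lt(abs(got$p_empirical - exact),
            3 * sqrt(exact * (1 - exact) / 2000) + 2 / 2000)
  expect_error(permutation_pass(make_pheno(cbind(y = y), pos = 2000),
                                make_geno(d), n_perm = 50), ">= 100")
})

test_that("group-best permutation takes the best across a gene's transcripts", {
  set.seed(37)
  n <- 40
  d <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  g <- make_geno(d)
  vals <- cbind(t1 = rnorm(n), t2 = 0.9 * d[, 1] + rnorm(n, sd = 0.4))
  pm <- make_pheno(vals, pos = c(1500, 1500), group = c("geneA", "geneA"))
  res <- permutation_pass(pm, g, window_bp = 1e4, n_perm = 200,
                          grouping = "group", seed = 2)
  expect_identical(nrow(res), 1L)
  expect_identical(res$group_id, "geneA")
  expect_identical(res$phenotype_id, "t2")
  expect_lt(res$p_empirical, 0.05)
})

test_that("conditional pass separates independent signals from proxies", {
  set.seed(38)
  n <- 200
  g1 <- rbinom(n, 2, 0.4)
  g2 <- rbinom(n, 2, 0.4)          # unlinked second signal
  proxy <- g1
  flip <- sample(n, 4)              # r^2 ~ 0.95 proxy of g1
  proxy[flip] <- rbinom(4, 2, 0.4)
  noise <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  d <- cbind(g1, g2, proxy, noise)
  colnames(d) <- sprintf("v%03d", 1:6)
  geno <- make_geno(d)
  expect_lt(cor(g1, g2)^2, 0.05)
  expect_gt(cor(g1, proxy)^2, 0.85)
  y <- 0.8 * g1 + 0.8 * g2 + rnorm(n)
  pm <- make_pheno(cbind(y = y), pos = 3000)
  recs <- conditional_pass(pm, geno, window_bp = 1e4, p_threshold = 1e-4)
  expect_identical(nrow(recs), 2L)
  # one signal from the g1/proxy clump, plus the unlinked g2
  expect_identical(sum(recs$variant_id %in% c("v001", "v003")), 1L)
  expect_true("v002" %in% recs$variant_id)
  expect_setequal(recs$signal_rank, 1:2)
  # one signal plus its proxy: exactly one reported
  y2 <- 0.8 * g1 + rnorm(n)
  recs2 <- conditional_pass(make_pheno(cbind(y = y2), pos = 3000), geno,
                            window_bp = 1e4, p_threshold = 1e-4)
  expect_identical(nrow(recs2), 1L)
  expect_true(recs2$variant_id %in% c("v001", "v003"))
  # no significant primary: empty result, no error
  y3 <- rnorm(n)
  recs3 <- conditional_pass(make_pheno(cbind(y = y3), pos = 3000), geno,
                            window_bp = 1e4, p_threshold = 1e-6)
  expect_identical(nrow(recs3), 0L)
})

test_that("conditional pass recovers planted independent signals", {
  set.seed(39)
  n <- 200
  hits <- 0; total <- 0
  for (locus in 1:60) {
    d <- matrix(rbinom(n * 12, 2, runif(12, 0.2, 0.5)), n, 12)
    keep <- apply(d, 2, sd) > 0
    d <- d[, keep, drop = FALSE]
    colnames(d) <- sprintf("v%03d", seq_len(ncol(d)))
    a <- 1; b <- ncol(d)
    if (cor(d[, a], d[, b])^2 > 0.01) next
    y <- 0.7 * d[, a] + 0.7 * d[, b] + rnorm(n)
    recs <- conditional_pass(make_pheno(cbind(y = y), pos = 5000),
                             make_geno(d), window_bp = 1e5,
                             p_threshold = 1e-4)
    total <- total + 2
    hits <- hits + sum(c(colnames(d)[a], colnames(d)[b]) %in%
                         recs$variant_id)
  }
  expect_gte(hits / total, 0.95)
})

test_that("LD clumping keeps the lowest-p member of each clump", {
  set.seed(40)
  n <- 100
  g1 <- rbinom(n, 2, 0.4)
  g3 <- rbinom(n, 2, 0.4)
  d <- cbind(v1 = g1, v2 = g1, v3 = g3)   # v1, v2 identical (r^2 = 1)
  geno <- make_geno(d, pos = c(100, 200, 300))
  recs <- tibble::tibble(variant_id = c("v1", "v2", "v3"),
                         p_nominal = c(1e-8, 1e-10, 1e-4))
  leads <- ld_clump(recs, geno, r2_threshold = 1e-3)
  expect_setequal(leads$variant_id, c("v2", "v3"))
  # uncorrelated variants all become leads
  d2 <- matrix(rbinom(n * 3, 2, 0.5), n, 3)
  while (max(abs(cor(d2)[upper.tri(diag(3))])) > 0.03) {
    d2 <- matrix(rbinom(n * 3, 2, 0.5), n, 3)
  }
  geno2 <- make_geno(d2)
  recs2 <- tibble::tibble(variant_id = colnames(geno2$dosage),
                          p_nominal = c(0.01, 0.02, 0.03))
  expect_identical(nrow(ld_clump(recs2, geno2, r2_threshold = 0.5)), 3L)
  # tie in p inside a clump: the smaller genomic position wins
  recs3 <- tibble::tibble(variant_id = c("v1", "v2"),
                          p_nominal = c(1e-6, 1e-6))
  expect_identical(ld_clump(recs3, geno, r2_threshold = 1e-3)$variant_id,
                   "v1")
  expect_identical(nrow(ld_clump(recs3[0, ], geno)), 0L)
})

test_that("BH wrapper and pi1 estimator behave at the limits", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "outside")
  set.seed(41)
  expect_lt(estimate_pi1(runif(5000)), 0.05)
  expect_gt(estimate_pi1(rep(1e-8, 5000)), 0.95)
  p_mix <- c(rep(1e-8, 3000), runif(7000))
  expect_lt(abs(estimate_pi1(p_mix) - 0.3), 0.05)
})

test_that("analytic power matches a Monte-Carlo rejection rate", {
  n <- 138; slope <- 0.25; maf <- 0.3; sigma_e <- 1; alpha <- 0.05
  var_g <- 2 * maf * (1 - maf)
  sigma_y <- sqrt(sigma_e^2 + slope^2 * var_g)
  analytic <- eqtl_power_slr(n, slope, maf, sigma_y = sigma_y,
                             alpha = alpha)
  set.seed(42)
  n_sims <- 20000
  rej <- vapply(seq_len(n_sims), function(i) {
    g <- rbinom(n, 2, maf)
    if (sd(g) == 0) return(NA)
    y <- slope * g + rnorm(n, sd = sigma_e)
    r <- cor(y, g)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    abs(tval) > qt(1 - alpha / 2, n - 2)
  }, logical(1))
  expect_equal(mean(rej, na.rm = TRUE), analytic, tolerance = 0.01)
})

test_that("power is monotone and handles the degenerate limits", {
  expect_equal(eqtl_power_slr(100, 0, 0.3, sigma_y = 1, alpha = 0.05),
               0.05, tolerance = 1e-12)
  # slope huge relative to the residual SD: power saturates
  expect_gt(eqtl_power_slr(138, 1, 0.3,
                           sigma_y = sqrt(1 * 2 * 0.3 * 0.7 + 0.01),
                           alpha = 0.01), 0.999)
  p_n <- vapply(c(50, 100, 200, 400), eqtl_power_slr, numeric(1),
                slope = 0.3, maf = 0.3, sigma_y = 1.5, alpha = 0.01)
  expect_true(all(diff(p_n) > 0))
  p_b <- vapply(c(0.1, 0.2, 0.4), function(b)
    eqtl_power_slr(100, b, 0.3, sigma_y = 2, alpha = 0.01), numeric(1))
  expect_true(all(diff(p_b) > 0))
  p_s <- vapply(c(1, 2, 4), function(s)
    eqtl_power_slr(100, 0.3, 0.3, sigma_y = s, alpha = 0.01), numeric(1))
  expect_true(all(diff(p_s) < 0))
  expect_error(eqtl_power_slr(100, 2, 0.5, sigma_y = 1), "residual")
})
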