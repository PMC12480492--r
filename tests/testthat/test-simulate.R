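test_that("simulation spec rejects degenerate frequency ranges", {
  expect_error(sim_spec(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_spec(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_spec(n_individuals = 5), "n_individuals")
})

test_that("genotypes follow HWE at the planted frequency", {
  spec <- sim_spec(n_individuals = 20000, n_variants = 5,
                   maf_range = c(0.5, 0.5), seed = 42)
  geno <- simulate_genotypes(spec)
  for (j in 1:5) {
    freq <- tabulate(geno$dosage[, j] + 1, 3) / 20000
    expected <- c(0.25, 0.5, 0.25)
    sds <- sqrt(expected * (1 - expected) / 20000)
    expect_true(all(abs(freq - expected) < 3 * sds))
  }
  # empirical MAF within 3 binomial SDs of the request across a range
  spec2 <- sim_spec(n_individuals = 5000, n_variants = 50, seed = 7)
  g2 <- simulate_genotypes(spec2)
  emp <- colMeans(g2$dosage) / 2
  sds <- sqrt(g2$map$maf * (1 - g2$map$maf) / (2 * 5000))
  expect_true(all(abs(emp - g2$map$maf) < 3 * sds))
})

test_that("the seed fully determines generator output", {
  spec <- sim_spec(n_individuals = 50, n_variants = 20, seed = 3)
  g1 <- simulate_genotypes(spec)
  g2 <- simulate_genotypes(spec)
  expect_identical(g1$dosage, g2$dosage)
  eff <- list(planted_effect("var_0001", "gene1",
                             beta = c(UT = 1, LPS = 0, IFN = 0)))
  e1 <- simulate_expression(g1, eff, n_background_genes = 3, spec = spec)
  e2 <- simulate_expression(g1, eff, n_background_genes = 3, spec = spec)
  expect_identical(e1$UT$values, e2$UT$values)
  fx1 <- simulate_study_fixture(seed = 5)
  fx2 <- simulate_study_fixture(seed = 5)
  expect_identical(rlang::hash(fx1), rlang::hash(fx2))
})

test_that("noiseless planted effect reproduces the generative identity", {
  spec <- sim_spec(n_individuals = 30, n_variants = 5, seed = 1)
  geno <- simulate_genotypes(spec)
  eff <- list(planted_effect("var_0002", "g1", noise_sd = 0,
                             beta = c(UT = 1, LPS = 0, IFN = 0)))
  expr <- simulate_expression(geno, eff, n_background_genes = 0,
                              n_confounders = 0, spec = spec)
  expect_equal(unname(expr$UT$values[, "g1"]),
               unname(geno$dosage[, "var_0002"]))
  expect_equal(unname(expr$LPS$values[, "g1"]), rep(0, 30))
})

test_that("duplicate planting and all-zero effects are rejected", {
  spec <- sim_spec(n_individuals = 20, n_variants = 5, seed = 1)
  geno <- simulate_genotypes(spec)
  eff <- planted_effect("var_0001", "g1", beta = c(UT = 1))
  expect_error(simulate_expression(geno, list(eff, eff), spec = spec),
               "duplicate")
  expect_error(planted_effect("var_0001", "g1", beta = c(UT = 0)),
               "beta != 0")
})

test_that("coexpression strata converge to their target correlations", {
  spec <- sim_spec(n_individuals = 20000, n_variants = 3,
                   maf_range = c(0.4, 0.5), genome_length = 1e5, seed = 9)
  geno <- simulate_genotypes(spec)
  v <- geno$map$variant_id[1]
  geno <- set_exact_hwe_variant(geno, v, maf = 0.5)
  # equal targets: pooled and stratified correlations all ~ 0.6
  cs <- coex_spec("a", "b", v, r_by_genotype = c(RR = 0.6, RM = 0.6,
                                                 MM = 0.6))
  expr <- simulate_coexpression(geno, list(cs), spec)
  g <- round(geno$dosage[, v])
  expect_equal(stats::cor(expr$values[, "a"], expr$values[, "b"]), 0.6,
               tolerance = 0.03)
  for (k in 0:2) {
    idx <- g == k
    expect_equal(stats::cor(expr$values[idx, "a"], expr$values[idx, "b"]),
                 0.6, tolerance = 0.03)
  }
  # sign-discordant targets are recovered per stratum
  cs2 <- coex_spec("a", "b", v, r_by_genotype = c(RR = 0.7, RM = 0,
                                                  MM = -0.7))
  expr2 <- simulate_coexpression(geno, list(cs2), spec)
  r_rr <- stats::cor(expr2$values[g == 0, "a"], expr2$values[g == 0, "b"])
  r_mm <- stats::cor(expr2$values[g == 2, "a"], expr2$values[g == 2, "b"])
  expect_equal(r_rr, 0.7, tolerance = 0.03)
  expect_equal(r_mm, -0.7, tolerance = 0.03)
  expect_error(coex_spec("a", "b", v, c(RR = 1, RM = 0, MM = 0)),
               "< 1")
})

test_that("mediation chains have the declared generative structure", {
  spec <- sim_spec(n_individuals = 5000, n_variants = 4,
                   maf_range = c(0.3, 0.5), genome_length = 1e5,
                   seed = 11)
  geno <- simulate_genotypes(spec)
  ids <- geno$map$variant_id
  specs <- list(
    mediation_spec(ids[1], "c1", "e1", chain = "SNP->M->E"),
    mediation_spec(ids[2], "c2", "e2", chain = "independent"),
    mediation_spec(ids[3], "c3", "e3", chain = "SNP->M->E", b2 = -0.6))
  med <- simulate_methylation(geno, specs, spec)
  # SNP explains methylation better than expression downstream of it
  expect_gt(abs(stats::cor(geno$dosage[, 1], med$meth$values[, "c1"])),
            abs(stats::cor(geno$dosage[, 1], med$expr$values[, "e1"])))
  # independence chain: SNP-gene correlation ~ 0
  expect_lt(abs(stats::cor(geno$dosage[, 2], med$expr$values[, "e2"])),
            0.05)
  # negative methylation->expression edge gives a negative correlation
  expect_lt(stats::cor(med$meth$values[, "c3"], med$expr$values[, "e3"]),
            0)
  # betas live in (0, 1)
  expect_true(all(med$meth$values > 0 & med$meth$values < 1))
  expect_error(mediation_spec(ids[1], "x", "x"), "cyclic")
})

test_that("null GWAS summary statistics are uniform", {
  spec <- sim_spec(n_individuals = 300, n_variants = 400, seed = 13)
  geno <- simulate_genotypes(spec)
  gw <- simulate_gwas_summary(geno, causal_variant = NULL, effect = 0,
                              spec = spec)
  expect_gt(stats::ks.test(gw$p, "punif")$p.value, 0.01)
  gw2 <- simulate_gwas_summary(geno, geno$map$variant_id[5], effect = 1,
                               spec = spec)
  expect_lt(gw2$p[5], 1e-10)
})

test_that("annotation placement respects fold and genome bounds", {
  spec <- sim_spec(n_individuals = 10, n_variants = 500,
                   genome_length = 1e7, seed = 17)
  geno <- simulate_genotypes(spec)
  fg <- geno$map$pos[1:100]
  feats <- simulate_annotations(spec, geno$map$pos, fg, fold = 4,
                                bg_rate = 0.1)
  expect_true(all(feats$start >= 0 & feats$end <= spec$genome_length))
  expect_error(simulate_annotations(spec, geno$map$pos, fg, fold = 0.5),
               "fold")
  expect_error(simulate_annotations(spec, c(geno$map$pos, 2e7), fg,
                                    fold = 2),
               "bounds")
})
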