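test_that("stratification applies the strict homozygote-count rule", {
  d <- c(rep(0, 10), rep(1, 10), rep(2, 5))
  g5 <- make_geno(cbind(v1 = d))
  s5 <- stratify(g5, "v1")
  expect_false(s5$eligible)                       # MM count = 5: strict >
  g6 <- make_geno(cbind(v1 = c(d, 2)))
  expect_true(stratify(g6, "v1")$eligible)        # MM count = 6
  mono <- make_geno(cbind(v1 = rep(0, 20)))
  s0 <- stratify(mono, "v1")
  expect_identical(s0$n[["RR"]], 20L)
  expect_false(s0$eligible)
  expect_identical(length(intersect(s5$RR, s5$MM)), 0L)
})

test_that("Fisher z matches its closed form and round-trips", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-15)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  r2 <- seq(-0.999, 0.999, length.out = 201)
  expect_lt(max(abs(inv_fisher_z(fisher_z(r2)) - r2)), 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("dz statistic agrees with an independently coded z-test", {
  same <- dz_statistic(0.4, 50, 0.4, 60)
  expect_identical(same$dz, 0)
  expect_identical(same$p, 1)
  # frozen oracle value: (atanh(0.8) - atanh(0.2)) / sqrt(2/50)
  hand <- dz_statistic(0.8, 53, 0.2, 53)
  expect_equal(hand$dz, 4.4793985, tolerance = 1e-6)
  set.seed(71)
  for (i in 1:100) {
    r1 <- runif(1, -0.95, 0.95); r2 <- runif(1, -0.95, 0.95)
    n1 <- sample(10:500, 1); n2 <- sample(10:500, 1)
    expect_lt(abs(dz_statistic(r1, n1, r2, n2)$dz -
                    oracle_dz(r1, n1, r2, n2)), 1e-10)
  }
  # the printed literal denominator is singular for equal group sizes
  expect_error(dz_statistic(0.5, 53, 0.2, 53, mode = "literal"),
               "equal group sizes")
  lit <- dz_statistic(0.5, 40, 0.2, 80, mode = "literal")
  expect_equal(lit$dz,
               (atanh(0.5) - atanh(0.2)) / sqrt(abs(1 / 37 - 1 / 77)),
               tolerance = 1e-12)
  expect_error(dz_statistic(0.5, 3, 0.2, 50), "> 3")
})

test_that("the nine differential-correlation classes enumerate exactly", {
  labels <- c(pos = 0.9, ns = 0.05, neg = -0.9)
  ps <- c(pos = 1e-4, ns = 0.5, neg = 1e-4)
  grid <- expand.grid(a = names(labels), b = names(labels),
                      stringsAsFactors = FALSE)
  got <- classify_dc(labels[grid$a], ps[grid$a],
                     labels[grid$b], ps[grid$b])
  expect_identical(sort(unique(got)), sort(got))   # all distinct
  expect_identical(length(got), 9L)
  expect_setequal(got, paste(grid$a, grid$b, sep = "/"))
  expect_identical(classify_dc(0.9, 1e-4, -0.9, 1e-4), "pos/neg")
})

test_that("the pairwise consistency rule fires only when q holds", {
  # q true: d must equal p
  expect_true(dc_consistent(TRUE, TRUE, TRUE))
  expect_false(dc_consistent(TRUE, TRUE, FALSE))
  expect_true(dc_consistent(FALSE, TRUE, FALSE))
  expect_false(dc_consistent(FALSE, TRUE, TRUE))
  # q false: rule silent
  expect_true(all(dc_consistent(c(TRUE, FALSE), FALSE, c(TRUE, FALSE))))
})

test_that("coexqtl detection recovers a planted sign flip", {
  spec <- sim_spec(n_individuals = 280, n_variants = 3,
                   genome_length = 1e5, seed = 72)
  geno <- simulate_genotypes(spec)
  v <- geno$map$variant_id[1]
  geno <- set_exact_hwe_variant(geno, v, maf = 0.5)
  cs <- coex_spec("anchor", "partner", v,
                  r_by_genotype = c(RR = 0.7, RM = 0.1, MM = -0.5))
  expr <- simulate_coexpression(geno, list(cs), spec,
                                n_background_genes = 4)
  res <- detect_coexqtl("anchor", v, expr, geno, alpha = 1e-3)
  hit <- res[res$partner == "partner", ]
  expect_true(hit$pass)
  expect_identical(hit$dc_class, "pos/neg")
  expect_lt(hit$dz_mm_rr, 0)
  # the anchor is never its own partner
  expect_false("anchor" %in% res$partner)
  # dz z-scores are antisymmetric under stratum swap
  fwd <- dz_statistic(hit$r_mm, hit$n_mm, hit$r_rr, hit$n_rr)
  rev <- dz_statistic(hit$r_rr, hit$n_rr, hit$r_mm, hit$n_mm)
  expect_equal(fwd$dz, -rev$dz)
})

test_that("interaction and dz p-values agree in rank order", {
  spec <- sim_spec(n_individuals = 240, n_variants = 2,
                   genome_length = 1e5, seed = 73)
  geno <- simulate_genotypes(spec)
  v <- geno$map$variant_id[1]
  geno <- set_exact_hwe_variant(geno, v, maf = 0.5)
  specs <- lapply(1:25, function(i) {
    delta <- seq(0, 0.9, length.out = 25)[i]
    coex_spec("anchor", sprintf("p%02d", i), v,
              r_by_genotype = c(RR = delta / 2, RM = 0, MM = -delta / 2))
  })
  expr <- simulate_coexpression(geno, specs, spec)
  res <- detect_coexqtl("anchor", v, expr, geno)
  rho <- stats::cor(res$p_interaction, res$p_dz, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("ineligible strata and degenerate partners are handled", {
  set.seed(74)
  d <- cbind(v1 = c(rep(0, 30), rep(1, 20), rep(2, 3)))
  geno <- make_geno(d)
  expr <- make_pheno(cbind(anchor = rnorm(53), p1 = rnorm(53)))
  expect_error(detect_coexqtl("anchor", "v1", expr, geno), "ineligible")
  d2 <- cbind(v1 = rep(c(0, 1, 2), c(20, 20, 13)))
  geno2 <- make_geno(d2)
  vals <- cbind(anchor = rnorm(53), flat = rep(1, 53), p2 = rnorm(53))
  expect_message(
    res <- detect_coexqtl("anchor", "v1", make_pheno(vals), geno2,
                          verbose = TRUE),
    "zero-variance")
  expect_identical(res$partner, "p2")
})

test_that("replication requires the triple and the direction to match", {
  rec <- tibble::tibble(anchor = "a", partner = "b", variant_id = "v",
                        dz_mm_rr = -3)
  expect_true(replicate_coexqtl(rec, rec)$replicated)
  flipped <- dplyr::mutate(rec, dz_mm_rr = 3)
  expect_false(replicate_coexqtl(rec, flipped)$replicated)
  other <- dplyr::mutate(rec, partner = "c")
  expect_false(replicate_coexqtl(rec, other)$replicated)
})

test_that("methylation links recover genotype-dependent CpG coupling", {
  spec <- sim_spec(n_individuals = 280, n_variants = 2,
                   genome_length = 1e5, seed = 75)
  geno <- simulate_genotypes(spec)
  v <- geno$map$variant_id[1]
  geno <- set_exact_hwe_variant(geno, v, maf = 0.5)
  set.seed(76)
  n <- 280
  g <- round(geno$dosage[, v])
  cpg_lat <- rnorm(n)
  r_by_g <- c(0.7, 0.1, -0.5)[g + 1]
  gene <- r_by_g * cpg_lat + sqrt(1 - r_by_g^2) * rnorm(n)
  meth_v <- cbind(linked = plogis(cpg_lat), free = runif(n),
                  flat = rep(0.5, n))
  rownames(meth_v) <- rownames(geno$dosage)
  expr_v <- cbind(net_gene = gene)
  rownames(expr_v) <- rownames(geno$dosage)
  coex <- tibble::tibble(anchor = "x", partner = "net_gene",
                         variant_id = v)
  expect_message(
    links <- coex_methylation_links(coex, make_pheno(meth_v),
                                    make_pheno(expr_v), geno,
                                    alpha = 0.01),
    "constant CpG")
  linked <- links[links$anchor == "linked", ]
  free <- links[links$anchor == "free", ]
  expect_true(linked$p_interaction < 1e-6)
  expect_gt(free$p_interaction, 0.01)
})
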