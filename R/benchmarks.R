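# Seeded simulation studies: parameter-recovery and null-calibration
# experiments over the synthetic generators. These are the reproducible
# experiments behind the package's validation claims; the acceptance
# script and the test suite both run them.

#' Context-label recovery over replicate fixtures
#'
#' For each replicate: builds the default study fixture, rank-inverse-
#' normalises the condition-wise expression, maps cis associations per
#' condition, picks each phenotype's best variant across conditions,
#' BH-adjusts within condition, classifies context, and compares the
#' label with the planted truth.
#'
#' @param n_rep Number of replicate fixtures.
#' @param seed Base seed.
#' @param sig_fdr,nonsig_floor Passed to [classify_context()].
#' @param ... Passed to [simulate_study_fixture()].
#' @return Tibble: one row per planted QTL per replicate with `truth`,
#'   `label`, `correct`.
#' @export
sim_study_context <- function(n_rep = 50, seed = 1, sig_fdr = 0.01,
                              nonsig_floor = 0.05, ...) {
  purrr::map_dfr(seq_len(n_rep), function(rep_i) {
    fx <- simulate_study_fixture(seed = seed + rep_i * 1009L, ...)
    conds <- fx$spec$conditions
    nominal <- purrr::map_dfr(conds, function(cond) {
      pm <- fx$expr[[cond]]
      vals <- apply(pm$values, 2, rank_inverse_normal)
      rownames(vals) <- rownames(pm$values)
      map_cis_nominal(pheno_matrix(vals, pm$map), fx$geno,
                      maf_min = 0.04, condition = cond)
    })
    best <- dplyr::slice_min(
      dplyr::group_by(nominal, .data$phenotype_id),
      .data$p_nominal, n = 1, with_ties = FALSE)
    best <- dplyr::ungroup(best)[, c("phenotype_id", "variant_id")]
    recs <- dplyr::inner_join(nominal, best,
                              by = c("phenotype_id", "variant_id"))
    recs <- dplyr::ungroup(dplyr::mutate(
      dplyr::group_by(recs, .data$condition),
      fdr = fdr_bh(.data$p_nominal)))
    calls <- classify_context(recs, sig_fdr = sig_fdr,
                              nonsig_floor = nonsig_floor,
                              conditions = conds)
    # left join: a planted pair whose best variant was not even recovered
    # counts as incorrectly labelled, not as missing
    out <- dplyr::left_join(
      fx$truth, calls, by = c("phenotype_id", "variant_id"))
    tibble::tibble(replicate = rep_i, phenotype_id = out$phenotype_id,
                   truth = out$label.x, label = out$label.y,
                   correct = !is.na(out$label.y) &
                     out$label.x == out$label.y)
  })
}

#' Steiger-direction recovery over planted mediation chains
#'
#' Simulates `n_chains` SNP/CpG/gene triples under one declared chain,
#' computes the SNP-methylation and SNP-expression correlations, and
#' checks the Steiger direction call against the generative truth.
#'
#' @param n_chains Number of chains.
#' @param seed Seed.
#' @param chain Generative chain for all triples.
#' @param n_individuals Cohort size.
#' @param threshold Steiger significance threshold.
#' @return Tibble: per-chain correlations, `direction`, `correct`
#'   (significant and pointing the planted way).
#' @export
sim_study_steiger <- function(n_chains = 200, seed = 1,
                              chain = "SNP->M->E", n_individuals = 280,
                              threshold = 0.05) {
  spec <- sim_spec(n_individuals = n_individuals, n_variants = n_chains,
                   maf_range = c(0.2, 0.5), seed = seed)
  geno <- simulate_genotypes(spec)
  specs <- lapply(seq_len(n_chains), function(i) {
    mediation_spec(geno$map$variant_id[i], sprintf("cpg_%03d", i),
                   sprintf("gene_%03d", i), chain = chain)
  })
  med <- simulate_methylation(geno, specs, spec)
  r_sm <- vapply(seq_len(n_chains), function(i) {
    stats::cor(geno$dosage[, i], med$meth$values[, i])
  }, numeric(1))
  r_se <- vapply(seq_len(n_chains), function(i) {
    stats::cor(geno$dosage[, i], med$expr$values[, i])
  }, numeric(1))
  out <- steiger_direction(r_sm, r_se, n_individuals, n_individuals,
                           threshold = threshold)
  expected <- switch(chain, "SNP->M->E" = "M->E", "SNP->E->M" = "E->M",
                     "undetermined")
  out$correct <- out$direction == expected
  out
}

#' Colocalization recovery under shared vs distinct causal variants
#'
#' Per simulation: a fresh genotype region, a cis eQTL trait mapped with
#' [map_cis_nominal()] (giving the trait-1 summary statistics), and a
#' GWAS summary table from [simulate_gwas_summary()] whose causal variant
#' either equals the eQTL variant (`"shared"`) or is a different variant
#' in the region (`"distinct"`).
#'
#' @param n_sims Number of simulations.
#' @param seed Base seed.
#' @param scenario `"shared"` or `"distinct"`.
#' @param effect Planted slope for both traits.
#' @param n_individuals,n_variants Region shape.
#' @return Tibble: per-sim posteriors and the top hypothesis.
#' @export
sim_study_coloc <- function(n_sims = 30, seed = 1,
                            scenario = c("shared", "distinct"),
                            effect = 0.8, n_individuals = 280,
                            n_variants = 60) {
  scenario <- match.arg(scenario)
  purrr::map_dfr(seq_len(n_sims), function(i) {
    spec <- sim_spec(n_individuals = n_individuals,
                     n_variants = n_variants, maf_range = c(0.1, 0.5),
                     genome_length = 1e6, seed = seed + i * 613L)
    geno <- simulate_genotypes(spec)
    # strong-signal scenario: causal variants at healthy MAF (as for the
    # fixture's planted QTL), so both traits carry unambiguous signals
    common <- which(geno$map$maf >= 0.25)
    causal_e <- geno$map$variant_id[common[1]]
    causal_g <- if (scenario == "shared") causal_e else
      geno$map$variant_id[common[length(common)]]
    eff <- planted_effect(causal_e, "egene",
                          beta = c(UT = effect, LPS = 0, IFN = 0))
    expr <- simulate_expression(geno, list(eff), n_background_genes = 0,
                                n_confounders = 0, spec = spec)$UT
    vals <- apply(expr$values, 2, rank_inverse_normal)
    rownames(vals) <- rownames(expr$values)
    stats1 <- map_cis_nominal(pheno_matrix(vals, expr$map), geno,
                              window_bp = 1e6)
    stats1 <- dplyr::select(stats1, "variant_id", beta = "b", "se")
    gwas <- simulate_gwas_summary(geno, causal_g, effect = effect,
                                  spec = spec)
    cl <- coloc_abf(stats1,
                    dplyr::select(gwas, "variant_id", "beta", "se"))
    tibble::as_tibble(as.list(cl$posteriors)) |>
      dplyr::mutate(sim = i, scenario = scenario,
                    top = names(which.max(cl$posteriors)))
  })
}

#' Co-expression QTL detection power over seeded replicates
#'
#' Per replicate: one exact-HWE MAF-0.5 variant, a planted anchor-partner
#' pair with the given stratum correlations plus null background
#' partners, then [detect_coexqtl()]; detection means the planted partner
#' passes the BH-adjusted interaction threshold, and the sign pattern is
#' recovered when the extreme-stratum correlation signs match the plan.
#'
#' @param n_rep Replicates.
#' @param seed Base seed.
#' @param r_by_genotype Planted stratum correlations.
#' @param alpha Detection threshold on the BH-adjusted interaction p.
#' @param n_individuals Cohort size (280 gives ~70 per extreme stratum).
#' @param n_background Null partners alongside the planted one.
#' @return Tibble: per-replicate `detected`, `sign_ok`, estimated r.
#' @export
sim_study_coexqtl <- function(n_rep = 100, seed = 1,
                              r_by_genotype = c(RR = 0.6, RM = 0.1,
                                                MM = -0.4),
                              alpha = 1e-3, n_individuals = 280,
                              n_background = 5) {
  purrr::map_dfr(seq_len(n_rep), function(i) {
    spec <- sim_spec(n_individuals = n_individuals, n_variants = 4,
                     genome_length = 1e5, seed = seed + i * 389L)
    geno <- simulate_genotypes(spec)
    v <- geno$map$variant_id[1]
    geno <- set_exact_hwe_variant(geno, v, maf = 0.5)
    cs <- coex_spec("anchor", "partner", v,
                    r_by_genotype = r_by_genotype)
    expr <- simulate_coexpression(geno, list(cs), spec,
                                  n_background_genes = n_background)
    res <- detect_coexqtl("anchor", v, expr, geno, alpha = alpha)
    hit <- res[res$partner == "partner", ]
    tibble::tibble(
      replicate = i, detected = hit$pass,
      sign_ok = sign(hit$r_rr) == sign(r_by_genotype[["RR"]]) &
        sign(hit$r_mm) == sign(r_by_genotype[["MM"]]),
      dc_class = hit$dc_class, r_rr = hit$r_rr, r_mm = hit$r_mm,
      p_interaction = hit$p_interaction)
  })
}

#' Type-I error of the nominal cis test under the null
#'
#' Null phenotypes against one variant each; returns the nominal
#' p-values (each replicate contributes one test).
#'
#' @param n_rep Replicates.
#' @param seed Seed.
#' @param n_individuals Cohort size.
#' @return Numeric vector of `n_rep` p-values.
#' @export
calibrate_cis_type1 <- function(n_rep = 2000, seed = 1,
                                n_individuals = 100) {
  spec <- sim_spec(n_individuals = n_individuals, n_variants = 1,
                   maf_range = c(0.2, 0.5), genome_length = 1e4,
                   seed = seed)
  geno <- simulate_genotypes(spec)
  set.seed(seed + 1L)
  vals <- matrix(stats::rnorm(n_individuals * n_rep), n_individuals,
                 dimnames = list(rownames(geno$dosage),
                                 sprintf("null_%04d", seq_len(n_rep))))
  map <- tibble::tibble(phenotype_id = colnames(vals), chrom = "chr1",
                        pos = geno$map$pos[1], strand = "+",
                        group_id = colnames(vals))
  recs <- map_cis_nominal(pheno_matrix(vals, map), geno,
                          window_bp = 1e4)
  recs$p_nominal
}

#' Type-I error of the co-expression interaction test under the null
#'
#' Anchor and partner share the same correlation in every genotype
#' stratum; returns the interaction p-values from [detect_coexqtl()].
#'
#' @param n_rep Replicates.
#' @param seed Base seed.
#' @param n_individuals Cohort size.
#' @param r Common correlation across strata.
#' @return Numeric vector of `n_rep` interaction p-values.
#' @export
calibrate_interaction_type1 <- function(n_rep = 2000, seed = 1,
                                        n_individuals = 150, r = 0.3) {
  spec <- sim_spec(n_individuals = n_individuals, n_variants = 1,
                   genome_length = 1e4, seed = seed)
  geno <- simulate_genotypes(spec)
  v <- geno$map$variant_id[1]
  geno <- set_exact_hwe_variant(geno, v, maf = 0.5)
  map <- tibble::tibble(phenotype_id = c("anchor", "partner"),
                        chrom = "chr1", pos = c(100, 200), strand = "+",
                        group_id = c("anchor", "partner"))
  set.seed(seed + 2L)
  vapply(seq_len(n_rep), function(i) {
    a <- stats::rnorm(n_individuals)
    b <- r * a + sqrt(1 - r^2) * stats::rnorm(n_individuals)
    vals <- cbind(anchor = a, partner = b)
    rownames(vals) <- rownames(geno$dosage)
    res <- detect_coexqtl("anchor", v, pheno_matrix(vals, map), geno)
    res$p_interaction[1]
  }, numeric(1))
}

#' Type-I error of the MDC permutation test under the null
#'
#' Module expression drawn from one population (a common factor with
#' genotype-independent coupling); returns the permutation p-values.
#'
#' @param n_rep Replicates.
#' @param seed Base seed.
#' @param n_genes Module size.
#' @param n_per_stratum Individuals per compared stratum.
#' @param n_perm Permutations per test.
#' @param rho Common pairwise correlation.
#' @return Numeric vector of `n_rep` permutation p-values.
#' @export
calibrate_mdc_type1 <- function(n_rep = 2000, seed = 1, n_genes = 5,
                                n_per_stratum = 50, n_perm = 199,
                                rho = 0.3) {
  n <- 2 * n_per_stratum
  strata <- list(RR = seq_len(n_per_stratum),
                 MM = n_per_stratum + seq_len(n_per_stratum))
  set.seed(seed + 3L)
  vapply(seq_len(n_rep), function(i) {
    f <- stats::rnorm(n)
    X <- sqrt(rho) * f + sqrt(1 - rho) *
      matrix(stats::rnorm(n * n_genes), n)
    colnames(X) <- sprintf("g%02d", seq_len(n_genes))
    mdc_test(X, strata, colnames(X), n_perm = n_perm,
             gene_filter = FALSE)$p
  }, numeric(1))
}

#' Null and planted-fold behaviour of the enrichment z-score
#'
#' Per replicate: annotation intervals placed by [simulate_annotations()]
#' at the given fold for the foreground SNP set, then the aggregated
#' enrichment z. `fold = 1` gives the null calibration; `fold > 1`
#' measures planted-enrichment recovery.
#'
#' @param n_rep Replicates.
#' @param seed Base seed.
#' @param n_fg,n_bg Foreground and background set sizes.
#' @param fold Planted fold.
#' @param bg_rate Background coverage rate.
#' @return Tibble: per-replicate `Z` and two-sided `p`.
#' @export
calibrate_enrichment <- function(n_rep = 2000, seed = 1, n_fg = 200,
                                 n_bg = 2000, fold = 1, bg_rate = 0.3) {
  n_snp <- n_fg + n_bg
  base_spec <- sim_spec(n_individuals = 10, n_variants = n_snp,
                        genome_length = 1e8, seed = seed)
  set.seed(seed + 4L)
  positions <- sort(sample.int(base_spec$genome_length, n_snp))
  fg_idx <- sample.int(n_snp, n_fg)
  snps <- tibble::tibble(variant_id = sprintf("s%05d", seq_len(n_snp)),
                         chrom = "chr1", pos = positions)
  fgbg <- tibble::tibble(phenotype_id = "all", variant_id = snps$variant_id,
                         set = ifelse(seq_len(n_snp) %in% fg_idx,
                                      "fg", "bg"))
  purrr::map_dfr(seq_len(n_rep), function(i) {
    sp <- base_spec
    sp$seed <- base_spec$seed + i * 227L
    feats <- simulate_annotations(
      sp, snp_positions = positions,
      enriched_positions = positions[fg_idx],
      feature_classes = "feat", fold = fold, bg_rate = bg_rate,
      halfwidth = 0)
    enr <- snp_enrichment(fgbg, snps, feats)
    tibble::tibble(replicate = i, Z = enr$Z[1], p = enr$p[1])
  })
}
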