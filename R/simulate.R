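# Synthetic cohort generator.
#
# Emulates the statistical structure the mapping stages assume: HWE
# genotypes on a toy genome, cis effects that are condition-specific or
# sign-discordant across stimulation conditions, genotype-dependent
# pairwise correlation, SNP -> CpG -> gene mediation chains, GWAS summary
# statistics, and annotation intervals enriched for chosen SNP sets.
# Every generator is fully determined by the seed carried in the spec.

.seed_offsets <- c(geno = 11L, expr = 29L, coex = 43L, meth = 57L,
                   gwas = 71L, annot = 83L, module = 97L)

.set_sim_seed <- function(spec, stage) {
  set.seed((spec$seed + .seed_offsets[[stage]]) %% .Machine$integer.max)
}

#' Simulation specification
#'
#' Cohort-shape parameters for the synthetic generators: number of
#' individuals (paired across conditions, as in a repeated-stimulation
#' design), number of variants placed uniformly on a single toy
#' chromosome, the minor-allele-frequency range, and the condition labels
#' (a naive condition first, stimulated conditions after).
#'
#' @param n_individuals Number of individuals (>= 10).
#' @param n_variants Number of variants.
#' @param maf_range Length-2 numeric in (0, 0.5], lower bound > 0.
#' @param conditions Character vector of condition labels; the first is
#'   treated as the naive/untreated condition.
#' @param genome_length Length of the toy chromosome in bp.
#' @param seed Integer seed; fully determines all generator output.
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(n_individuals = 280, n_variants = 300,
                     maf_range = c(0.04, 0.5),
                     conditions = c("UT", "LPS", "IFN"),
                     genome_length = 2e7, seed = 1L) {
  if (n_individuals < 10) rlang::abort("n_individuals must be >= 10")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    rlang::abort("maf_range must lie within (0, 0.5] with lower bound > 0")
  }
  if (n_variants < 1 || genome_length < n_variants) {
    rlang::abort("need n_variants >= 1 and genome_length >= n_variants")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 maf_range = as.numeric(maf_range),
                 conditions = as.character(conditions),
                 genome_length = as.numeric(genome_length),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Planted cis effect
#'
#' Describes one variant-phenotype association to plant: the slope per
#' minor allele in each condition (0 = absent in that condition;
#' sign-discordant slopes model the differential class), the residual
#' noise SD, and optional latent-confounder loadings.
#'
#' @param variant_id,phenotype_id Identifiers resolvable in the genotype /
#'   phenotype maps.
#' @param beta Named numeric vector, one slope per condition.
#' @param noise_sd Residual standard deviation (>= 0).
#' @param confounder_loadings Optional numeric vector of per-factor
#'   weights; `NULL` draws them at random like background genes.
#' @return A list of class `planted_effect`.
#' @export
planted_effect <- function(variant_id, phenotype_id, beta, noise_sd = 1,
                           confounder_loadings = NULL) {
  if (all(beta == 0)) {
    rlang::abort("a planted QTL needs beta != 0 in at least one condition")
  }
  if (noise_sd < 0) rlang::abort("noise_sd must be >= 0")
  structure(list(variant_id = variant_id, phenotype_id = phenotype_id,
                 beta = beta, noise_sd = noise_sd,
                 confounder_loadings = confounder_loadings),
            class = "planted_effect")
}

#' Genotype-dependent co-expression target
#'
#' Specifies a gene pair whose correlation depends on the genotype at a
#' variant: a target correlation per genotype stratum (RR = homozygous
#' reference, RM = heterozygous, MM = homozygous minor).
#'
#' @param anchor_gene_id,partner_gene_id,variant_id Identifiers.
#' @param r_by_genotype Named numeric vector `c(RR=, RM=, MM=)`, each in
#'   (-1, 1).
#' @return A list of class `coex_spec`.
#' @export
coex_spec <- function(anchor_gene_id, partner_gene_id, variant_id,
                      r_by_genotype = c(RR = 0.6, RM = 0.1, MM = -0.4)) {
  if (!all(c("RR", "RM", "MM") %in% names(r_by_genotype))) {
    rlang::abort("r_by_genotype must name RR, RM and MM")
  }
  if (any(abs(r_by_genotype) >= 1)) {
    rlang::abort("|r| must be < 1 in every genotype stratum")
  }
  structure(list(anchor_gene_id = anchor_gene_id,
                 partner_gene_id = partner_gene_id,
                 variant_id = variant_id,
                 r_by_genotype = r_by_genotype[c("RR", "RM", "MM")]),
            class = "coex_spec")
}

#' SNP / methylation / expression mediation chain
#'
#' Declares the generative factorisation for one variant-CpG-gene triple:
#' `"SNP->M->E"` (genotype drives methylation which drives expression),
#' `"SNP->E->M"` (the reverse), or `"independent"`. `b1` is the slope of
#' the first edge, `b2` of the second.
#'
#' @param variant_id,cpg_id,gene_id Identifiers.
#' @param chain One of `"SNP->M->E"`, `"SNP->E->M"`, `"independent"`.
#' @param b1,b2 Edge effect sizes.
#' @param noise_sd Per-node residual SD.
#' @return A list of class `mediation_spec`.
#' @export
mediation_spec <- function(variant_id, cpg_id, gene_id,
                           chain = c("SNP->M->E", "SNP->E->M", "independent"),
                           b1 = 1.2, b2 = 0.6, noise_sd = 1) {
  chain <- match.arg(chain)
  if (identical(cpg_id, gene_id)) {
    rlang::abort("cyclic chain: cpg_id and gene_id must differ")
  }
  structure(list(variant_id = variant_id, cpg_id = cpg_id, gene_id = gene_id,
                 chain = chain, b1 = b1, b2 = b2, noise_sd = noise_sd),
            class = "mediation_spec")
}

#' Simulate HWE genotype dosages on a toy genome
#'
#' Each variant gets a minor-allele frequency drawn uniformly from the
#' spec's `maf_range` and minor-allele counts sampled under
#' Hardy-Weinberg equilibrium (binomial with two trials). Variants are
#' placed at distinct uniform positions on a single chromosome.
#'
#' @param spec A [sim_spec()].
#' @return A [geno_matrix()].
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .set_sim_seed(spec, "geno")
  n <- spec$n_individuals
  v <- spec$n_variants
  maf <- stats::runif(v, spec$maf_range[1], spec$maf_range[2])
  dosage <- vapply(maf, function(p) stats::rbinom(n, 2L, p), numeric(n))
  pos <- sort(sample.int(spec$genome_length, v))
  map <- tibble::tibble(
    variant_id = sprintf("var_%04d", seq_len(v)),
    chrom = "chr1", pos = pos, ref = "A", alt = "G", maf = maf)
  dimnames(dosage) <- list(sprintf("ind_%03d", seq_len(n)), map$variant_id)
  geno_matrix(dosage, map)
}

# Replace a variant's dosages with an exact-HWE permutation at a given MAF
# (genotype counts fixed at rounded HWE proportions, order randomised).
# Used to guarantee well-filled homozygous-minor strata for the
# co-expression arm of the default fixture.
set_exact_hwe_variant <- function(geno, variant_id, maf = 0.5) {
  n <- nrow(geno$dosage)
  n_mm <- round(n * maf^2)
  n_rm <- round(n * 2 * maf * (1 - maf))
  n_rr <- n - n_mm - n_rm
  g <- sample(rep(c(0, 1, 2), times = c(n_rr, n_rm, n_mm)))
  geno$dosage[, variant_id] <- g
  geno$map$maf[geno$map$variant_id == variant_id] <- maf
  geno
}

#' Simulate condition-wise expression with planted cis effects
#'
#' Each phenotype is generated as `intercept + b * genotype +
#' sum(loading_f * factor_f) + noise`, per condition. Latent confounder
#' factors are global (shared across genes within a condition), so PC
#' correction is genuinely needed downstream; background genes carry
#' confounder signal but no genetic effect. Planted genes get a TSS
#' placed within 50 kb of their variant.
#'
#' @param geno A [geno_matrix()].
#' @param effects List of [planted_effect()]s.
#' @param n_background_genes Number of genes with no genetic effect.
#' @param n_confounders Number of global latent factors.
#' @param spec The [sim_spec()] used for `geno`.
#' @param confounder_sd SD of random confounder loadings.
#' @return Named list of [pheno_matrix()], one per condition.
#' @export
simulate_expression <- function(geno, effects, n_background_genes = 30,
                                n_confounders = 2, spec,
                                confounder_sd = 0.5) {
  stopifnot(inherits(spec, "sim_spec"))
  .set_sim_seed(spec, "expr")
  n <- nrow(geno$dosage)
  keys <- vapply(effects, function(e) paste(e$variant_id, e$phenotype_id),
                 character(1))
  if (anyDuplicated(keys) > 0) {
    rlang::abort("duplicate (variant, phenotype) planting")
  }
  for (e in effects) {
    if (!e$variant_id %in% geno$map$variant_id) {
      rlang::abort(paste0("unknown variant id: ", e$variant_id))
    }
    if (!all(names(e$beta) %in% spec$conditions) || is.null(names(e$beta))) {
      rlang::abort("planted_effect beta must be named by condition")
    }
  }
  planted_ids <- vapply(effects, `[[`, character(1), "phenotype_id")
  bg_ids <- if (n_background_genes > 0) {
    sprintf("bg_gene_%03d", seq_len(n_background_genes))
  } else character(0)
  all_ids <- c(planted_ids, bg_ids)
  # positions: planted near their variant, background uniform
  vpos <- stats::setNames(geno$map$pos, geno$map$variant_id)
  tss <- c(
    vapply(effects, function(e) {
      min(max(1, vpos[[e$variant_id]] + sample(-5e4:5e4, 1)),
          spec$genome_length)
    }, numeric(1)),
    if (n_background_genes > 0) sample.int(spec$genome_length,
                                           n_background_genes) else numeric(0))
  map <- tibble::tibble(
    phenotype_id = all_ids, chrom = "chr1", pos = tss,
    strand = sample(c("+", "-"), length(all_ids), replace = TRUE),
    group_id = all_ids)
  # fixed loadings per phenotype (shared across conditions)
  loadings <- matrix(stats::rnorm(length(all_ids) * n_confounders,
                                  sd = confounder_sd),
                     nrow = length(all_ids), ncol = max(n_confounders, 0))
  if (n_confounders > 0) {
    for (i in seq_along(effects)) {
      if (!is.null(effects[[i]]$confounder_loadings)) {
        loadings[i, ] <- effects[[i]]$confounder_loadings
      }
    }
  }
  out <- list()
  for (cond in spec$conditions) {
    latent <- if (n_confounders > 0) {
      matrix(stats::rnorm(n * n_confounders), nrow = n)
    } else matrix(0, n, 0)
    vals <- matrix(0, n, length(all_ids),
                   dimnames = list(rownames(geno$dosage), all_ids))
    for (i in seq_along(effects)) {
      e <- effects[[i]]
      b <- if (cond %in% names(e$beta)) e$beta[[cond]] else 0
      noise <- if (e$noise_sd > 0) stats::rnorm(n, sd = e$noise_sd) else 0
      vals[, i] <- b * geno$dosage[, e$variant_id] +
        (if (n_confounders > 0) drop(latent %*% loadings[i, ]) else 0) + noise
    }
    for (j in seq_along(bg_ids)) {
      i <- length(effects) + j
      vals[, i] <- (if (n_confounders > 0) drop(latent %*% loadings[i, ])
                    else 0) + stats::rnorm(n)
    }
    out[[cond]] <- pheno_matrix(vals, map)
  }
  out
}

#' Simulate genotype-dependent pairwise co-expression
#'
#' Within each genotype stratum g of the spec's variant, the partner gene
#' is generated as `r_g * anchor + sqrt(1 - r_g^2) * noise`, so the
#' population correlation in stratum g equals the target `r_g`. Anchors
#' are standard normal and shared across specs naming the same anchor.
#'
#' @param geno A [geno_matrix()].
#' @param coex_specs List of [coex_spec()]s.
#' @param spec The [sim_spec()].
#' @param n_background_genes Extra independent standard-normal genes.
#' @return A [pheno_matrix()] holding anchors, partners and background.
#' @export
simulate_coexpression <- function(geno, coex_specs, spec,
                                  n_background_genes = 0) {
  stopifnot(inherits(spec, "sim_spec"))
  .set_sim_seed(spec, "coex")
  n <- nrow(geno$dosage)
  keys <- vapply(coex_specs, function(s)
    paste(s$anchor_gene_id, s$partner_gene_id, s$variant_id), character(1))
  if (anyDuplicated(keys) > 0) rlang::abort("duplicate co-expression spec")
  anchor_ids <- unique(vapply(coex_specs, `[[`, character(1),
                              "anchor_gene_id"))
  partner_ids <- vapply(coex_specs, `[[`, character(1), "partner_gene_id")
  if (any(partner_ids %in% anchor_ids)) {
    rlang::abort("a partner gene may not also be an anchor")
  }
  anchors <- matrix(stats::rnorm(n * length(anchor_ids)), nrow = n,
                    dimnames = list(rownames(geno$dosage), anchor_ids))
  partners <- matrix(NA_real_, n, length(coex_specs),
                     dimnames = list(rownames(geno$dosage), partner_ids))
  vpos <- stats::setNames(geno$map$pos, geno$map$variant_id)
  for (i in seq_along(coex_specs)) {
    s <- coex_specs[[i]]
    if (!s$variant_id %in% geno$map$variant_id) {
      rlang::abort(paste0("unknown variant id: ", s$variant_id))
    }
    g <- round(geno$dosage[, s$variant_id])
    a <- anchors[, s$anchor_gene_id]
    for (k in 0:2) {
      idx <- which(g == k)
      if (length(idx) == 0) next  # stratum absent in this panel
      r <- s$r_by_genotype[[c("RR", "RM", "MM")[k + 1]]]
      partners[idx, i] <- r * a[idx] +
        sqrt(1 - r^2) * stats::rnorm(length(idx))
    }
  }
  bg_ids <- if (n_background_genes > 0) {
    sprintf("coexbg_%03d", seq_len(n_background_genes))
  } else character(0)
  bg <- if (n_background_genes > 0) {
    matrix(stats::rnorm(n * n_background_genes), nrow = n,
           dimnames = list(rownames(geno$dosage), bg_ids))
  } else NULL
  vals <- cbind(anchors, partners, bg)
  ids <- colnames(vals)
  anchor_pos <- vapply(anchor_ids, function(id) {
    v <- coex_specs[[match(id, vapply(coex_specs, `[[`, character(1),
                                      "anchor_gene_id"))]]$variant_id
    min(max(1, vpos[[v]] + sample(-5e4:5e4, 1)), spec$genome_length)
  }, numeric(1))
  other_n <- length(ids) - length(anchor_ids)
  map <- tibble::tibble(
    phenotype_id = ids, chrom = "chr1",
    pos = c(anchor_pos, sample.int(spec$genome_length, other_n)),
    strand = "+", group_id = ids)
  pheno_matrix(vals, map)
}

#' Simulate a gene module with genotype-dependent connectivity
#'
#' All module genes load on one latent factor whose coupling depends on
#' the genotype stratum: within stratum g each gene is
#' `sqrt(rho_g) * factor + sqrt(1 - rho_g) * noise`, giving pairwise
#' correlation `rho_g` between any two module genes. Used to exercise the
#' pathway differential-connectivity test.
#'
#' @param geno A [geno_matrix()].
#' @param variant_id Stratifying variant.
#' @param rho_by_genotype Named vector `c(RR=, RM=, MM=)` of pairwise
#'   correlations in `[0, 1)`.
#' @param n_genes Module size.
#' @param spec The [sim_spec()].
#' @param prefix Phenotype-id prefix.
#' @return A [pheno_matrix()].
#' @export
simulate_module <- function(geno, variant_id,
                            rho_by_genotype = c(RR = 0.7, RM = 0.35, MM = 0),
                            n_genes = 8, spec, prefix = "mod") {
  stopifnot(inherits(spec, "sim_spec"))
  if (any(rho_by_genotype < 0 | rho_by_genotype >= 1)) {
    rlang::abort("rho_by_genotype entries must be in [0, 1)")
  }
  .set_sim_seed(spec, "module")
  n <- nrow(geno$dosage)
  g <- round(geno$dosage[, variant_id])
  f <- stats::rnorm(n)
  vals <- matrix(NA_real_, n, n_genes,
                 dimnames = list(rownames(geno$dosage),
                                 sprintf("%s_gene_%02d", prefix,
                                         seq_len(n_genes))))
  for (k in 0:2) {
    idx <- which(g == k)
    if (length(idx) == 0) next
    rho <- rho_by_genotype[[c("RR", "RM", "MM")[k + 1]]]
    for (j in seq_len(n_genes)) {
      vals[idx, j] <- sqrt(rho) * f[idx] +
        sqrt(1 - rho) * stats::rnorm(length(idx))
    }
  }
  map <- tibble::tibble(phenotype_id = colnames(vals), chrom = "chr1",
                        pos = sample.int(spec$genome_length, n_genes),
                        strand = "+", group_id = colnames(vals))
  pheno_matrix(vals, map)
}

#' Simulate SNP / CpG-methylation / expression mediation chains
#'
#' Generates data exactly according to each chain's declared
#' factorisation. Methylation is generated on a latent Gaussian scale and
#' mapped through the logistic function to the (0, 1) beta-value range,
#' which keeps linear mQTL mapping well behaved.
#'
#' @param geno A [geno_matrix()].
#' @param mediation_specs List of [mediation_spec()]s.
#' @param spec The [sim_spec()].
#' @return List with elements `meth` and `expr`, both [pheno_matrix()].
#' @export
simulate_methylation <- function(geno, mediation_specs, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .set_sim_seed(spec, "meth")
  n <- nrow(geno$dosage)
  m <- length(mediation_specs)
  cpg_ids <- vapply(mediation_specs, `[[`, character(1), "cpg_id")
  gene_ids <- vapply(mediation_specs, `[[`, character(1), "gene_id")
  if (anyDuplicated(cpg_ids) > 0 || anyDuplicated(gene_ids) > 0) {
    rlang::abort("cpg and gene ids must be unique across mediation specs")
  }
  meth <- matrix(NA_real_, n, m,
                 dimnames = list(rownames(geno$dosage), cpg_ids))
  expr <- matrix(NA_real_, n, m,
                 dimnames = list(rownames(geno$dosage), gene_ids))
  vpos <- stats::setNames(geno$map$pos, geno$map$variant_id)
  pos_cpg <- numeric(m); pos_gene <- numeric(m)
  for (i in seq_len(m)) {
    s <- mediation_specs[[i]]
    g <- geno$dosage[, s$variant_id] - mean(geno$dosage[, s$variant_id])
    e1 <- stats::rnorm(n, sd = s$noise_sd)
    e2 <- stats::rnorm(n, sd = s$noise_sd)
    if (s$chain == "SNP->M->E") {
      m_lat <- s$b1 * g + e1
      expr[, i] <- s$b2 * m_lat + e2
    } else if (s$chain == "SNP->E->M") {
      expr[, i] <- s$b1 * g + e1
      m_lat <- s$b2 * expr[, i] + e2
    } else {
      m_lat <- e1
      expr[, i] <- e2
    }
    meth[, i] <- stats::plogis(m_lat)
    pos_cpg[i] <- min(max(1, vpos[[s$variant_id]] + sample(-2e4:2e4, 1)),
                      spec$genome_length)
    pos_gene[i] <- min(max(1, vpos[[s$variant_id]] + sample(-5e4:5e4, 1)),
                       spec$genome_length)
  }
  list(
    meth = pheno_matrix(meth, tibble::tibble(
      phenotype_id = cpg_ids, chrom = "chr1", pos = pos_cpg,
      strand = "+", group_id = cpg_ids)),
    expr = pheno_matrix(expr, tibble::tibble(
      phenotype_id = gene_ids, chrom = "chr1", pos = pos_gene,
      strand = "+", group_id = gene_ids)))
}

#' Simulate GWAS summary statistics from the genotype panel
#'
#' A quantitative trait is generated from one causal variant; every
#' variant is then regressed on the trait one at a time, yielding the
#' per-variant beta, se and p of a harmonised GWAS summary table. Signal
#' decays with LD to the causal variant (for an LD-free panel, only the
#' causal variant carries signal).
#'
#' @param geno A [geno_matrix()].
#' @param causal_variant Variant id (or `NULL` for a pure-null trait).
#' @param effect Trait slope per minor allele at the causal variant.
#' @param spec The [sim_spec()].
#' @param noise_sd Trait residual SD.
#' @return Tibble: variant_id, chrom, pos, ref, alt, maf, beta, se, p, n.
#' @export
simulate_gwas_summary <- function(geno, causal_variant, effect, spec,
                                  noise_sd = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  .set_sim_seed(spec, "gwas")
  n <- nrow(geno$dosage)
  if (!is.null(causal_variant) &&
      !causal_variant %in% geno$map$variant_id) {
    rlang::abort(paste0("unknown causal variant: ", causal_variant))
  }
  y <- stats::rnorm(n, sd = noise_sd)
  if (!is.null(causal_variant) && effect != 0) {
    y <- y + effect * geno$dosage[, causal_variant]
  }
  fit <- fast_marginal_assoc(y, geno$dosage)
  dplyr::bind_cols(geno$map,
                   tibble::tibble(beta = fit$b, se = fit$se, p = fit$p,
                                  n = n))
}

#' Simulate annotation intervals enriched for a SNP set
#'
#' Places BED intervals (0-based half-open) around SNP positions so that
#' the enriched SNP set overlaps the target feature class at
#' approximately `fold` times the background coverage rate; all other
#' classes, and all other SNPs, are covered at the background rate.
#'
#' @param spec The [sim_spec()] (supplies genome length).
#' @param snp_positions 1-based positions of all SNPs under study.
#' @param enriched_positions Positions of the SNP set to enrich.
#' @param feature_classes Character vector of class names.
#' @param enriched_class The class carrying the planted enrichment.
#' @param fold Planted fold enrichment (>= 1).
#' @param bg_rate Background per-SNP coverage probability.
#' @param halfwidth Interval half-width in bp around a covered SNP.
#' @return Tibble BED: chrom, start, end, name.
#' @export
simulate_annotations <- function(spec, snp_positions, enriched_positions,
                                 feature_classes = c("enhancer", "promoter",
                                                     "quiescent"),
                                 enriched_class = feature_classes[1],
                                 fold = 4, bg_rate = 0.1, halfwidth = 50) {
  stopifnot(inherits(spec, "sim_spec"))
  if (fold < 1) rlang::abort("fold must be >= 1")
  if (fold * bg_rate > 1) {
    rlang::abort("fold * bg_rate exceeds 1; lower bg_rate or fold")
  }
  if (any(snp_positions < 1 | snp_positions > spec$genome_length)) {
    rlang::abort("snp positions outside genome bounds")
  }
  .set_sim_seed(spec, "annot")
  is_enriched <- snp_positions %in% enriched_positions
  rows <- list()
  for (cls in feature_classes) {
    p_cover <- rep(bg_rate, length(snp_positions))
    if (cls == enriched_class) p_cover[is_enriched] <- fold * bg_rate
    covered <- stats::runif(length(snp_positions)) < p_cover
    if (!any(covered)) next
    pos <- snp_positions[covered]
    rows[[cls]] <- tibble::tibble(
      chrom = "chr1",
      start = pmax(0, pos - 1 - halfwidth),
      end = pmin(spec$genome_length, pos + halfwidth),
      name = cls)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$start, .data$end)
}
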