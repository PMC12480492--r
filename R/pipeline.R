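# Top-level orchestration: configuration, the default synthetic study
# fixture, and the end-to-end pipeline driver.

#' Pipeline configuration
#'
#' Collects the window sizes and thresholds used across the stages. Every
#' threshold is validated against its legal range; the seed is mandatory
#' because several stages are stochastic.
#'
#' @param gene_window_bp,transcript_window_bp Cis half-windows (genes and
#'   CpGs 1e6, transcripts 1e5 by convention).
#' @param maf_min MAF floor for tested variants.
#' @param fdr Discovery FDR threshold.
#' @param fg_fdr Enrichment foreground FDR threshold.
#' @param nonsig_floor Nominal-p floor for context specificity.
#' @param alpha_interaction coExQTL interaction threshold (on BH-adjusted
#'   p).
#' @param pph4 Colocalization shared-variant posterior threshold.
#' @param n_perm Permutations for the permutation pass and MDC test.
#' @param seed Integer seed.
#' @param conditions Condition labels, naive first.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_window_bp = 1e6, transcript_window_bp = 1e5,
                            maf_min = 0.04, fdr = 0.01, fg_fdr = 0.001,
                            nonsig_floor = 0.05, alpha_interaction = 1e-6,
                            pph4 = 0.8, n_perm = 1000, seed = 1L,
                            conditions = c("UT", "LPS", "IFN")) {
  chk01 <- function(x, nm) {
    if (x <= 0 || x >= 1) rlang::abort(paste0(nm, " must be in (0, 1)"))
  }
  chk01(fdr, "fdr"); chk01(fg_fdr, "fg_fdr"); chk01(pph4, "pph4")
  chk01(nonsig_floor, "nonsig_floor")
  chk01(alpha_interaction, "alpha_interaction")
  if (maf_min < 0 || maf_min > 0.5) rlang::abort("maf_min outside [0, 0.5]")
  if (gene_window_bp <= 0 || transcript_window_bp <= 0) {
    rlang::abort("windows must be positive")
  }
  if (transcript_window_bp > gene_window_bp) {
    rlang::warn("transcript window larger than gene window (unusual)")
  }
  if (n_perm < 100) rlang::abort("n_perm must be >= 100")
  structure(list(gene_window_bp = gene_window_bp,
                 transcript_window_bp = transcript_window_bp,
                 maf_min = maf_min, fdr = fdr, fg_fdr = fg_fdr,
                 nonsig_floor = nonsig_floor,
                 alpha_interaction = alpha_interaction, pph4 = pph4,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 conditions = conditions),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The file representation round-trips losslessly: reading a written
#' config reproduces the validated object.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly; `read_pipeline_config()` returns the config.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Default synthetic study fixture
#'
#' Builds the full multi-condition fixture the pipeline and its
#' simulation studies run on: HWE genotypes, condition-wise expression
#' with planted condition-specific / shared / sign-discordant
#' (differential) cis effects plus latent confounders, a genotype-
#' dependent co-expression panel (high-MAF exact-HWE variants so the
#' homozygous-minor strata are well filled), SNP-CpG-gene mediation
#' chains, GWAS summary statistics with a shared and a distinct causal
#' variant, fold-enriched annotation intervals, and gene sets including
#' one genotype-rewired module.
#'
#' @param seed Integer seed; determines everything.
#' @param n_individuals Cohort size (paired across conditions).
#' @param n_variants Variants on the toy genome.
#' @param qtl_beta Planted cis slope per minor allele.
#' @param n_specific,n_shared,n_differential Planted QTL counts per
#'   context class (`n_specific` is split across conditions).
#' @param n_coex Planted co-expression pairs.
#' @param coex_r Stratum correlation targets for planted pairs.
#' @param n_chains_me,n_chains_em,n_chains_ind Mediation chain counts.
#' @param annot_fold Planted annotation fold enrichment.
#' @return List: `spec`, `geno`, `expr` (per condition), `truth`,
#'   `coex_specs`, `coex_expr`, `module_expr`, `module_variant`,
#'   `mediation_specs`, `meth`, `meth_expr`, `gwas_shared`,
#'   `gwas_distinct`, `gwas_causal`, `features`, `fg_variants`,
#'   `gene_sets`.
#' @export
simulate_study_fixture <- function(seed = 1L, n_individuals = 280,
                                   n_variants = 300, qtl_beta = 0.8,
                                   n_specific = 12, n_shared = 8,
                                   n_differential = 8, n_coex = 10,
                                   coex_r = c(RR = 0.6, RM = 0.1,
                                              MM = -0.4),
                                   n_chains_me = 12, n_chains_em = 4,
                                   n_chains_ind = 4, annot_fold = 4) {
  spec <- sim_spec(n_individuals = n_individuals, n_variants = n_variants,
                   seed = seed)
  geno <- simulate_genotypes(spec)
  conds <- spec$conditions
  # planted QTL variants: decent MAF for power, distinct per effect
  set.seed(spec$seed + 7L)
  n_qtl <- n_specific + n_shared + n_differential
  pool <- geno$map$variant_id[geno$map$maf >= 0.2]
  qtl_vars <- sample(pool, n_qtl)
  truth <- list(); effects <- list(); i <- 0
  add <- function(variant, beta, label) {
    i <<- i + 1
    pid <- sprintf("qtl_gene_%02d", i)
    effects[[i]] <<- planted_effect(variant, pid, beta = beta)
    truth[[i]] <<- tibble::tibble(phenotype_id = pid, variant_id = variant,
                                  label = label)
  }
  per_cond <- n_specific %/% length(conds)
  k <- 0
  for (cond in conds) {
    for (j in seq_len(per_cond)) {
      k <- k + 1
      beta <- stats::setNames(rep(0, length(conds)), conds)
      beta[cond] <- qtl_beta
      add(qtl_vars[k], beta, paste0("condition-specific:", cond))
    }
  }
  for (j in seq_len(n_shared)) {
    k <- k + 1
    add(qtl_vars[k], stats::setNames(rep(qtl_beta, length(conds)), conds),
        "shared")
  }
  for (j in seq_len(n_differential)) {
    k <- k + 1
    beta <- stats::setNames(rep(-qtl_beta, length(conds)), conds)
    beta[conds[1]] <- qtl_beta
    add(qtl_vars[k], beta, "differential")
  }
  expr <- simulate_expression(geno, effects, n_background_genes = 30,
                              n_confounders = 2, spec = spec)
  # co-expression arm: exact-HWE maf-0.5 variants so MM strata are filled
  set.seed(spec$seed + 13L)
  coex_vars <- sample(setdiff(geno$map$variant_id, qtl_vars),
                      n_coex + 1)
  for (v in coex_vars) geno <- set_exact_hwe_variant(geno, v, maf = 0.5)
  coex_specs <- lapply(seq_len(n_coex), function(j) {
    coex_spec(sprintf("anchor_%02d", j), sprintf("partner_%02d", j),
              coex_vars[j], r_by_genotype = coex_r)
  })
  coex_expr <- simulate_coexpression(geno, coex_specs, spec,
                                     n_background_genes = 20)
  module_variant <- coex_vars[n_coex + 1]
  module_expr <- simulate_module(geno, module_variant,
                                 rho_by_genotype = c(RR = 0.7, RM = 0.35,
                                                     MM = 0),
                                 n_genes = 8, spec = spec)
  # mediation chains
  set.seed(spec$seed + 17L)
  med_vars <- sample(setdiff(geno$map$variant_id,
                             c(qtl_vars, coex_vars)),
                     n_chains_me + n_chains_em + n_chains_ind)
  chains <- rep(c("SNP->M->E", "SNP->E->M", "independent"),
                c(n_chains_me, n_chains_em, n_chains_ind))
  mediation_specs <- lapply(seq_along(med_vars), function(j) {
    mediation_spec(med_vars[j], sprintf("cpg_%02d", j),
                   sprintf("med_gene_%02d", j), chain = chains[j])
  })
  med <- simulate_methylation(geno, mediation_specs, spec)
  # GWAS: shared causal variant with the first planted QTL, and a
  # distinct unrelated causal variant
  gwas_causal <- qtl_vars[1]
  gwas_shared <- simulate_gwas_summary(geno, gwas_causal, effect = 0.8,
                                       spec = spec)
  spec2 <- spec; spec2$seed <- spec$seed + 1L
  # the distinct causal variant must fall inside the eGene's cis window
  # (otherwise the two-signal hypothesis is untestable by construction)
  causal_pos <- geno$map$pos[geno$map$variant_id == gwas_causal]
  cand <- geno$map$variant_id[
    abs(geno$map$pos - causal_pos) > 1e5 &
      abs(geno$map$pos - causal_pos) < 5e5 &
      !geno$map$variant_id %in% c(qtl_vars, coex_vars) &
      geno$map$maf >= 0.2]
  if (length(cand) == 0) {  # sparse panel: take the nearest non-planted
    free <- geno$map[!geno$map$variant_id %in%
                       c(qtl_vars, coex_vars, gwas_causal), ]
    cand <- free$variant_id[order(abs(free$pos - causal_pos))]
  }
  distinct_var <- cand[1]
  gwas_distinct <- simulate_gwas_summary(geno, distinct_var, effect = 0.8,
                                         spec = spec2)
  # annotations enriched for the planted QTL variants
  fg_variants <- qtl_vars
  features <- simulate_annotations(
    spec, snp_positions = geno$map$pos,
    enriched_positions =
      geno$map$pos[geno$map$variant_id %in% fg_variants],
    fold = annot_fold, bg_rate = 0.1)
  # gene sets: the rewired module plus random sets over the coex genes
  set.seed(spec$seed + 23L)
  universe <- colnames(coex_expr$values)
  gene_sets <- c(
    list(rewired_module = colnames(module_expr$values)),
    stats::setNames(lapply(1:4, function(j) sample(universe, 8)),
                    sprintf("random_set_%d", 1:4)))
  list(spec = spec, geno = geno, expr = expr,
       truth = dplyr::bind_rows(truth), coex_specs = coex_specs,
       coex_expr = coex_expr, module_expr = module_expr,
       module_variant = module_variant,
       mediation_specs = mediation_specs, meth = med$meth,
       meth_expr = med$expr, gwas_shared = gwas_shared,
       gwas_distinct = gwas_distinct, gwas_causal = gwas_causal,
       features = features, fg_variants = fg_variants,
       gene_sets = gene_sets)
}

#' Run the full pipeline on a study fixture
#'
#' Executes the stages in order: normalisation, PC-count selection, cis
#' nominal mapping per condition, permutation pass, BH FDR, conditional
#' pass on significant phenotypes, lead-SNP clumping, context
#' classification, GWAS colocalization and MR, methylation-expression
#' correlation and Steiger directionality, SNP feature enrichment,
#' coExQTL detection, and the pathway differential-connectivity test.
#' Every stage's row counts are logged; output is deterministic given
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param fixture A fixture list from [simulate_study_fixture()] (built
#'   from `config$seed` when `NULL`).
#' @return List of class `qtl_pipeline`: stage outputs plus a `log`
#'   tibble.
#' @export
run_pipeline <- function(config = pipeline_config(), fixture = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(fixture)) fixture <- simulate_study_fixture(config$seed)
  log <- list()
  note <- function(stage, n, detail = "") {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, n_rows = n,
                                              detail = detail)
  }
  run_stage <- function(stage, expr_) {
    tryCatch(expr_, error = function(e) {
      rlang::abort(paste0("stage '", stage, "' failed: ",
                          conditionMessage(e)))
    })
  }
  conds <- config$conditions
  # normalise (simulated values are continuous: rank-INT per phenotype)
  norm <- run_stage("normalize", lapply(fixture$expr, function(pm) {
    vals <- apply(pm$values, 2, rank_inverse_normal)
    rownames(vals) <- rownames(pm$values)
    pheno_matrix(vals, pm$map)
  }))
  note("normalize", sum(vapply(norm, function(p) ncol(p$values),
                               numeric(1))))
  # PC selection on the naive condition
  pcsel <- run_stage("select_pcs", select_pc_count(
    norm[[conds[1]]], fixture$geno, k_grid = 0:5,
    window_bp = config$gene_window_bp, maf_min = config$maf_min))
  note("select_pcs", pcsel$k, sprintf("k = %d", pcsel$k))
  pcs <- lapply(norm, function(pm) {
    if (pcsel$k == 0) NULL else
      stats::prcomp(pm$values)$x[, seq_len(pcsel$k), drop = FALSE]
  })
  # nominal + permutation + FDR per condition
  nominal <- list(); perm <- list()
  for (cond in conds) {
    nm <- run_stage("map_cis_nominal", map_cis_nominal(
      norm[[cond]], fixture$geno, window_bp = config$gene_window_bp,
      covariates = pcs[[cond]], maf_min = config$maf_min,
      condition = cond))
    pm <- run_stage("permutation_pass", permutation_pass(
      norm[[cond]], fixture$geno, window_bp = config$gene_window_bp,
      covariates = pcs[[cond]], n_perm = config$n_perm,
      maf_min = config$maf_min, seed = config$seed + match(cond, conds)))
    pm$fdr <- fdr_bh(ifelse(is.na(pm$p_beta), pm$p_empirical, pm$p_beta))
    pm$condition <- cond
    nominal[[cond]] <- nm
    perm[[cond]] <- pm
  }
  nominal_all <- dplyr::bind_rows(nominal)
  perm_all <- dplyr::bind_rows(perm)
  note("map_cis_nominal", nrow(nominal_all))
  note("permutation_pass", nrow(perm_all),
       sprintf("n_perm = %d", config$n_perm))
  # per-pair records for context classification: each phenotype's best
  # variant across conditions, then tested in every condition
  best <- dplyr::slice_min(dplyr::group_by(perm_all, .data$phenotype_id),
                           .data$p_nominal_best, n = 1, with_ties = FALSE)
  best <- dplyr::ungroup(best)[, c("phenotype_id", "variant_id")]
  pair_records <- dplyr::inner_join(
    nominal_all, best, by = c("phenotype_id", "variant_id"))
  # significance per condition comes from the selection-corrected
  # permutation fdr, not from the nominal p at the selected variant
  pair_records <- dplyr::left_join(
    pair_records,
    perm_all[, c("phenotype_id", "condition", "fdr")],
    by = c("phenotype_id", "condition"))
  pair_records$fdr[is.na(pair_records$fdr)] <- 1
  context <- run_stage("classify_context", classify_context(
    pair_records, sig_fdr = config$fdr,
    nonsig_floor = config$nonsig_floor, conditions = conds))
  note("classify_context", nrow(context))
  # conditional pass + clumping on significant naive phenotypes
  sig_ph <- perm[[conds[1]]]$phenotype_id[perm[[conds[1]]]$fdr < config$fdr]
  norm_sig <- norm[[conds[1]]]
  keepj <- match(sig_ph, norm_sig$map$phenotype_id)
  cond_recs <- if (length(keepj) > 0) {
    sub <- pheno_matrix(norm_sig$values[, keepj, drop = FALSE],
                        norm_sig$map[keepj, ])
    run_stage("conditional_pass", conditional_pass(
      sub, fixture$geno, window_bp = config$gene_window_bp,
      covariates = pcs[[conds[1]]], p_threshold = 1e-4,
      maf_min = config$maf_min))
  } else tibble::tibble()
  note("conditional_pass", nrow(cond_recs))
  leads <- run_stage("ld_clump", ld_clump(
    dplyr::filter(nominal[[conds[1]]],
                  .data$p_nominal < config$fdr), fixture$geno))
  note("ld_clump", nrow(leads))
  # colocalization of the naive eQTL signal with the GWAS traits
  egene <- fixture$truth$phenotype_id[
    fixture$truth$variant_id == fixture$gwas_causal][1]
  eqtl_stats <- dplyr::select(
    dplyr::filter(nominal[[conds[1]]], .data$phenotype_id == egene),
    "variant_id", beta = "b", "se")
  coloc_shared <- run_stage("coloc", coloc_abf(
    eqtl_stats, dplyr::select(fixture$gwas_shared, "variant_id",
                              "beta", "se")))
  coloc_distinct <- run_stage("coloc", coloc_abf(
    eqtl_stats, dplyr::select(fixture$gwas_distinct, "variant_id",
                              "beta", "se")))
  note("coloc", 2, sprintf("PPH4 shared = %.3f",
                           coloc_shared$posteriors[["PPH4"]]))
  # MR: instruments = clumped significant eQTL variants for the eGene
  instr <- dplyr::filter(eqtl_stats,
                         .data$variant_id %in% leads$variant_id)
  mr <- if (nrow(instr) >= 1) {
    run_stage("mr", mr_estimate(
      instr, dplyr::select(fixture$gwas_shared, "variant_id", "beta",
                           "se"),
      method = "wald"))
  } else NULL
  note("mr", if (is.null(mr)) 0 else nrow(mr$instruments))
  # methylation arm: correlation, coloc pairing implicit, Steiger
  med_pairs <- tibble::tibble(
    cpg_id = colnames(fixture$meth$values),
    gene_id = colnames(fixture$meth_expr$values),
    variant_id = vapply(fixture$mediation_specs, `[[`, character(1),
                        "variant_id"))
  me_rel <- run_stage("meth_expr_relation", meth_expr_relation(
    fixture$meth, fixture$meth_expr, med_pairs, geno = fixture$geno))
  r_sm <- vapply(seq_len(nrow(med_pairs)), function(i) {
    stats::cor(fixture$geno$dosage[, med_pairs$variant_id[i]],
               fixture$meth$values[, med_pairs$cpg_id[i]])
  }, numeric(1))
  r_se <- vapply(seq_len(nrow(med_pairs)), function(i) {
    stats::cor(fixture$geno$dosage[, med_pairs$variant_id[i]],
               fixture$meth_expr$values[, med_pairs$gene_id[i]])
  }, numeric(1))
  n_ind <- nrow(fixture$geno$dosage)
  steiger <- run_stage("steiger", steiger_direction(
    r_sm, r_se, n_ind, n_ind))
  steiger$variant_id <- med_pairs$variant_id
  note("steiger", nrow(steiger))
  # enrichment of planted-QTL foreground against the annotations
  fgbg <- tibble::tibble(
    phenotype_id = "all",
    variant_id = fixture$geno$map$variant_id,
    set = ifelse(fixture$geno$map$variant_id %in% fixture$fg_variants,
                 "fg", "bg"))
  enr <- run_stage("enrichment", snp_enrichment(
    fgbg, fixture$geno$map, fixture$features))
  note("enrichment", nrow(enr))
  # coExQTL detection on the planted panel
  coex <- run_stage("coexqtl", dplyr::bind_rows(lapply(
    fixture$coex_specs, function(s) {
      res <- detect_coexqtl(s$anchor_gene_id, s$variant_id,
                            fixture$coex_expr, fixture$geno,
                            alpha = config$alpha_interaction)
      dplyr::filter(res, .data$partner == s$partner_gene_id)
    })))
  note("coexqtl", nrow(coex))
  # pathway differential connectivity on the rewired module
  strata <- stratify(fixture$geno, fixture$module_variant)
  pdc <- run_stage("pdc", pdc_test(
    fixture$module_expr, strata, fixture$gene_sets["rewired_module"],
    n_perm = min(config$n_perm, 500), gene_filter = TRUE,
    seed = config$seed + 101))
  note("pdc", nrow(pdc))
  structure(list(
    config = config, pc_selection = pcsel, nominal = nominal_all,
    permutation = perm_all, context = context, conditional = cond_recs,
    leads = leads, coloc_shared = coloc_shared,
    coloc_distinct = coloc_distinct, mr = mr, meth_expr = me_rel,
    steiger = steiger, enrichment = enr, coexqtl = coex, pdc = pdc,
    log = dplyr::bind_rows(log)), class = "qtl_pipeline")
}

#' @export
print.qtl_pipeline <- function(x, ...) {
  cat("<qtl_pipeline> stages:\n")
  print(as.data.frame(x$log), row.names = FALSE)
  invisible(x)
}
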