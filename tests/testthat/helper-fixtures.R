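# Shared builders and independent oracle implementations. Oracles are
# deliberately written with plain per-case loops (lm / cor.test / direct
# formulas), independent of the package's matrix-algebra path.

make_geno <- function(dosage, pos = NULL, maf = NULL, chrom = "chr1") {
  dosage <- as.matrix(dosage)
  v <- ncol(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("v%03d", seq_len(v))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("i%03d", seq_len(nrow(dosage)))
  }
  if (is.null(pos)) pos <- seq_len(v) * 1000
  if (is.null(maf)) {
    emp <- colMeans(dosage) / 2
    maf <- pmin(emp, 1 - emp)
  }
  geno_matrix(dosage, tibble::tibble(
    variant_id = colnames(dosage), chrom = chrom, pos = pos,
    ref = "A", alt = "G", maf = maf))
}

make_pheno <- function(values, pos = NULL, strand = "+", group = NULL,
                       chrom = "chr1") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("p%03d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("i%03d", seq_len(nrow(values)))
  }
  if (is.null(pos)) pos <- seq_len(ncol(values)) * 1000
  if (is.null(group)) group <- colnames(values)
  pheno_matrix(values, tibble::tibble(
    phenotype_id = colnames(values), chrom = chrom, pos = pos,
    strand = strand, group_id = group))
}

# Oracle: per-variant regression p via stats::lm, one fit per variant.
oracle_lm_scan <- function(y, dosage, covariates = NULL) {
  vapply(seq_len(ncol(dosage)), function(j) {
    d <- data.frame(y = y, g = dosage[, j])
    fml <- y ~ g
    if (!is.null(covariates)) {
      d <- cbind(d, as.data.frame(covariates))
      fml <- stats::as.formula(
        paste("y ~ g +", paste(colnames(as.data.frame(covariates)),
                               collapse = "+")))
    }
    summary(stats::lm(fml, data = d))$coefficients["g", 4]
  }, numeric(1))
}

# Oracle: two-sample correlation z-test, direct transcription of the
# textbook formula.
oracle_dz <- function(r1, n1, r2, n2) {
  z1 <- 0.5 * log((1 + r1) / (1 - r1))
  z2 <- 0.5 * log((1 + r2) / (1 - r2))
  (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}

# Oracle: exhaustive permutation p for the best-cis statistic of a single
# phenotype, via plain loops over every permutation and variant.
oracle_perm_exhaustive <- function(y, dosage) {
  n <- length(y)
  perms <- all_perms_list(n)
  best_abs_cor <- function(yy) {
    max(vapply(seq_len(ncol(dosage)), function(j) {
      abs(stats::cor(yy, dosage[, j]))
    }, numeric(1)))
  }
  obs <- best_abs_cor(y)
  stat <- vapply(perms, function(p) best_abs_cor(y[p]), numeric(1))
  mean(stat >= obs - 1e-12)
}

all_perms_list <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms_list(n - 1L)
  out <- list()
  for (k in seq_len(n)) {
    for (s in sub) out[[length(out) + 1]] <- c(k, s + (s >= k))
  }
  out
}

# Oracle: ORA p by exhaustive enumeration of all query-sized subsets of
# the background (feasible for |background| <= 20).
oracle_ora_enumeration <- function(query, background, set_members) {
  k <- length(query)
  obs <- length(intersect(query, set_members))
  subsets <- utils::combn(background, k, simplify = FALSE)
  mean(vapply(subsets, function(s) {
    length(intersect(s, set_members)) >= obs
  }, logical(1)))
}
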