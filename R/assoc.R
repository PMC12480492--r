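# Internal least-squares machinery shared by the mapping stages.
#
# All per-variant tests are simple linear regressions of a (residualised)
# phenotype on a (residualised) genotype; expressing them through the
# phenotype-genotype correlation lets whole cis windows be tested with one
# crossproduct, which is what makes the permutation and calibration loops
# tractable.

# Residualise the columns of M on an intercept plus optional covariates.
residualize <- function(M, covariates = NULL) {
  X <- cbind(rep(1, nrow(M)),
             if (!is.null(covariates)) as.matrix(covariates))
  qr.resid(qr(X), M)
}

n_covariates <- function(covariates) {
  if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
}

# Per-variant slope/se/p of y ~ g (+ covariates already removed from both).
# yr, Gr residualised; df = n - 2 - k.
assoc_from_residuals <- function(yr, Gr, df) {
  ss_y <- sum(yr^2)
  ss_g <- colSums(Gr^2)
  xy <- drop(crossprod(Gr, yr))
  ok <- ss_g > 1e-12
  b <- se <- tstat <- p <- r <- rep(NA_real_, length(ss_g))
  b[ok] <- xy[ok] / ss_g[ok]
  r[ok] <- xy[ok] / sqrt(ss_g[ok] * ss_y)
  r[ok] <- pmin(pmax(r[ok], -1), 1)
  sigma2 <- (ss_y * (1 - r[ok]^2)) / df
  se[ok] <- sqrt(sigma2 / ss_g[ok])
  tstat[ok] <- b[ok] / se[ok]
  p[ok] <- 2 * stats::pt(-abs(tstat[ok]), df)
  list(b = b, se = se, t = tstat, p = p, r = r, ok = ok)
}

# All n! permutations of 1..n, one per column (lexicographic).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(cbind, lapply(seq_len(n), function(k) {
    rbind(rep(k, ncol(sub)), sub + (sub >= k))
  }))
}

# Marginal association of a trait against every variant (no covariates).
fast_marginal_assoc <- function(y, dosage) {
  yr <- y - mean(y)
  Gr <- sweep(dosage, 2, colMeans(dosage))
  assoc_from_residuals(yr, Gr, df = length(y) - 2)
}
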