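# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the PC-selection yield curve
#'
#' Number of phenotypes with a significant cis association as a function
#' of the number of expression PCs removed; the chosen k is marked.
#'
#' @param object A `pc_selection` from [select_pc_count()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pc_selection <- function(object, ...) {
  ggplot2::ggplot(object$yield, ggplot2::aes(x = .data$k,
                                             y = .data$n_hits)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "expression PCs removed",
                  y = "phenotypes with significant cis association",
                  title = sprintf("PC selection: k = %d", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot colocalization posteriors
#'
#' Bar chart of the five hypothesis posteriors.
#'
#' @param object A [coloc_abf()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.coloc_abf <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hypothesis,
                                  y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "posterior probability",
                  title = sprintf("top shared variant: %s",
                                  object$top_shared_variant)) +
    ggplot2::theme_minimal()
}

#' Plot Mendelian-randomization instruments
#'
#' Per-instrument exposure vs outcome effects with the combined slope.
#'
#' @param object An [mr_estimate()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mr_result <- function(object, ...) {
  d <- object$instruments
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_exposure,
                                  y = .data$beta_outcome)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$estimate, intercept = 0,
                         colour = "firebrick") +
    ggplot2::labs(title = sprintf("%s estimate = %.3f (p = %.2g)",
                                  object$method, object$estimate,
                                  object$p)) +
    ggplot2::theme_minimal()
}

#' Genotype-stratified co-expression scatter
#'
#' Anchor vs partner expression, one panel per genotype stratum, with
#' per-stratum least-squares lines: the visual form of an allele-specific
#' co-expression QTL.
#'
#' @param expr [pheno_matrix()] holding both genes.
#' @param geno [geno_matrix()].
#' @param anchor_id,partner_id,variant_id Identifiers.
#' @return A ggplot.
#' @export
plot_coexqtl <- function(expr, geno, anchor_id, partner_id, variant_id) {
  vals <- align_individuals(geno$dosage, expr$values, "genotypes",
                            "phenotypes")
  g <- round(geno$dosage[, variant_id])
  d <- tibble::tibble(anchor = vals[, anchor_id],
                      partner = vals[, partner_id],
                      stratum = factor(c("RR", "RM", "MM")[g + 1],
                                       levels = c("RR", "RM", "MM")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$anchor, y = .data$partner)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = anchor_id, y = partner_id,
                  title = sprintf("co-expression by genotype at %s",
                                  variant_id)) +
    ggplot2::theme_minimal()
}

#' Plot feature-enrichment z-scores
#'
#' @param enr Tibble from [snp_enrichment()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enr) {
  ggplot2::ggplot(enr, ggplot2::aes(x = stats::reorder(.data$feature_class,
                                                       .data$Z),
                                    y = .data$Z)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96), linetype = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "enrichment Z") +
    ggplot2::theme_minimal()
}
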