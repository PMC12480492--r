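# SNP feature-enrichment: per-phenotype foreground/background selection
# and the two-proportion enrichment z-score against interval annotations.

#' Select foreground and background SNP sets per phenotype
#'
#' Foreground = variants associated at `fdr < fdr_fg`; background = the
#' other variants within the phenotype's cis window. Foreground can be
#' expanded by LD proxies at `r2 >= proxy_r2` computed on a genotype
#' panel; the sets stay disjoint. Phenotypes with an empty foreground
#' yield no rows (logged when `verbose`).
#'
#' @param records Tibble of QTL records with `phenotype_id`,
#'   `variant_id`, `fdr`, `distance_to_tss` (all variants tested in the
#'   window, not only significant ones).
#' @param fdr_fg Foreground FDR threshold.
#' @param window_bp Cis window half-width defining the background.
#' @param geno Optional [geno_matrix()] enabling proxy expansion.
#' @param proxy_r2 r-squared threshold for proxy expansion (`NULL` = off).
#' @param verbose Log empty foregrounds.
#' @return Tibble: `phenotype_id`, `variant_id`, `set` ("fg"/"bg").
#' @export
select_fg_bg <- function(records, fdr_fg = 0.001, window_bp = 1e6,
                         geno = NULL, proxy_r2 = NULL, verbose = FALSE) {
  in_window <- abs(records$distance_to_tss) <= window_bp
  records <- records[in_window, , drop = FALSE]
  out <- lapply(split(records, records$phenotype_id), function(d) {
    fg <- unique(d$variant_id[d$fdr < fdr_fg])
    if (length(fg) == 0) {
      if (verbose) message("empty foreground for ", d$phenotype_id[1])
      return(NULL)
    }
    if (!is.null(proxy_r2) && !is.null(geno)) {
      cand <- setdiff(unique(d$variant_id), fg)
      if (length(cand) > 0) {
        r2 <- stats::cor(geno$dosage[, cand, drop = FALSE],
                         geno$dosage[, fg, drop = FALSE])^2
        proxies <- cand[apply(r2, 1, max, na.rm = TRUE) >= proxy_r2]
        fg <- union(fg, proxies)
      }
    }
    bg <- setdiff(unique(d$variant_id), fg)
    tibble::tibble(phenotype_id = d$phenotype_id[1],
                   variant_id = c(fg, bg),
                   set = rep(c("fg", "bg"), c(length(fg), length(bg))))
  })
  dplyr::bind_rows(out)
}

#' Count SNP overlaps per feature class
#'
#' BED intervals are 0-based half-open and SNP positions 1-based: a SNP
#' at position p overlaps `[start, end)` iff `start < p <= end`.
#'
#' @param snps Tibble with `variant_id`, `chrom`, `pos`.
#' @param features Tibble BED: `chrom`, `start`, `end`, `name` (class).
#' @return Tibble: `feature_class`, `n_overlap`, plus the per-SNP overlap
#'   table as attribute `"hits"`.
#' @export
overlap_counts <- function(snps, features) {
  validate_bed(features)
  classes <- unique(features$name)
  hits <- lapply(split(features, features$name), function(fc) {
    per_chrom <- lapply(intersect(unique(fc$chrom), unique(snps$chrom)),
                        function(ch) {
      fi <- fc[fc$chrom == ch, , drop = FALSE]
      si <- snps[snps$chrom == ch, , drop = FALSE]
      if (nrow(fi) == 0 || nrow(si) == 0) return(character(0))
      # 0-based half-open [start, end) covers 1-based bases start+1 .. end
      ir <- IRanges::IRanges(start = fi$start + 1, end = fi$end)
      sr <- IRanges::IRanges(start = si$pos, end = si$pos)
      ov <- IRanges::findOverlaps(sr, ir)
      unique(si$variant_id[S4Vectors::queryHits(ov)])
    })
    unique(unlist(per_chrom))
  })
  out <- tibble::tibble(feature_class = names(hits),
                        n_overlap = unname(lengths(hits)))
  attr(out, "hits") <- hits
  out
}

validate_bed <- function(features) {
  req <- c("chrom", "start", "end", "name")
  if (!all(req %in% names(features))) {
    rlang::abort("BED table needs chrom, start, end, name")
  }
  bad <- which(!is.finite(features$start) | !is.finite(features$end) |
                 features$start < 0 | features$end <= features$start)
  if (length(bad) > 0) {
    rlang::abort(paste0("malformed BED interval at line ", bad[1]))
  }
  invisible(features)
}

#' Two-proportion enrichment z-score
#'
#' `Z = (f/F - b/B) / SE` where the default (unpooled) standard error is
#' `sqrt((f/F)(1-f/F)/F + (b/B)(1-b/B)/B)`; a pooled-SE variant is
#' available. Degenerate cases with SE = 0 (both proportions 0 or 1)
#' return Z = 0 with a warning so downstream ranking stays total.
#'
#' @param f,F_,b,B_ Foreground overlap count, foreground size, background
#'   overlap count, background size (vectors recycle).
#' @param se `"unpooled"` (default) or `"pooled"`.
#' @return Numeric z-score(s).
#' @export
enrichment_z <- function(f, F_, b, B_, se = c("unpooled", "pooled")) {
  se <- match.arg(se)
  if (any(F_ <= 0) || any(B_ <= 0)) rlang::abort("F and B must be > 0")
  if (any(f < 0 | f > F_) || any(b < 0 | b > B_)) {
    rlang::abort("need 0 <= f <= F and 0 <= b <= B")
  }
  p1 <- f / F_
  p2 <- b / B_
  se_val <- if (se == "unpooled") {
    sqrt(p1 * (1 - p1) / F_ + p2 * (1 - p2) / B_)
  } else {
    pp <- (f + b) / (F_ + B_)
    sqrt(pp * (1 - pp) * (1 / F_ + 1 / B_))
  }
  z <- (p1 - p2) / se_val
  if (any(se_val == 0)) {
    rlang::warn("zero standard error; returning Z = 0 for degenerate case(s)")
    z[se_val == 0] <- 0
  }
  z
}

#' Feature-enrichment z-scores for foreground vs background SNP sets
#'
#' Aggregates foreground/background overlap counts against each feature
#' class and computes the enrichment z-score. By default counts are
#' aggregated across phenotypes (one 2x2 per feature class); per-
#' phenotype mode computes a z per phenotype per class.
#'
#' @param fg_bg Output of [select_fg_bg()].
#' @param snps Tibble with `variant_id`, `chrom`, `pos`.
#' @param features BED tibble.
#' @param se Passed to [enrichment_z()].
#' @param per_phenotype Compute per-phenotype z-scores instead of
#'   aggregating counts.
#' @return Tibble of enrichment results: `feature_class`, `f`, `F`, `b`,
#'   `B`, `Z`, `p` (two-sided normal).
#' @export
snp_enrichment <- function(fg_bg, snps, features, se = "unpooled",
                           per_phenotype = FALSE) {
  validate_bed(features)
  if (nrow(features) == 0) rlang::abort("empty feature table")
  oc <- overlap_counts(snps, features)
  hits <- attr(oc, "hits")
  one <- function(d) {
    fg <- unique(d$variant_id[d$set == "fg"])
    bg <- unique(d$variant_id[d$set == "bg"])
    purrr::map_dfr(names(hits), function(cls) {
      tibble::tibble(feature_class = cls,
                     f = sum(fg %in% hits[[cls]]), F = length(fg),
                     b = sum(bg %in% hits[[cls]]), B = length(bg))
    })
  }
  counts <- if (per_phenotype) {
    dplyr::bind_rows(lapply(split(fg_bg, fg_bg$phenotype_id), one),
                     .id = "phenotype_id")
  } else {
    one(fg_bg)
  }
  counts$Z <- enrichment_z(counts$f, counts$F, counts$b, counts$B, se = se)
  counts$p <- 2 * stats::pnorm(-abs(counts$Z))
  counts
}
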