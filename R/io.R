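# Readers and writers for the external formats: VCF 4.2 genotypes, TSV
# phenotype matrices (phenotypes x individuals) with position maps, BED
# annotations (0-based half-open), GMT gene sets, GWAS summary TSV.
# Variant positions are 1-based (VCF convention) everywhere; interval
# conversions are confined to this file and to overlap_counts().

#' Write genotypes as plain-text VCF 4.2
#'
#' GT-encoded from rounded dosages (0/0, 0/1, 1/1); the alt allele is the
#' minor allele, so GT alt-allele counts equal the dosage matrix.
#'
#' @param geno [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  gt <- c("0/0", "0/1", "1/1")[round(t(geno$dosage)) + 1]
  gt <- matrix(gt, nrow = ncol(geno$dosage))
  body <- cbind(geno$map$chrom, geno$map$pos, geno$map$variant_id,
                geno$map$ref, geno$map$alt, ".", "PASS",
                sprintf("MAF=%.6g", geno$map$maf), "GT", gt)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(geno$map$chrom)),
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$dosage)), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from VCF or TSV dosage matrix
#'
#' VCF input goes through `vcfR`; dosages are alt-allele counts from GT.
#' Missing genotypes are mean-imputed per variant (logged). TSV input
#' (individuals x variants, header of variant ids, first column of
#' individual ids) requires a variant map TSV.
#'
#' @param path VCF (`.vcf`) or TSV file.
#' @param map_path Variant map TSV (required for TSV input): columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `maf`.
#' @param verbose Log imputation.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, map_path = NULL, verbose = FALSE) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(x) {
      ifelse(is.na(x) | grepl("\\.", x), NA_real_,
             vapply(strsplit(x, "[/|]"), function(a)
               sum(a == "1"), numeric(1)))
    }
    dosage <- apply(gt, 2, count_alt)
    rownames(dosage) <- rownames(gt)
    nmiss <- colSums(is.na(t(dosage)))
    dosage <- t(dosage)  # to individuals x variants
    if (any(is.na(dosage))) {
      if (verbose) {
        message("mean-imputing missing genotypes at ",
                sum(colSums(is.na(dosage)) > 0), " variant(s)")
      }
      for (j in which(colSums(is.na(dosage)) > 0)) {
        dosage[is.na(dosage[, j]), j] <- mean(dosage[, j], na.rm = TRUE)
      }
    }
    fix <- tibble::as_tibble(as.data.frame(v@fix,
                                           stringsAsFactors = FALSE))
    maf <- suppressWarnings(
      as.numeric(sub(".*MAF=([0-9.eE+-]+).*", "\\1", fix$INFO)))
    emp <- colMeans(dosage) / 2
    maf[is.na(maf)] <- pmin(emp, 1 - emp)[is.na(maf)]
    map <- tibble::tibble(variant_id = fix$ID, chrom = fix$CHROM,
                          pos = as.numeric(fix$POS), ref = fix$REF,
                          alt = fix$ALT, maf = maf)
    colnames(dosage) <- map$variant_id
    return(geno_matrix(dosage, map))
  }
  if (is.null(map_path)) rlang::abort("TSV genotypes need a variant map")
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  dosage <- as.matrix(d[, -1, drop = FALSE])
  rownames(dosage) <- d[[1]]
  map <- tibble::as_tibble(utils::read.table(map_path, header = TRUE,
                                             sep = "\t"))
  geno_matrix(dosage, map)
}

#' Write a phenotype matrix as TSV (phenotypes x individuals) plus map
#' @param pheno [pheno_matrix()].
#' @param values_path,map_path Output paths.
#' @return `values_path`, invisibly.
#' @export
write_phenotypes <- function(pheno, values_path, map_path) {
  d <- data.frame(phenotype_id = colnames(pheno$values),
                  t(pheno$values), check.names = FALSE)
  utils::write.table(d, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(pheno$map), map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(values_path)
}

#' Read a phenotype matrix written by [write_phenotypes()]
#' @param values_path,map_path Input paths.
#' @return A [pheno_matrix()].
#' @export
read_phenotypes <- function(values_path, map_path) {
  d <- utils::read.table(values_path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  vals <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(vals) <- d[[1]]
  map <- tibble::as_tibble(utils::read.table(map_path, header = TRUE,
                                             sep = "\t"))
  pheno_matrix(vals, map)
}

#' Read BED3+name annotations (0-based half-open)
#' @param path BED file (no header).
#' @return Tibble: `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 4)
  if (length(bad) > 0) {
    rlang::abort(paste0("malformed BED line ", bad[1], " in ", path))
  }
  out <- tibble::tibble(
    chrom = vapply(parts, `[[`, character(1), 1),
    start = suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2))),
    end = suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3))),
    name = vapply(parts, `[[`, character(1), 4))
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad) > 0) {
    rlang::abort(paste0("non-numeric BED coordinates at line ", bad[1]))
  }
  validate_bed(out)
}

#' Write BED annotations
#' @param features Tibble: `chrom`, `start`, `end`, `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  utils::write.table(
    features[, c("chrom", "start", "end", "name")], path, sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read GMT gene sets
#' @param path GMT file (set name, description, tab-separated members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  parts <- strsplit(readLines(path), "\t")
  nms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nms) > 0) {
    rlang::abort(paste0("duplicate gene-set name in ", path, ": ",
                        nms[duplicated(nms)][1]))
  }
  stats::setNames(lapply(parts, function(x) x[-(1:2)]), nms)
}

#' Write GMT gene sets
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read GWAS summary statistics TSV
#' @param path TSV with at least `variant_id`, `beta`, `se`, `p`.
#' @return Tibble.
#' @export
read_gwas <- function(path) {
  d <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  req <- c("variant_id", "beta", "se", "p")
  if (!all(req %in% names(d))) {
    rlang::abort(paste0(path, " lacks column(s): ",
                        paste(setdiff(req, names(d)), collapse = ", ")))
  }
  d
}

#' Write a simulated object set as plain-text fixtures
#'
#' Writes VCF (genotypes), TSV (phenotype matrices and maps, GWAS), BED
#' (features) and GMT (gene sets) into `outdir` and returns a manifest
#' of file checksums, also saved as `manifest.json`.
#'
#' @param outdir Output directory (created if needed).
#' @param geno Optional [geno_matrix()].
#' @param phenotypes Optional named list of [pheno_matrix()].
#' @param gwas Optional GWAS tibble.
#' @param features Optional BED tibble.
#' @param gene_sets Optional named list for GMT.
#' @return Tibble manifest: `file`, `md5`.
#' @export
write_fixtures <- function(outdir, geno = NULL, phenotypes = NULL,
                           gwas = NULL, features = NULL,
                           gene_sets = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) rlang::abort(paste0("cannot create ", outdir))
  files <- character(0)
  put <- function(fn) files[[length(files) + 1]] <<- fn
  if (!is.null(geno)) {
    write_vcf(geno, file.path(outdir, "genotypes.vcf"))
    put("genotypes.vcf")
  }
  for (nm in names(phenotypes)) {
    vp <- paste0("phenotypes_", nm, ".tsv")
    mp <- paste0("phenotype_map_", nm, ".tsv")
    write_phenotypes(phenotypes[[nm]], file.path(outdir, vp),
                     file.path(outdir, mp))
    put(vp); put(mp)
  }
  if (!is.null(gwas)) {
    utils::write.table(as.data.frame(gwas),
                       file.path(outdir, "gwas_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    put("gwas_summary.tsv")
  }
  if (!is.null(features)) {
    write_bed(features, file.path(outdir, "features.bed"))
    put("features.bed")
  }
  if (!is.null(gene_sets)) {
    write_gmt(gene_sets, file.path(outdir, "gene_sets.gmt"))
    put("gene_sets.gmt")
  }
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))))
  json <- paste0(
    "{\n",
    paste(sprintf("  \"%s\": \"%s\"", manifest$file, manifest$md5),
          collapse = ",\n"),
    "\n}\n")
  writeLines(json, file.path(outdir, "manifest.json"))
  manifest
}
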