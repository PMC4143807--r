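#' Read gene regions from a BED file
#'
#' Reads a BED4 file (chrom, start, end, name) of gene boundaries.  BED
#' coordinates are 0-based half-open; a variant with 1-based position `p`
#' belongs to a region when `start < p <= end`.
#'
#' @param path path to a BED file with at least 4 columns.
#' @return a tibble with columns `gene`, `chrom`, `start`, `end`, in file
#'   order.  Overlapping regions are permitted.
#' @export
read_regions <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4) {
    abort(sprintf("BED file needs >= 4 columns (chrom, start, end, name), found %d",
                  ncol(raw)))
  }
  start <- as.numeric(raw[[2]])
  end <- as.numeric(raw[[3]])
  bad <- which(!(start < end))
  if (length(bad) > 0) {
    abort(sprintf("BED line %d: start (%s) must be < end (%s)",
                  bad[1], raw[[2]][bad[1]], raw[[3]][bad[1]]))
  }
  tibble(gene = raw[[4]], chrom = raw[[1]], start = start, end = end)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF (plain or bgzipped) into an ALT-allele dosage matrix plus a
#' variant table.  Only biallelic records are kept; multi-allelic records
#' are skipped with a warning.  Missing genotypes are `NA` at this stage.
#'
#' @param path path to a VCF file.
#' @return a list of class `vcf_genotypes` with elements `dosage`
#'   (individuals x variants matrix of ALT-allele counts, `NA` for missing)
#'   and `variants` (tibble with `chrom`, `pos`, `ref`, `alt`).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warn(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  dosage <- gt_to_dosage(gt)  # variants x individuals
  structure(list(
    dosage = t(dosage),
    variants = tibble(
      chrom = unname(fix[keep, "CHROM"]),
      pos = as.numeric(fix[keep, "POS"]),
      ref = unname(fix[keep, "REF"]),
      alt = unname(fix[keep, "ALT"])
    )
  ), class = "vcf_genotypes")
}

# "0/0", "0|1", "1/1", "./." (etc.) -> 0, 1, 2, NA
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "." | is.na(gt)] <- NA
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

#' Assemble a per-gene genotype matrix
#'
#' Extracts the variants of one gene region for a set of individuals and
#' produces the analysis-ready dosage matrix: each column is oriented so
#' that the counted allele is the minor allele in the analyzed sample
#' (dosage 0/1/2 for zero, one or two copies; a 0.5 frequency tie counts
#' the ALT allele), monomorphic columns are dropped, and missing genotypes
#' are imputed to the column mean dosage.
#'
#' @param vcf a `vcf_genotypes` object from [read_vcf_genotypes()], or a
#'   path to a VCF file.
#' @param region a one-row data frame with `gene`, `chrom`, `start`, `end`
#'   (BED half-open convention), e.g. one row of [read_regions()].
#' @param ids ordered character vector of individual ids to analyze; must
#'   all be present in the VCF.
#' @return a `gene_matrix` object (see [gene_matrix()]), possibly with zero
#'   variant columns if nothing in the region is polymorphic.
#' @export
extract_gene_matrix <- function(vcf, region, ids) {
  if (is.character(vcf)) vcf <- read_vcf_genotypes(vcf)
  stopifnot(inherits(vcf, "vcf_genotypes"))
  region <- as.list(as.data.frame(region)[1, ])
  check_ids_present(ids, rownames(vcf$dosage), "VCF sample")
  sel <- vcf$variants$chrom == region$chrom &
    vcf$variants$pos > region$start & vcf$variants$pos <= region$end
  gene_matrix(
    dosage = vcf$dosage[ids, sel, drop = FALSE],
    variants = vcf$variants[sel, , drop = FALSE],
    gene = region$gene
  )
}

#' Construct an analysis-ready gene genotype matrix
#'
#' Takes raw ALT-allele dosages (0/1/2/NA) for one gene and applies the
#' standard preparation: orient each column to the sample minor allele,
#' drop monomorphic columns, mean-impute missing genotypes, and record the
#' per-variant minor allele frequency.
#'
#' @param dosage numeric matrix, individuals x variants, of ALT-allele
#'   counts in \{0, 1, 2, NA\}; rownames are individual ids.
#' @param variants tibble with one row per column of `dosage`; must contain
#'   `pos`, and optionally `chrom`, `ref`, `alt`.
#' @param gene gene name.
#' @return an object of class `gene_matrix`: a list with `gene`, `dosage`
#'   (oriented, imputed), and `variants` (tibble with `pos`, `maf`,
#'   `minor_is_alt`, `collapsed` and any input metadata).
#' @export
gene_matrix <- function(dosage, variants, gene = "gene") {
  dosage <- as.matrix(dosage)
  variants <- as_tibble(variants)
  stopifnot(ncol(dosage) == nrow(variants), "pos" %in% names(variants))
  n_obs <- colSums(!is.na(dosage))
  alt_freq <- ifelse(n_obs > 0, colSums(dosage, na.rm = TRUE) / (2 * n_obs), NA)
  # polymorphic = at least two distinct observed dosages
  poly <- vapply(seq_len(ncol(dosage)), function(j) {
    u <- unique(dosage[!is.na(dosage[, j]), j])
    length(u) >= 2
  }, logical(1))
  dosage <- dosage[, poly, drop = FALSE]
  variants <- variants[poly, , drop = FALSE]
  alt_freq <- alt_freq[poly]
  # orient to the minor allele; frequency ties keep the ALT allele
  minor_is_alt <- alt_freq <= 0.5
  flip <- which(!minor_is_alt)
  if (length(flip)) dosage[, flip] <- 2 - dosage[, flip]
  maf <- ifelse(minor_is_alt, alt_freq, 1 - alt_freq)
  # mean imputation preserves the column mean, hence the MAF
  for (j in which(colSums(is.na(dosage)) > 0)) {
    m <- mean(dosage[, j], na.rm = TRUE)
    dosage[is.na(dosage[, j]), j] <- m
  }
  variants$maf <- as.numeric(maf)
  variants$minor_is_alt <- minor_is_alt
  if (!"collapsed" %in% names(variants)) variants$collapsed <- FALSE
  structure(list(gene = gene, dosage = dosage, variants = variants),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> %s: %d individuals x %d variants\n",
              x$gene, nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Number of variants in a gene matrix
#' @param x a `gene_matrix`.
#' @return integer count of variant columns.
#' @export
n_variants <- function(x) {
  stopifnot(inherits(x, "gene_matrix"))
  ncol(x$dosage)
}

#' Minor/major allele counts in a group
#'
#' Sums minor-allele dosages over a group of individuals for one variant;
#' mean-imputed dosages contribute fractionally.  These are the 2x2 table
#' margins used by the per-variant chi-square tests.
#'
#' @param x a `gene_matrix`.
#' @param variant column index of the variant.
#' @param group non-empty character vector of individual ids (subset of the
#'   matrix rownames).
#' @return a one-row tibble with `minor` and `major` allele counts.
#' @export
allele_counts <- function(x, variant, group) {
  stopifnot(inherits(x, "gene_matrix"))
  if (length(group) == 0) abort("group must be non-empty")
  check_ids_present(group, rownames(x$dosage))
  minor <- sum(x$dosage[group, variant])
  tibble(minor = minor, major = 2 * length(group) - minor)
}
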