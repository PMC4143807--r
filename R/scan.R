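#' Bonferroni-corrected per-gene significance threshold
#'
#' @param n_genes number of genes tested (>= 1).
#' @param family_alpha family-wise error rate in (0, 1), default 0.05.
#' @return `family_alpha / n_genes`.  With the 10,580 genes of the
#'   odd-numbered autosomes this is the conventional 4.7e-6 gene-level
#'   threshold.
#' @export
bonferroni_threshold <- function(n_genes, family_alpha = 0.05) {
  stopifnot(n_genes >= 1, family_alpha > 0, family_alpha < 1)
  family_alpha / n_genes
}

#' Genome scan: run the four family tests over all gene regions
#'
#' Iterates the gene regions, extracts each gene's genotype matrix, and
#' runs the pedigree-adjusted T2, CMC, FPCA and chi-square minimum tests
#' against a binary phenotype.  The kinship correction factor is computed
#' once from the pedigree and the case/control partition and shared by all
#' genes and methods (it does not depend on genotype).
#'
#' Individuals analyzed are those present in the VCF, the pedigree, and
#' the phenotype table with a non-missing phenotype.  Genes with no
#' polymorphic variants are dropped from the result (recorded in the
#' `skipped` attribute with a reason); genes with fewer than 3 variants
#' get `NA` FPCA entries.
#'
#' @param vcf a `vcf_genotypes` object or a VCF file path.
#' @param regions a regions tibble from [read_regions()] (or a BED path).
#' @param pedigree a pedigree tibble from [read_pedigree()] (or a FAM/PED
#'   path).
#' @param phenotype optional tibble with columns `individual_id` and
#'   `affection` ("case"/"control"/NA), or a path to a tab-separated table
#'   with header `fid iid pheno` (2 = case, 1 = control).  Defaults to the
#'   pedigree's affection column.
#' @param rare_maf CMC rare-variant threshold (see [cmc_collapse()]).
#' @param variance_explained FPCA retained-variance fraction (see
#'   [fpca_family()]).
#' @param sidak see [chi_min_family()].
#' @param tol covariance pseudo-inverse tolerance.
#' @return a `gene_scan` object: a tibble with one row per analyzed gene
#'   and method (`gene`, `chrom`, `n_variants`, `p_corr`, `method`,
#'   `statistic`, `df`, `p_value`), in input region order.  Attributes:
#'   `n_genes_loaded`, `n_cases`, `n_controls`, `skipped` (tibble of
#'   genes not analyzed and why).
#' @export
scan_genome <- function(vcf, regions, pedigree, phenotype = NULL,
                        rare_maf = 0.01, variance_explained = 0.85,
                        sidak = FALSE, tol = 1e-8) {
  if (is.character(vcf)) vcf <- read_vcf_genotypes(vcf)
  if (is.character(regions)) regions <- read_regions(regions)
  if (is.character(pedigree)) pedigree <- read_pedigree(pedigree)
  if (is.character(phenotype)) phenotype <- read_phenotype(phenotype)
  if (is.null(phenotype)) {
    phenotype <- dplyr::select(pedigree, "individual_id", "affection")
  }
  ids <- intersect(
    intersect(rownames(vcf$dosage), pedigree$individual_id),
    phenotype$individual_id[!is.na(phenotype$affection)]
  )
  if (length(ids) == 0) {
    abort("no individuals shared by the VCF, pedigree and phenotype inputs")
  }
  aff <- setNames(phenotype$affection, phenotype$individual_id)[ids]
  cases <- ids[aff == "case"]
  controls <- ids[aff == "control"]
  phi <- kinship_matrix(pedigree)
  pc <- correction_factor(phi, cases, controls)

  mats <- lapply(seq_len(nrow(regions)), function(i) {
    extract_gene_matrix(vcf, regions[i, ], ids)
  })
  scan_matrices(mats, cases, controls, pc,
                chrom = regions$chrom,
                rare_maf = rare_maf,
                variance_explained = variance_explained,
                sidak = sidak, tol = tol,
                n_genes_loaded = nrow(regions))
}

#' Run the four tests over a list of gene matrices
#'
#' Core scan driver used both by [scan_genome()] and by the in-memory
#' simulation pipeline: no file I/O, just a list of [gene_matrix()]
#' objects and a case/control partition.
#'
#' @param matrices list of `gene_matrix` objects.
#' @param cases,controls id vectors (rows of every matrix).
#' @param p_corr shared correction factor (number or
#'   [correction_factor()] tibble).
#' @param chrom optional chromosome label(s) for the output.
#' @inheritParams scan_genome
#' @param n_genes_loaded denominator recorded for Bonferroni thresholds
#'   (defaults to `length(matrices)`).
#' @return a `gene_scan` object as described in [scan_genome()].
#' @export
scan_matrices <- function(matrices, cases, controls, p_corr = 1,
                          chrom = NA_character_, rare_maf = 0.01,
                          variance_explained = 0.85, sidak = FALSE,
                          tol = 1e-8, n_genes_loaded = length(matrices)) {
  pc <- as_p_corr(p_corr)
  chrom <- rep_len(chrom, length(matrices))
  rows <- vector("list", length(matrices))
  skipped <- list()
  for (i in seq_along(matrices)) {
    gm <- matrices[[i]]
    if (n_variants(gm) == 0) {
      skipped[[length(skipped) + 1L]] <-
        tibble(gene = gm$gene, reason = "no polymorphic variants")
      next
    }
    res <- gene_tests(gm, cases, controls, p_corr = pc, rare_maf = rare_maf,
                      variance_explained = variance_explained, tol = tol,
                      sidak = sidak)
    res$gene <- gm$gene
    res$chrom <- chrom[i]
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(method = character(), statistic = numeric(),
                  df = integer(), p_value = numeric(),
                  n_variants = integer(), p_corr = numeric(),
                  gene = character(), chrom = character())
  }
  out <- dplyr::select(out, "gene", "chrom", "n_variants", "p_corr",
                       "method", "statistic", "df", "p_value")
  skipped <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble(gene = character(), reason = character())
  new_gene_scan(out, n_genes_loaded = n_genes_loaded,
                n_cases = length(cases), n_controls = length(controls),
                skipped = skipped)
}

new_gene_scan <- function(tbl, n_genes_loaded, n_cases, n_controls, skipped) {
  structure(tbl,
            class = c("gene_scan", class(tibble())),
            n_genes_loaded = n_genes_loaded,
            n_cases = n_cases, n_controls = n_controls,
            skipped = skipped)
}

#' Count significant genes for a method at a level
#'
#' @param scan a `gene_scan` from [scan_genome()] / [scan_matrices()].
#' @param method one of "T2F", "CMCF", "FPCAF", "CHIMIN"; `NULL` counts
#'   all methods.
#' @param alpha significance level; p <= alpha counts.  Skipped entries
#'   (`NA` p) are never significant.
#' @return a tibble with columns `method`, `alpha`, `n_significant`.
#' @export
count_significant <- function(scan, method = NULL, alpha = 0.05) {
  tbl <- as_tibble(scan)
  methods <- method %||% unique(tbl$method)
  purrr::map_dfr(alpha, function(a) {
    tibble(
      method = methods,
      alpha = a,
      n_significant = vapply(methods, function(m) {
        sum(tbl$method == m & !is.na(tbl$p_value) & tbl$p_value <= a)
      }, integer(1), USE.NAMES = FALSE)
    )
  })
}

#' Overlaps of significant gene sets between methods
#'
#' Computes, for the chosen methods at a level, the count of genes in
#' every exclusive subset combination (Venn regions), and optionally the
#' per-method intersection with an external gene list (e.g. genes known
#' from GWAS).
#'
#' @inheritParams count_significant
#' @param methods methods to intersect (default the three all-gene
#'   methods T2F, CMCF, CHIMIN).
#' @param alpha significance level.
#' @param external_list optional character vector of gene names.
#' @return a list with `venn` (tibble: one row per non-empty method
#'   combination, columns `members` and `n`), `sets` (named list of the
#'   significant gene sets), and, when `external_list` is given,
#'   `external` (tibble `method`, `n_overlap`).
#' @export
overlap_sets <- function(scan, methods = c("T2F", "CMCF", "CHIMIN"),
                         alpha = 0.05, external_list = NULL) {
  tbl <- as_tibble(scan)
  sets <- lapply(setNames(methods, methods), function(m) {
    unique(tbl$gene[tbl$method == m & !is.na(tbl$p_value) &
                      tbl$p_value <= alpha])
  })
  genes <- unique(unlist(sets))
  venn <- tibble(gene = genes)
  if (nrow(venn) > 0) {
    member <- vapply(genes, function(g) {
      paste(methods[vapply(sets, function(s) g %in% s, logical(1))],
            collapse = "&")
    }, character(1))
    venn <- dplyr::count(tibble(members = member), .data$members, name = "n")
  } else {
    venn <- tibble(members = character(), n = integer())
  }
  out <- list(venn = venn, sets = sets)
  if (!is.null(external_list)) {
    out$external <- tibble(
      method = methods,
      n_overlap = vapply(sets, function(s)
        length(intersect(s, external_list)), integer(1))
    )
  }
  out
}

#' Write a scan result as a wide tab-separated table
#'
#' One row per gene, columns `gene chrom n_variants p_corr` followed by
#' `<method>_stat`, `<method>_df`, `<method>_p` for each of the four
#' methods, `NA` where a method was skipped.
#'
#' @param scan a `gene_scan`.
#' @param path output file path.
#' @return the wide tibble, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  wide <- as_tibble(scan) |>
    dplyr::mutate(method = tolower(.data$method)) |>
    tidyr::pivot_wider(
      id_cols = c("gene", "chrom", "n_variants", "p_corr"),
      names_from = "method",
      values_from = c("statistic", "df", "p_value"),
      names_glue = "{method}_{dplyr::recode(.value, statistic = 'stat', p_value = 'p', df = 'df')}"
    )
  per_method <- unlist(lapply(c("t2f", "cmcf", "fpcaf", "chimin"),
                              function(m) paste0(m, c("_stat", "_df", "_p"))))
  wide <- dplyr::select(wide, "gene", "chrom", "n_variants", "p_corr",
                        dplyr::any_of(per_method))
  readr::write_tsv(wide, path)
  invisible(wide)
}

#' Read the tab-separated phenotype table
#'
#' Expected header `fid iid pheno` with 2 = case, 1 = control, anything
#' else missing.
#'
#' @param path file path.
#' @return tibble with `family_id`, `individual_id`, `affection`.
#' @export
read_phenotype <- function(path) {
  raw <- utils::read.table(path, header = TRUE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c("fid", "iid", "pheno") %in% names(raw))) {
    abort("phenotype table must have header: fid iid pheno")
  }
  tibble(
    family_id = raw$fid,
    individual_id = raw$iid,
    affection = dplyr::case_match(raw$pheno, "2" ~ "case", "1" ~ "control",
                                  .default = NA_character_)
  )
}
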