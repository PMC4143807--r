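#' Write a pedigree as a PLINK FAM file
#'
#' @param ped pedigree tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fam <- function(ped, path) {
  lines <- sprintf(
    "%s %s %s %s %d %d",
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    dplyr::case_match(ped$sex, "male" ~ 1L, "female" ~ 2L, .default = 0L),
    dplyr::case_match(ped$affection, "case" ~ 2L, "control" ~ 1L,
                      .default = 0L)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write gene regions as a BED4 file
#'
#' @param regions tibble with `gene`, `chrom`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom,
                     as.integer(regions$start), as.integer(regions$end),
                     regions$gene), path)
  invisible(path)
}

#' Write a phenotype table (header `fid iid pheno`)
#'
#' @param phenotype tibble with `family_id`, `individual_id`,
#'   `affection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pheno <- function(phenotype, path) {
  pheno <- dplyr::case_match(phenotype$affection, "case" ~ 2L,
                             "control" ~ 1L, .default = 0L)
  writeLines(c("fid\tiid\tpheno",
               sprintf("%s\t%s\t%d", phenotype$family_id,
                       phenotype$individual_id, pheno)), path)
  invisible(path)
}

# Write simulated gene matrices as a plain VCF 4.2 file.  Uses the raw
# (unfiltered, simulation-oriented) haplotypes kept by gene_drop(), so
# monomorphic sites are emitted too and a round trip through
# extract_gene_matrix() reproduces the analysis matrices.
write_sim_vcf <- function(matrices, ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pedassoc_simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  for (gm in matrices) {
    raw <- attr(gm, "raw")
    if (is.null(raw)) abort("matrix lacks the simulator's 'raw' attribute")
    h1 <- raw$h1[ids, , drop = FALSE]
    h2 <- raw$h2[ids, , drop = FALSE]
    for (j in seq_along(raw$pos)) {
      gt <- paste(h1[, j], h2[, j], sep = "/")
      writeLines(paste(c(raw$chrom, raw$pos[j],
                         sprintf("%s_v%d", gm$gene, j), "A", "T", ".",
                         "PASS", ".", "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}
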