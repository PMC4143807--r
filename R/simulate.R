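#' Simulation configuration
#'
#' Defines a synthetic family sequencing study: replicated template
#' pedigrees, a fixed gene map with founder allele frequencies drawn from
#' a mixed common/rare site-frequency spectrum, Mendelian gene dropping,
#' and a binary liability phenotype from a logistic model with
#' configurable causal genes.
#'
#' The default study is 300 nuclear families of two parents and two
#' children (1200 individuals) and 1000 genes carrying 5 to 20 variants
#' each, of which 60% are rare (founder MAF uniform on 0.001-0.01) and
#' 40% common (uniform on 0.05-0.5), with a 30% baseline prevalence and
#' no causal genes -- a pure null for calibration work.
#'
#' @param n_pedigrees number of template pedigrees.
#' @param template pedigree template: `"nuclear"` (2 parents +
#'   `n_children`), `"trio"`, or `"three_generation"` (a grandparental
#'   couple, their child married to an unrelated founder, and two
#'   grandchildren).
#' @param n_children children per nuclear family.
#' @param n_genes number of genes on the map.
#' @param variants_per_gene integer range `c(min, max)` (or a single
#'   count) of variants drawn per gene.
#' @param prop_rare expected proportion of rare variants per gene.
#' @param rare_maf_range,common_maf_range uniform founder-MAF ranges for
#'   rare and common variants.
#' @param n_causal_genes number of causal genes (0 = null model).
#' @param beta_common per-copy log-odds effect of each common variant in
#'   a causal gene.
#' @param beta_rare log-odds effect of carrying a minor allele at each
#'   rare variant in a causal gene.
#' @param rare_sign_mix fraction of causal rare variants whose effect
#'   sign is flipped to protective (models within-gene effect
#'   heterogeneity).
#' @param prevalence baseline disease probability for a zero-genotype
#'   individual.
#' @param n_replicates number of independent replicates; replicates share
#'   the pedigree structure and gene map but redraw founder haplotypes,
#'   transmissions and phenotypes.
#' @param seed integer seed; all randomness derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pedigrees = 300,
                       template = c("nuclear", "trio", "three_generation"),
                       n_children = 2,
                       n_genes = 1000,
                       variants_per_gene = c(5, 20),
                       prop_rare = 0.6,
                       rare_maf_range = c(0.001, 0.01),
                       common_maf_range = c(0.05, 0.5),
                       n_causal_genes = 0,
                       beta_common = 0,
                       beta_rare = 0,
                       rare_sign_mix = 0,
                       prevalence = 0.3,
                       n_replicates = 1,
                       seed = 1) {
  template <- match.arg(template)
  stopifnot(
    n_pedigrees >= 1, n_genes >= 1, n_replicates >= 1,
    n_causal_genes <= n_genes, n_causal_genes >= 0,
    prevalence > 0, prevalence < 1,
    prop_rare >= 0, prop_rare <= 1,
    rare_sign_mix >= 0, rare_sign_mix <= 1
  )
  structure(list(
    n_pedigrees = as.integer(n_pedigrees), template = template,
    n_children = as.integer(n_children), n_genes = as.integer(n_genes),
    variants_per_gene = as.integer(rep_len(variants_per_gene, 2)),
    prop_rare = prop_rare, rare_maf_range = rare_maf_range,
    common_maf_range = common_maf_range,
    n_causal_genes = as.integer(n_causal_genes),
    beta_common = beta_common, beta_rare = beta_rare,
    rare_sign_mix = rare_sign_mix,
    prevalence = prevalence, n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Build the replicated template pedigrees
#'
#' Deterministic (no randomness): pedigree structure is fixed across
#' replicates, as in fixed-map family simulation designs.
#'
#' @param config a [sim_config()], or a pedigree count (with `template`
#'   and `n_children` as extra arguments).
#' @param template,n_children see [sim_config()].
#' @return a pedigree tibble (see [read_pedigree()]), affection all
#'   missing.
#' @export
simulate_pedigrees <- function(config, template = "nuclear", n_children = 2) {
  if (!inherits(config, "sim_config")) {
    config <- sim_config(n_pedigrees = config, template = template,
                         n_children = n_children)
  }
  one <- switch(config$template,
    trio = tibble(
      individual_id = c("p1", "p2", "c1"),
      father_id = c(NA, NA, "p1"), mother_id = c(NA, NA, "p2"),
      sex = c("male", "female", "male")
    ),
    nuclear = {
      k <- config$n_children
      tibble(
        individual_id = c("p1", "p2", paste0("c", seq_len(k))),
        father_id = c(NA, NA, rep("p1", k)),
        mother_id = c(NA, NA, rep("p2", k)),
        sex = c("male", "female",
                rep_len(c("male", "female"), k))
      )
    },
    three_generation = tibble(
      individual_id = c("g1", "g2", "p1", "p2", "c1", "c2"),
      father_id = c(NA, NA, "g1", NA, "p1", "p1"),
      mother_id = c(NA, NA, "g2", NA, "p2", "p2"),
      sex = c("male", "female", "male", "female", "male", "female")
    )
  )
  ped <- purrr::map_dfr(seq_len(config$n_pedigrees), function(f) {
    fam <- sprintf("F%04d", f)
    dplyr::mutate(one,
      family_id = fam,
      individual_id = paste(fam, .data$individual_id, sep = "_"),
      father_id = ifelse(is.na(.data$father_id), NA,
                         paste(fam, .data$father_id, sep = "_")),
      mother_id = ifelse(is.na(.data$mother_id), NA,
                         paste(fam, .data$mother_id, sep = "_"))
    )
  })
  ped$affection <- NA_character_
  dplyr::select(ped, "family_id", "individual_id", "father_id", "mother_id",
                "sex", "affection")
}

#' Draw the fixed gene map of a simulated study
#'
#' Gene count, per-gene variant counts, positions, founder MAFs (mixed
#' rare/common spectrum), causal gene labels and per-variant effect sizes
#' are all drawn once under the configuration seed and then shared by
#' every replicate.
#'
#' @param config a [sim_config()].
#' @return a list with `regions` (BED-convention tibble), `variants`
#'   (list of per-gene tibbles: `pos`, `maf`, `is_rare`, `beta`,
#'   `carrier_effect`), and `causal_genes` (character vector).
#' @export
draw_gene_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gene_len <- 20000
  spacing <- 100000
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  start <- (seq_len(config$n_genes) - 1) * spacing
  regions <- tibble(gene = genes, chrom = "chr3",
                    start = start, end = start + gene_len)
  causal <- if (config$n_causal_genes > 0) {
    sort(sample(config$n_genes, config$n_causal_genes))
  } else integer(0)
  variants <- lapply(seq_len(config$n_genes), function(g) {
    m <- if (config$variants_per_gene[1] == config$variants_per_gene[2]) {
      config$variants_per_gene[1]
    } else {
      sample(seq(config$variants_per_gene[1], config$variants_per_gene[2]), 1)
    }
    pos <- sort(sample(seq_len(gene_len - 1), m)) + start[g]
    is_rare <- runif(m) < config$prop_rare
    maf <- ifelse(is_rare,
                  runif(m, config$rare_maf_range[1], config$rare_maf_range[2]),
                  runif(m, config$common_maf_range[1], config$common_maf_range[2]))
    beta <- rep(0, m)
    if (g %in% causal) {
      beta[!is_rare] <- config$beta_common
      sgn <- ifelse(runif(m) < config$rare_sign_mix, -1, 1)
      beta[is_rare] <- config$beta_rare * sgn[is_rare]
    }
    tibble(pos = pos, maf = maf, is_rare = is_rare, beta = beta,
           carrier_effect = is_rare)
  })
  list(regions = regions, variants = variants, causal_genes = genes[causal])
}

#' Gene dropping through a pedigree
#'
#' Simulates one gene: founder haplotypes are drawn per variant as
#' independent Bernoulli(MAF) alleles (linkage equilibrium among
#' founders) and each non-founder receives one allele per parent, chosen
#' per variant by an independent fair transmission coin.  Uses the
#' current RNG state.
#'
#' @param ped a pedigree tibble.
#' @param mafs founder minor-allele frequencies, one per variant.
#' @param positions 1-based variant positions (defaults to `1:m`).
#' @param gene,chrom labels for the resulting matrix.
#' @return a [gene_matrix()] (oriented, monomorphic columns dropped).
#'   The attribute `"raw"` holds the unfiltered simulated data: allele
#'   matrices `h1`/`h2` (counting the simulated minor allele), `dosage`,
#'   `pos` and `maf` -- used by the VCF writer and by the phenotype
#'   model, which acts on the simulated (not re-oriented) alleles.
#' @export
gene_drop <- function(ped, mafs, positions = NULL, gene = "gene",
                      chrom = "chr1") {
  m <- length(mafs)
  positions <- positions %||% seq_len(m)
  n <- nrow(ped)
  ids <- ped$individual_id
  idx <- setNames(seq_len(n), ids)
  h1 <- matrix(0L, n, m, dimnames = list(ids, NULL))
  h2 <- h1
  ord <- topo_order(ped)
  founders <- is.na(ped$father_id)
  nf <- sum(founders)
  h1[founders, ] <- rbinom(nf * m, 1, rep(mafs, each = nf))
  h2[founders, ] <- rbinom(nf * m, 1, rep(mafs, each = nf))
  for (i in ord[!founders[ord]]) {
    fa <- idx[[ped$father_id[i]]]
    mo <- idx[[ped$mother_id[i]]]
    coin_f <- runif(m) < 0.5
    coin_m <- runif(m) < 0.5
    h1[i, ] <- ifelse(coin_f, h1[fa, ], h2[fa, ])
    h2[i, ] <- ifelse(coin_m, h1[mo, ], h2[mo, ])
  }
  dosage <- h1 + h2
  gm <- gene_matrix(
    dosage,
    tibble(chrom = chrom, pos = positions, ref = "A", alt = "T",
           founder_maf = mafs),
    gene = gene
  )
  attr(gm, "raw") <- list(h1 = h1, h2 = h2, dosage = dosage,
                          pos = positions, maf = mafs, chrom = chrom)
  gm
}

#' Simulate the binary phenotype given causal genotypes
#'
#' Each individual's case probability is
#' `plogis(qlogis(prevalence) + sum of centered variant effects)`, where
#' a common causal variant contributes `beta * dosage` and a rare causal
#' variant `beta * carrier` (carrier = at least one minor allele).  Each
#' effect is centered at its founder-frequency expectation
#' (`2 * maf` copies, `1 - (1 - maf)^2` carrier probability) so that
#' `prevalence` remains the disease probability at the mean genotype no
#' matter how many causal variants the configuration carries.  Disease
#' status is then an independent Bernoulli draw given genotype: no shared
#' environment or polygenic term, so a null configuration is exactly
#' exchangeable.  Uses the current RNG state.
#'
#' @param ped pedigree tibble.
#' @param causal_matrices list of `gene_matrix` objects (from
#'   [gene_drop()]) for the causal genes, with their `"raw"` attribute.
#' @param causal_variants list (parallel to `causal_matrices`) of variant
#'   tibbles with `beta` and `carrier_effect` columns, as produced by
#'   [draw_gene_map()].
#' @param prevalence baseline probability.
#' @return tibble `family_id`, `individual_id`, `affection`.
#' @export
simulate_phenotype <- function(ped, causal_matrices = list(),
                               causal_variants = list(), prevalence = 0.3) {
  eta <- rep(qlogis(prevalence), nrow(ped))
  for (k in seq_along(causal_matrices)) {
    raw <- attr(causal_matrices[[k]], "raw")
    v <- causal_variants[[k]]
    stopifnot(nrow(v) == ncol(raw$dosage))
    act <- which(v$beta != 0)
    for (j in act) {
      if (v$carrier_effect[j]) {
        g <- as.numeric(raw$dosage[, j] > 0)
        mu <- 1 - (1 - raw$maf[j])^2
      } else {
        g <- raw$dosage[, j]
        mu <- 2 * raw$maf[j]
      }
      eta <- eta + v$beta[j] * (g - mu)
    }
  }
  y <- rbinom(nrow(ped), 1, plogis(eta))
  tibble(
    family_id = ped$family_id,
    individual_id = ped$individual_id,
    affection = ifelse(y == 1, "case", "control")
  )
}

#' Simulate one replicate of the study
#'
#' Redraws founder haplotypes, transmissions and phenotypes for a fixed
#' pedigree structure and gene map.  Each replicate gets its own RNG
#' substream derived from the configuration seed by a fixed offset, so
#' replicates are independent and individually reproducible.
#'
#' @param config a [sim_config()].
#' @param replicate replicate index (1-based).
#' @param map gene map from [draw_gene_map()] (recomputed if missing).
#' @param ped pedigree from [simulate_pedigrees()] (recomputed if
#'   missing).
#' @return list with `pedigree`, `matrices` (list of [gene_matrix()]),
#'   `phenotype`, `regions`, `causal_genes`, `replicate`.
#' @export
simulate_replicate <- function(config, replicate = 1, map = NULL, ped = NULL) {
  stopifnot(inherits(config, "sim_config"))
  map <- map %||% draw_gene_map(config)
  ped <- ped %||% simulate_pedigrees(config)
  set.seed(config$seed + 10007L * as.integer(replicate))
  matrices <- lapply(seq_len(config$n_genes), function(g) {
    gene_drop(ped, mafs = map$variants[[g]]$maf,
              positions = map$variants[[g]]$pos,
              gene = map$regions$gene[g], chrom = map$regions$chrom[g])
  })
  causal_idx <- match(map$causal_genes, map$regions$gene)
  phenotype <- simulate_phenotype(
    ped,
    causal_matrices = matrices[causal_idx],
    causal_variants = map$variants[causal_idx],
    prevalence = config$prevalence
  )
  list(pedigree = ped, matrices = matrices, phenotype = phenotype,
       regions = map$regions, causal_genes = map$causal_genes,
       replicate = as.integer(replicate))
}

#' Scan every replicate of a simulated study
#'
#' The in-memory simulate-then-scan pipeline: generates each replicate,
#' computes the case/control partition and its correction factor, runs
#' the four tests on every gene, and keeps only the per-gene results
#' (genotypes are discarded replicate by replicate, so memory stays
#' flat).
#'
#' @param config a [sim_config()].
#' @param rare_maf,variance_explained,sidak,tol test options, as in
#'   [scan_genome()].
#' @param progress print a line per replicate.
#' @return a `replicate_scans` tibble: the [scan_matrices()] columns plus
#'   `replicate`.  Attributes: `causal_genes`, `null_genes`, `config`.
#' @export
replicate_scans <- function(config, rare_maf = 0.01,
                            variance_explained = 0.85, sidak = FALSE,
                            tol = 1e-8, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  map <- draw_gene_map(config)
  ped <- simulate_pedigrees(config)
  phi <- kinship_matrix(ped)
  out <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    rep_data <- simulate_replicate(config, r, map = map, ped = ped)
    cases <- rep_data$phenotype$individual_id[rep_data$phenotype$affection == "case"]
    controls <- setdiff(ped$individual_id, cases)
    pc <- correction_factor(phi, cases, controls)
    sc <- scan_matrices(rep_data$matrices, cases, controls, pc,
                        chrom = map$regions$chrom, rare_maf = rare_maf,
                        variance_explained = variance_explained,
                        sidak = sidak, tol = tol,
                        n_genes_loaded = config$n_genes)
    sc <- as_tibble(sc)
    sc$replicate <- r
    out[[r]] <- sc
    if (progress) inform(sprintf("replicate %d/%d done", r, config$n_replicates))
  }
  res <- dplyr::bind_rows(out)
  structure(res,
            class = c("replicate_scans", class(tibble())),
            causal_genes = map$causal_genes,
            null_genes = setdiff(map$regions$gene, map$causal_genes),
            config = config)
}

#' Write a simulated study to disk
#'
#' Emits everything the file-based pipeline needs: one FAM and one BED
#' (structure and map are shared), one VCF and one phenotype TSV per
#' replicate, the causal gene list, and a YAML manifest recording the
#' seed and a configuration hash so the run can be reproduced
#' byte-identically.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return tibble of written files (`kind`, `replicate`, `path`),
#'   invisibly.
#' @export
generate_replicates <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  map <- draw_gene_map(config)
  ped <- simulate_pedigrees(config)
  files <- list()
  add <- function(kind, replicate, path) {
    files[[length(files) + 1L]] <<- tibble(kind = kind,
                                           replicate = replicate, path = path)
  }
  fam_path <- file.path(outdir, "pedigree.fam")
  write_fam(ped, fam_path); add("fam", NA_integer_, fam_path)
  bed_path <- file.path(outdir, "genes.bed")
  write_bed(map$regions, bed_path); add("bed", NA_integer_, bed_path)
  causal_path <- file.path(outdir, "causal_genes.txt")
  writeLines(map$causal_genes, causal_path)
  add("causal", NA_integer_, causal_path)
  for (r in seq_len(config$n_replicates)) {
    rep_data <- simulate_replicate(config, r, map = map, ped = ped)
    vcf_path <- file.path(outdir, sprintf("rep%03d.vcf", r))
    write_sim_vcf(rep_data$matrices, ped$individual_id, vcf_path)
    add("vcf", r, vcf_path)
    ph_path <- file.path(outdir, sprintf("rep%03d.pheno.tsv", r))
    write_pheno(rep_data$phenotype, ph_path)
    add("pheno", r, ph_path)
  }
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   config_hash = rlang::hash(unclass(config)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  add("manifest", NA_integer_, file.path(outdir, "manifest.yaml"))
  invisible(dplyr::bind_rows(files))
}
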