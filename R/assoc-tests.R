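#' Pedigree-adjusted generalized T-squared test
#'
#' Gene-based multivariate case-control test on all variant dosages of a
#' gene.  With case mean dosage vector minus control mean dosage vector
#' \eqn{d} and pooled within-group covariance \eqn{S},
#' \deqn{T^2 = \frac{n_A n_U}{n} d' S^{+} d}
#' where \eqn{S^{+}} is the Moore-Penrose pseudo-inverse (relative singular
#' value tolerance `tol`).  The family version divides by the kinship
#' correction factor, \eqn{T^2_F = T^2 / P_{corr}}, and is referred to a
#' chi-square distribution with degrees of freedom equal to the numerical
#' rank of \eqn{S}.
#'
#' @param x a [gene_matrix()].
#' @param cases,controls non-empty, disjoint id vectors, each of size
#'   >= 2 (the pooled covariance is inestimable otherwise).
#' @param p_corr the familial correction factor: either a number or the
#'   tibble returned by [correction_factor()].  1 for unrelated samples.
#' @param tol relative tolerance for the covariance pseudo-inverse.
#' @return a one-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `n_variants`, `p_corr`.
#' @export
t2_family <- function(x, cases, controls, p_corr = 1, tol = 1e-8) {
  pc <- as_p_corr(p_corr)
  grp <- check_groups(x, cases, controls)
  X <- x$dosage
  A <- X[grp$cases, , drop = FALSE]
  U <- X[grp$controls, , drop = FALSE]
  na <- nrow(A); nu <- nrow(U); n <- na + nu
  d <- colMeans(A) - colMeans(U)
  S <- ((na - 1) * stats::cov(A) + (nu - 1) * stats::cov(U)) / (n - 2)
  pi <- pseudo_inverse(S, tol = tol)
  stat <- (na * nu / n) * drop(t(d) %*% pi$pinv %*% d) / pc
  df <- max(pi$rank, 1L)
  test_result("T2F", stat, df, ncol(X), pc)
}

#' Collapse rare variants to a carrier indicator
#'
#' The combined multivariate and collapsing (CMC) reduction: columns with
#' minor allele frequency below `rare_maf` are replaced by a single 0/1
#' indicator of carrying at least one minor allele at any of them (a
#' mean-imputed fractional dosage > 0 counts as carrying); common columns
#' pass through unchanged.  With no rare columns the input is returned
#' as-is.
#'
#' @param x a [gene_matrix()].
#' @param rare_maf the rare-variant frequency threshold (default 0.01, the
#'   conventional "rare < 1%" cutoff).
#' @return a `gene_matrix` whose collapsed column (if any) has
#'   `collapsed = TRUE` in its variant metadata.
#' @export
cmc_collapse <- function(x, rare_maf = 0.01) {
  stopifnot(inherits(x, "gene_matrix"))
  rare <- x$variants$maf < rare_maf & !x$variants$collapsed
  if (!any(rare)) return(x)
  carrier <- as.numeric(rowSums(x$dosage[, rare, drop = FALSE] > 0) > 0)
  keep_dos <- x$dosage[, !rare, drop = FALSE]
  dosage <- cbind(keep_dos, rare_carrier = carrier)
  variants <- dplyr::bind_rows(
    x$variants[!rare, , drop = FALSE],
    tibble(
      chrom = if ("chrom" %in% names(x$variants))
        x$variants$chrom[which(rare)[1]] else NA_character_,
      pos = x$variants$pos[which(rare)[1]],
      maf = mean(carrier) / 2, minor_is_alt = NA, collapsed = TRUE
    )
  )
  structure(list(gene = x$gene, dosage = dosage, variants = variants),
            class = "gene_matrix")
}

#' Pedigree-adjusted CMC test
#'
#' Applies the rare-variant collapsing of [cmc_collapse()] and then the
#' multivariate machinery of [t2_family()] on the reduced matrix:
#' \eqn{T_{CMC,F} = T_{CMC} / P_{corr}}, with degrees of freedom the rank
#' of the reduced pooled covariance.  When the gene has no rare variants
#' the result equals [t2_family()] exactly.
#'
#' @inheritParams t2_family
#' @inheritParams cmc_collapse
#' @return a one-row tibble as in [t2_family()], with `method = "CMCF"`.
#'   `n_variants` is the number of original variants entering the test.
#' @export
cmc_family <- function(x, cases, controls, p_corr = 1, rare_maf = 0.01,
                       tol = 1e-8) {
  m0 <- n_variants(x)
  res <- t2_family(cmc_collapse(x, rare_maf), cases, controls,
                   p_corr = p_corr, tol = tol)
  res$method <- "CMCF"
  res$n_variants <- m0
  res
}

#' Pedigree-adjusted chi-square minimum test
#'
#' For each variant separately, builds the 2x2 minor/major allele-count
#' table for cases versus controls, computes the 1-df Pearson chi-square
#' (no continuity correction), divides by the correction factor, and takes
#' the upper-tail p-value.  The gene-level p-value is the minimum over
#' variants, with no within-gene multiplicity adjustment by default -- the
#' statistic is deliberately anti-conservative as a gene screen.  A
#' Sidak-adjusted variant (`sidak = TRUE`) replaces the minimum p by
#' \eqn{1 - (1 - p_{min})^m}.
#'
#' @inheritParams t2_family
#' @param sidak apply a Sidak within-gene correction to the minimum
#'   p-value (not the default).
#' @return a one-row tibble as in [t2_family()]: `statistic` is the
#'   corrected chi-square achieving the minimum p, `df = 1`.
#' @export
chi_min_family <- function(x, cases, controls, p_corr = 1, sidak = FALSE) {
  pc <- as_p_corr(p_corr)
  grp <- check_groups(x, cases, controls, min_size = 1L)
  m <- n_variants(x)
  stats_v <- vapply(seq_len(m), function(j) {
    variant_chisq(x$dosage[grp$cases, j], x$dosage[grp$controls, j])
  }, numeric(1)) / pc
  p_v <- chisq_upper(stats_v, 1)
  jmin <- which.min(p_v)
  p <- p_v[jmin]
  if (sidak) p <- 1 - (1 - p)^m
  out <- test_result("CHIMIN", stats_v[jmin], 1L, m, pc)
  out$p_value <- p
  out
}

# 1-df Pearson allele-count chi-square, fractional counts allowed.
variant_chisq <- function(dos_cases, dos_controls) {
  a <- sum(dos_cases); b <- 2 * length(dos_cases) - a
  c_ <- sum(dos_controls); d <- 2 * length(dos_controls) - c_
  n <- a + b + c_ + d
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (den <= 0) return(0)
  n * (a * d - b * c_)^2 / den
}

#' Run all four family tests on one gene
#'
#' Convenience wrapper running [t2_family()], [cmc_family()],
#' [fpca_family()] and [chi_min_family()] on the same gene matrix and
#' case/control partition.  FPCA is recorded as skipped (`NA` statistic
#' and p-value) for genes with fewer than 3 variants, where the functional
#' representation of the dosage profile cannot be estimated.
#'
#' @inheritParams t2_family
#' @inheritParams cmc_collapse
#' @inheritParams fpca_family
#' @param sidak see [chi_min_family()].
#' @return a four-row tibble (methods T2F, CMCF, FPCAF, CHIMIN).
#' @export
gene_tests <- function(x, cases, controls, p_corr = 1, rare_maf = 0.01,
                       variance_explained = 0.85, tol = 1e-8, sidak = FALSE) {
  fpca <- tryCatch(
    fpca_family(x, cases, controls, p_corr = p_corr,
                variance_explained = variance_explained),
    pedassoc_skip = function(cnd) {
      out <- test_result("FPCAF", NA_real_, NA_integer_, n_variants(x),
                         as_p_corr(p_corr))
      out$p_value <- NA_real_
      out
    }
  )
  dplyr::bind_rows(
    t2_family(x, cases, controls, p_corr = p_corr, tol = tol),
    cmc_family(x, cases, controls, p_corr = p_corr, rare_maf = rare_maf,
               tol = tol),
    fpca,
    chi_min_family(x, cases, controls, p_corr = p_corr, sidak = sidak)
  )
}

# ---- shared helpers ----

as_p_corr <- function(p_corr) {
  if (is.data.frame(p_corr)) p_corr <- p_corr$p_corr
  p_corr <- as.numeric(p_corr)
  stopifnot(length(p_corr) == 1, is.finite(p_corr), p_corr > 0)
  p_corr
}

check_groups <- function(x, cases, controls, min_size = 2L) {
  stopifnot(inherits(x, "gene_matrix"))
  if (n_variants(x) < 1) abort("gene matrix has no polymorphic variants")
  if (length(cases) < min_size || length(controls) < min_size) {
    abort(sprintf("each group needs >= %d individuals", min_size))
  }
  if (length(intersect(cases, controls)) > 0) {
    abort("case and control sets must be disjoint")
  }
  check_ids_present(c(cases, controls), rownames(x$dosage))
  list(cases = cases, controls = controls)
}

test_result <- function(method, stat, df, m, pc) {
  stat <- max(stat, 0)
  tibble(
    method = method,
    statistic = stat,
    df = as.integer(df),
    p_value = chisq_upper(stat, df),
    n_variants = as.integer(m),
    p_corr = pc
  )
}

skip_gene <- function(msg) {
  abort(msg, class = "pedassoc_skip")
}
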