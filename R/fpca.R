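#' Pedigree-adjusted functional principal component test
#'
#' Treats each individual's minor-allele dosages across the variant
#' positions of a gene as noisy evaluations of a smooth genotype function
#' and tests for a case-control difference in the leading functional
#' principal component scores.
#'
#' The procedure: (1) rescale variant positions within the gene to
#' \[0, 1\]; (2) fit each individual's dosage profile by least squares on
#' an order-4 (cubic) B-spline basis with `n_basis` functions (default
#' `min(m, 10)` for `m` variants); (3) extract functional principal
#' components of the fitted curves, using the basis Gram matrix as the
#' L2 inner product, and keep the smallest number K of components whose
#' eigenvalues cumulatively explain at least `variance_explained` of the
#' total variance; (4) form
#' \deqn{T_{FPCA} = \frac{n_A n_U}{n} \sum_{k=1}^{K}
#'   \frac{(\bar s_{A,k} - \bar s_{U,k})^2}{\hat\lambda_k}}
#' where \eqn{\bar s_{A,k}} is the mean case score on component k and
#' \eqn{\hat\lambda_k} the pooled within-group variance of that score;
#' (5) divide by the correction factor, \eqn{T_{FPCA,F} = T_{FPCA} /
#' P_{corr}}, with df = K.
#'
#' Genes with fewer than 3 variants are skipped (condition class
#' `pedassoc_skip`): too few points to estimate the functional form of the
#' allele counts along the gene.
#'
#' @inheritParams t2_family
#' @param variance_explained fraction of total functional variance the
#'   retained components must explain (default 0.85).
#' @param n_basis number of B-spline basis functions; default
#'   `min(n_variants, 10)`, floored at 4 (the order-4 minimum).
#' @return a one-row tibble as in [t2_family()] with `method = "FPCAF"`.
#' @export
fpca_family <- function(x, cases, controls, p_corr = 1,
                        variance_explained = 0.85, n_basis = NULL) {
  pc <- as_p_corr(p_corr)
  grp <- check_groups(x, cases, controls)
  m <- n_variants(x)
  if (m < 3) skip_gene(sprintf("gene '%s' has %d variant(s); FPCA needs >= 3",
                               x$gene, m))
  stopifnot(variance_explained > 0, variance_explained <= 1)
  nb <- n_basis %||% max(4L, min(m, 10L))
  scores <- fpca_scores(x$dosage, x$variants$pos, nb, variance_explained)
  if (is.null(scores)) skip_gene(sprintf("gene '%s' has zero functional variance",
                                         x$gene))
  S <- scores
  A <- S[grp$cases, , drop = FALSE]
  U <- S[grp$controls, , drop = FALSE]
  na <- nrow(A); nu <- nrow(U); n <- na + nu
  d <- colMeans(A) - colMeans(U)
  lam <- (colSums(scale(A, scale = FALSE)^2) +
            colSums(scale(U, scale = FALSE)^2)) / (n - 2)
  usable <- lam > 0
  if (!any(usable)) skip_gene(sprintf("gene '%s' has zero within-group score variance",
                                      x$gene))
  stat <- (na * nu / n) * sum(d[usable]^2 / lam[usable]) / pc
  test_result("FPCAF", stat, sum(usable), m, pc)
}

# Functional PC scores of the dosage profiles.
# Returns an n x K score matrix, or NULL if total variance is zero.
fpca_scores <- function(dosage, pos, n_basis, variance_explained) {
  t_ <- rescale_positions(pos)
  B <- bspline_basis(t_, n_basis)          # m x nb
  # per-individual least-squares coefficients: n x nb
  coefs <- dosage %*% t(pseudo_inverse(B)$pinv)
  W <- bspline_gram(t_, n_basis)           # nb x nb L2 inner product
  eW <- eigen(W, symmetric = TRUE)
  Whalf <- eW$vectors %*% (t(eW$vectors) * sqrt(pmax(eW$values, 0)))
  Cc <- sweep(coefs, 2, colMeans(coefs))
  M <- Cc %*% Whalf                        # curves in an orthonormal frame
  Sg <- crossprod(M) / (nrow(M) - 1)
  eS <- eigen(Sg, symmetric = TRUE)
  lam <- pmax(eS$values, 0)
  tot <- sum(lam)
  if (tot <= 0) return(NULL)
  K <- which(cumsum(lam) / tot >= variance_explained - 1e-12)[1]
  M %*% eS$vectors[, seq_len(K), drop = FALSE]
}

rescale_positions <- function(pos) {
  r <- range(pos)
  if (r[1] == r[2]) return(rep(0.5, length(pos)))
  (pos - r[1]) / (r[2] - r[1])
}

# Order-4 B-spline basis with `nb` functions on [0, 1], evaluated at t.
bspline_basis <- function(t_, nb) {
  knots <- bspline_knots(nb)
  splines::splineDesign(knots, t_, ord = 4, outer.ok = FALSE)
}

# Full knot sequence: boundary knots repeated 4 times, interior equispaced.
bspline_knots <- function(nb, ord = 4) {
  n_interior <- nb - ord
  if (n_interior < 0) {
    abort("n_basis must be >= 4 for an order-4 B-spline basis")
  }
  interior <- if (n_interior > 0) seq(0, 1, length.out = n_interior + 2)[-c(1, n_interior + 2)] else numeric(0)
  c(rep(0, ord), interior, rep(1, ord))
}

# Exact Gram matrix of the basis: entries are integrals over [0, 1] of
# basis products (piecewise degree-6 polynomials), by 4-point Gauss-
# Legendre quadrature on each knot interval (exact for degree <= 7).
bspline_gram <- function(t_, nb) {
  knots <- bspline_knots(nb)
  brk <- unique(knots)
  gl_x <- c(-0.8611363115940526, -0.3399810435848563,
            0.3399810435848563, 0.8611363115940526)
  gl_w <- c(0.3478548451374538, 0.6521451548625461,
            0.6521451548625461, 0.3478548451374538)
  W <- matrix(0, nb, nb)
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    xs <- (b - a) / 2 * gl_x + (a + b) / 2
    Bq <- splines::splineDesign(knots, xs, ord = 4)
    W <- W + (b - a) / 2 * crossprod(Bq * sqrt(gl_w), Bq * sqrt(gl_w))
  }
  (W + t(W)) / 2
}
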