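# Independent oracle implementations, deliberately written with different
# algorithms/primitives than the package code they check.

# Kinship by exhaustive enumeration of inheritance vectors: every founder
# allele gets a unique label, every non-founder meiosis is enumerated over
# both transmission choices, and phi_ij is the exact average probability
# that one allele sampled from i and one from j carry the same label.
oracle_kinship_enum <- function(ped) {
  n <- nrow(ped)
  ids <- ped$individual_id
  idx <- stats::setNames(seq_len(n), ids)
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  nonf <- which(!is.na(ped$father_id))
  founders <- which(is.na(ped$father_id))
  # founder allele labels
  lab1 <- lab2 <- integer(n)
  lab1[founders] <- seq_along(founders) * 2 - 1
  lab2[founders] <- seq_along(founders) * 2
  # order so parents resolve before children
  ord <- nonf[order(match(nonf, pedassoc:::topo_order(ped)))]
  k <- length(nonf)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  n_vec <- 4^k
  for (v in seq_len(n_vec) - 1) {
    bits <- (v %/% 4^(seq_len(k) - 1)) %% 4
    l1 <- lab1; l2 <- lab2
    for (t in seq_along(ord)) {
      i <- ord[t]
      b <- bits[match(i, ord)]
      l1[i] <- if (b %% 2 == 0) l1[fa[i]] else l2[fa[i]]
      l2[i] <- if (b %/% 2 == 0) l1[mo[i]] else l2[mo[i]]
    }
    for (i in seq_len(n)) for (j in i:n) {
      p <- mean(outer(c(l1[i], l2[i]), c(l1[j], l2[j]), "=="))
      phi[i, j] <- phi[i, j] + p
      phi[j, i] <- phi[i, j]
    }
  }
  phi / n_vec
}

# Random valid pedigree of n members: grows by adding either a founder or a
# child of two existing members (inbreeding loops allowed).
random_pedigree <- function(n, p_founder = 0.4) {
  fam <- "F1"
  father <- rep(NA_character_, n)
  mother <- rep(NA_character_, n)
  ids <- paste0("i", seq_len(n))
  for (i in seq_len(n)) {
    if (i <= 2 || stats::runif(1) < p_founder) next  # founder
    par <- sample(seq_len(i - 1), 2)
    father[i] <- ids[par[1]]
    mother[i] <- ids[par[2]]
  }
  tibble::tibble(
    family_id = fam, individual_id = ids, father_id = father,
    mother_id = mother,
    sex = sample(c("male", "female"), n, replace = TRUE),
    affection = NA_character_
  )
}

# Generalized T2 by explicit dense arithmetic (solve(), not the package's
# SVD pseudo-inverse); fixtures must have a non-singular pooled covariance.
oracle_t2 <- function(X, case_rows, control_rows) {
  A <- X[case_rows, , drop = FALSE]
  U <- X[control_rows, , drop = FALSE]
  na <- nrow(A); nu <- nrow(U); n <- na + nu
  d <- colMeans(A) - colMeans(U)
  center <- function(M) sweep(M, 2, colMeans(M))
  S <- (crossprod(center(A)) + crossprod(center(U))) / (n - 2)
  drop((na * nu / n) * t(d) %*% solve(S, d))
}

# 1-df Pearson chi-square on a 2x2 table of allele counts.
oracle_chisq_2x2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# FPCA statistic by independent dense linear algebra: same model
# (order-4 B-splines, L2 Gram metric, eigendecomposition of the smoothed
# covariance, pooled within-group score variance) but with the Gram matrix
# by composite Simpson quadrature and coefficients via qr.solve.
oracle_fpca_stat <- function(X, pos, case_rows, control_rows,
                             variance_explained = 0.85, n_basis = NULL) {
  m <- ncol(X)
  nb <- if (is.null(n_basis)) max(4, min(m, 10)) else n_basis
  t_ <- (pos - min(pos)) / (max(pos) - min(pos))
  knots <- c(rep(0, 4), if (nb > 4) seq(0, 1, length.out = nb - 2)[-c(1, nb - 2)],
             rep(1, 4))
  B <- splines::splineDesign(knots, t_, ord = 4)
  coefs <- t(apply(X, 1, function(x) qr.solve(B, x)))
  grid <- seq(0, 1, length.out = 2001)
  Bg <- splines::splineDesign(knots, grid, ord = 4)
  h <- grid[2] - grid[1]
  w <- c(1, rep(c(4, 2), length.out = length(grid) - 2), 1)
  w[length(w) - 1] <- 4
  W <- t(Bg) %*% (Bg * w) * h / 3
  eW <- eigen((W + t(W)) / 2, symmetric = TRUE)
  Wh <- eW$vectors %*% diag(sqrt(pmax(eW$values, 0))) %*% t(eW$vectors)
  M <- sweep(coefs, 2, colMeans(coefs)) %*% Wh
  eS <- eigen(crossprod(M) / (nrow(M) - 1), symmetric = TRUE)
  lam <- pmax(eS$values, 0)
  K <- which(cumsum(lam) / sum(lam) >= variance_explained - 1e-12)[1]
  S <- M %*% eS$vectors[, seq_len(K), drop = FALSE]
  A <- S[case_rows, , drop = FALSE]
  U <- S[control_rows, , drop = FALSE]
  na <- nrow(A); nu <- nrow(U); n <- na + nu
  d <- colMeans(A) - colMeans(U)
  lamk <- (colSums(sweep(A, 2, colMeans(A))^2) +
             colSums(sweep(U, 2, colMeans(U))^2)) / (n - 2)
  (na * nu / n) * sum(d^2 / lamk)
}

# Build an analysis-ready gene matrix from a plain dosage matrix.
make_gm <- function(dosage, pos = seq_len(ncol(dosage)), gene = "g") {
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  }
  gene_matrix(dosage, tibble::tibble(pos = pos), gene = gene)
}

# Unrelated singleton pedigree for n individuals (all founders).
singleton_pedigree <- function(ids) {
  tibble::tibble(
    family_id = paste0("F", seq_along(ids)), individual_id = ids,
    father_id = NA_character_, mother_id = NA_character_,
    sex = "male", affection = NA_character_
  )
}
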