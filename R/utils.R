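#' Moore-Penrose pseudo-inverse with numerical rank
#'
#' Singular values below `tol` times the largest are treated as zero.  Used
#' for the pooled covariance in the multivariate tests, where linkage
#' disequilibrium routinely makes the dosage covariance rank-deficient.
#'
#' @param x a numeric matrix.
#' @param tol relative singular-value tolerance.
#' @return list with `pinv` (the pseudo-inverse) and `rank` (numerical rank).
#' @keywords internal
#' @noRd
pseudo_inverse <- function(x, tol = 1e-8) {
  x <- as.matrix(x)
  sv <- svd(x)
  if (length(sv$d) == 0L || sv$d[1] <= 0) {
    return(list(pinv = matrix(0, ncol(x), nrow(x)), rank = 0L))
  }
  keep <- sv$d > tol * sv$d[1]
  r <- sum(keep)
  if (r == 0L) {
    return(list(pinv = matrix(0, ncol(x), nrow(x)), rank = 0L))
  }
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(pinv = pinv, rank = as.integer(r))
}

# Upper-tail chi-square p-value, tolerant of a zero statistic.
chisq_upper <- function(stat, df) {
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

# Stop unless `ids` are all rownames of the dosage matrix.
check_ids_present <- function(ids, have, what = "individual") {
  missing <- setdiff(ids, have)
  if (length(missing) > 0) {
    abort(sprintf(
      "%d %s id(s) not found: %s", length(missing), what,
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}
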