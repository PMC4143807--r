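#' Type I error estimate from replicate scans
#'
#' Proportion of (null gene x replicate) pairs with p <= alpha.  Pairs
#' where a method was skipped (NA p, e.g. FPCA on a gene with fewer than
#' 3 variants) are excluded from numerator and denominator, so methods
#' may have different denominators.  The binomial standard error
#' `sqrt(est (1 - est) / n_pairs)` is attached.
#'
#' @param scans a `replicate_scans` tibble from [replicate_scans()], or
#'   any tibble with columns `gene`, `method`, `p_value`, `replicate`.
#' @param method method name(s); default all present.
#' @param alpha significance level(s).
#' @param null_genes character vector of null gene names; defaults to the
#'   `null_genes` attribute of `scans`.
#' @param pool if `TRUE` (default) pool all gene x replicate pairs as
#'   Bernoulli trials; if `FALSE` average the per-replicate proportions
#'   (SE is then the standard error of the replicate mean).
#' @return tibble `method`, `alpha`, `estimate`, `se`, `n_pairs`.
#' @export
type1_error <- function(scans, method = NULL, alpha = 0.05,
                        null_genes = NULL, pool = TRUE) {
  genes <- null_genes %||% attr(scans, "null_genes")
  if (is.null(genes) || length(genes) == 0) {
    abort("no null genes: supply `null_genes` or use a replicate_scans object")
  }
  rejection_rate(scans, genes, method, alpha, pool)
}

#' Power estimate from replicate scans
#'
#' Proportion of (causal gene x replicate) pairs with p <= alpha; same
#' conventions as [type1_error()].
#'
#' @inheritParams type1_error
#' @param causal_genes character vector of causal gene names; defaults to
#'   the `causal_genes` attribute of `scans`.
#' @return tibble `method`, `alpha`, `estimate`, `se`, `n_pairs`.
#' @export
power_estimate <- function(scans, method = NULL, alpha = 0.05,
                           causal_genes = NULL, pool = TRUE) {
  genes <- causal_genes %||% attr(scans, "causal_genes")
  if (is.null(genes) || length(genes) == 0) {
    abort("no causal genes: supply `causal_genes` or use a replicate_scans object")
  }
  rejection_rate(scans, genes, method, alpha, pool)
}

rejection_rate <- function(scans, genes, method, alpha, pool) {
  tbl <- as_tibble(scans)
  if (!"replicate" %in% names(tbl)) tbl$replicate <- 1L
  tbl <- tbl[tbl$gene %in% genes & !is.na(tbl$p_value), , drop = FALSE]
  methods <- method %||% sort(unique(tbl$method))
  out <- purrr::map_dfr(methods, function(m) {
    sub <- tbl[tbl$method == m, , drop = FALSE]
    if (nrow(sub) == 0) abort(sprintf("no analyzable pairs for method '%s'", m))
    purrr::map_dfr(alpha, function(a) {
      if (pool) {
        n <- nrow(sub)
        est <- mean(sub$p_value <= a)
        se <- sqrt(est * (1 - est) / n)
      } else {
        per_rep <- tapply(sub$p_value <= a, sub$replicate, mean)
        n <- nrow(sub)
        est <- mean(per_rep)
        se <- if (length(per_rep) > 1) stats::sd(per_rep) / sqrt(length(per_rep)) else NA_real_
      }
      tibble(method = m, alpha = a, estimate = est, se = se, n_pairs = n)
    })
  })
  out
}

#' Type I error and power table across an alpha grid
#'
#' Reproduces the standard simulation-study summary: one row per method,
#' level and metric, with pooled gene x replicate estimates and binomial
#' standard errors.
#'
#' @inheritParams type1_error
#' @inheritParams power_estimate
#' @param alpha_grid significance levels (default 0.05, 0.01, 0.001,
#'   0.0001).
#' @return a `replicate_eval` tibble: `metric` ("type1" / "power"),
#'   `method`, `alpha`, `estimate`, `se`, `n_pairs`.
#' @export
evaluate_replicates <- function(scans, alpha_grid = c(0.05, 0.01, 0.001, 1e-4),
                                method = NULL, null_genes = NULL,
                                causal_genes = NULL, pool = TRUE) {
  null_genes <- null_genes %||% attr(scans, "null_genes")
  causal_genes <- causal_genes %||% attr(scans, "causal_genes")
  parts <- list()
  if (length(null_genes)) {
    t1 <- type1_error(scans, method, alpha_grid, null_genes, pool)
    t1$metric <- "type1"
    parts$t1 <- t1
  }
  if (length(causal_genes)) {
    pw <- power_estimate(scans, method, alpha_grid, causal_genes, pool)
    pw$metric <- "power"
    parts$pw <- pw
  }
  if (length(parts) == 0) abort("neither null nor causal genes available")
  out <- dplyr::bind_rows(parts) |>
    dplyr::select("metric", "method", "alpha", "estimate", "se", "n_pairs")
  structure(out, class = c("replicate_eval", class(tibble())))
}
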