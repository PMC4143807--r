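#' Tidy a genome scan
#'
#' @param x a `gene_scan`.
#' @param ... unused.
#' @return a plain tibble, one row per gene and method.
#' @method tidy gene_scan
#' @export
tidy.gene_scan <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a genome scan
#'
#' @param x a `gene_scan`.
#' @param alpha level used for the significance counts.
#' @param ... unused.
#' @return a one-row tibble: genes loaded/analyzed/skipped, cases,
#'   controls, the shared correction factor, the Bonferroni threshold at
#'   `alpha`, and per-method significant-gene counts at that threshold.
#' @method glance gene_scan
#' @export
glance.gene_scan <- function(x, alpha = 0.05, ...) {
  tbl <- as_tibble(x)
  n_loaded <- attr(x, "n_genes_loaded") %||% length(unique(tbl$gene))
  bonf <- bonferroni_threshold(n_loaded, alpha)
  counts <- count_significant(x, alpha = bonf)
  wide <- setNames(as.list(counts$n_significant),
                   paste0("n_sig_", tolower(counts$method)))
  dplyr::bind_cols(
    tibble(
      n_genes_loaded = n_loaded,
      n_genes_analyzed = length(unique(tbl$gene)),
      n_genes_skipped = nrow(attr(x, "skipped") %||% tibble()),
      n_cases = attr(x, "n_cases") %||% NA_integer_,
      n_controls = attr(x, "n_controls") %||% NA_integer_,
      p_corr = if (nrow(tbl)) tbl$p_corr[1] else NA_real_,
      bonferroni = bonf
    ),
    as_tibble(wide)
  )
}

#' Quantile-quantile plot of a genome scan
#'
#' Observed versus expected -log10 p-values per method, the standard
#' diagnostic for calibration and inflation of gene-based scans.
#'
#' @param object a `gene_scan`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gene_scan
#' @export
autoplot.gene_scan <- function(object, ...) {
  tbl <- as_tibble(object) |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::group_by(.data$method) |>
    dplyr::arrange(.data$p_value, .by_group = TRUE) |>
    dplyr::mutate(expected = (dplyr::row_number() - 0.5) / dplyr::n()) |>
    dplyr::ungroup()
  ggplot2::ggplot(tbl, ggplot2::aes(-log10(.data$expected),
                                    -log10(pmax(.data$p_value, 1e-300)))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)))
}

#' Tidy a replicate evaluation
#'
#' @param x a `replicate_eval`.
#' @param ... unused.
#' @return a plain tibble.
#' @method tidy replicate_eval
#' @export
tidy.replicate_eval <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a replicate evaluation
#'
#' @param x a `replicate_eval`.
#' @param ... unused.
#' @return a one-row tibble with the methods compared, the alpha grid,
#'   and pair counts.
#' @method glance replicate_eval
#' @export
glance.replicate_eval <- function(x, ...) {
  tbl <- as_tibble(x)
  tibble(
    n_methods = length(unique(tbl$method)),
    n_levels = length(unique(tbl$alpha)),
    n_null_pairs = max(c(tbl$n_pairs[tbl$metric == "type1"], 0)),
    n_causal_pairs = max(c(tbl$n_pairs[tbl$metric == "power"], 0))
  )
}

#' Plot type I error and power against the significance level
#'
#' Estimates with +/- 2 SE ribbons per method; the dashed identity line
#' marks nominal calibration for the type I error panel.
#'
#' @param object a `replicate_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot replicate_eval
#' @export
autoplot.replicate_eval <- function(object, ...) {
  tbl <- as_tibble(object)
  ggplot2::ggplot(tbl, ggplot2::aes(.data$alpha, .data$estimate,
                                    colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$estimate - 2 * .data$se, 0),
      ymax = pmin(.data$estimate + 2 * .data$se, 1))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "significance level", y = "rejection rate",
                  colour = NULL)
}
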