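#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result`.
#' @param fdr Highlight threshold on q (default 0.10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, fdr = 0.10, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$q < fdr
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Log2 fold change", y = "-log10 p",
                  colour = paste0("q < ", fdr),
                  title = paste("Model:", attr(object, "model"),
                                "term:", attr(object, "term"))) +
    ggplot2::theme_minimal()
}

#' Heat map of a rank-rank hypergeometric overlap grid
#'
#' @param object An `rrho_map` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rrho_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rank_a, y = .data$rank_b,
                               fill = .data$signed_log10p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "rank in list A (most up first)",
                  y = "rank in list B (most up first)",
                  fill = "signed -log10 p") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of SMR (or GWAS) records
#'
#' @param records Tibble with `variant_id`, `p`, and optionally `behavior`.
#' @param snp_meta Tibble with `snp_id`, `chrom`, `pos_bp`.
#' @param fdr_line Optional horizontal reference on q (drawn at the largest
#'   p with `q < fdr_line` when a `q` column is present).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(records, snp_meta, fdr_line = 0.10) {
  df <- dplyr::inner_join(records, snp_meta,
                          by = c(variant_id = "snp_id"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_bp,
                                        y = -log10(.data$p),
                                        colour = factor(.data$chrom))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "-log10 p", colour = "chrom") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if ("q" %in% names(df) && any(df$q < fdr_line)) {
    thr <- max(df$p[df$q < fdr_line])
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2)
  }
  p
}

#' Scatter of signed aFC predictions against observed line Log2FC
#'
#' @param segregation Output of [segregation_table()] (segregated rows are
#'   used).
#' @param f0_de Line-contrast `de_result`.
#' @return A ggplot object.
#' @export
plot_prediction_scatter <- function(segregation, f0_de) {
  j <- dplyr::inner_join(
    dplyr::filter(segregation, .data$segregated,
                  !is.na(.data$predicted_log2fc)),
    dplyr::select(tibble::as_tibble(f0_de), "gene_id", "log2fc"),
    by = "gene_id")
  ggplot2::ggplot(j, ggplot2::aes(x = .data$predicted_log2fc,
                                  y = .data$log2fc)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "predicted bLR vs bHR Log2FC (signed aFC)",
                  y = "observed bLR vs bHR Log2FC") +
    ggplot2::theme_minimal()
}
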