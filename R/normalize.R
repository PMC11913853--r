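#' Remove genes with low-level expression
#'
#' A gene is removed iff the proportion of samples with fewer than
#' `threshold` reads is at least `fraction` (boundary inclusive).
#'
#' @param counts Genes x samples integer matrix.
#' @param threshold Minimum read count (default 1).
#' @param fraction Removal fraction in `(0, 1]` (default 0.75).
#' @return The retained count matrix, with attributes `n_removed` and
#'   `removed_genes`.
#' @export
filter_low_expression <- function(counts, threshold = 1, fraction = 0.75) {
  stopifnot(is.matrix(counts))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  prop_low <- rowMeans(counts < threshold)
  keep <- prop_low < fraction
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed_genes") <- rownames(counts)[!keep]
  out
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scale factors computed by the TMM method (weighted trimmed
#' mean of log expression ratios against a reference sample), rescaled so
#' their geometric mean is 1.
#'
#' @param counts Genes x samples count matrix (>= 2 samples, positive
#'   library sizes).
#' @return Numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2, all(colSums(counts) > 0))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  unname(f)
}

#' Log2 counts per million
#'
#' \deqn{\log_2\left(\frac{c + p}{L f + 2p} \times 10^6\right)} with prior
#' count \eqn{p} (default 0.5), library size \eqn{L} and TMM factor \eqn{f}.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Per-sample normalization factors from [tmm_factors()].
#' @param lib_size Optional per-sample library sizes (default column sums).
#' @param prior_count Prior count (default 0.5).
#' @return Matrix of log2 CPM values.
#' @export
log2_cpm <- function(counts, factors = tmm_factors(counts),
                     lib_size = colSums(counts), prior_count = 0.5) {
  stopifnot(length(factors) == ncol(counts), length(lib_size) == ncol(counts))
  eff <- lib_size * factors
  log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
}
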