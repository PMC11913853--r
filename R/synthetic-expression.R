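AFC_CAP <- log2(100)

#' Simulate negative-binomial expression counts with planted cis effects
#'
#' Generative model per gene \eqn{g} and individual \eqn{i} with eVariant
#' dose \eqn{d_i}:
#' \deqn{\mu_{gi} = \mathrm{base}_g \cdot \frac{(2 - d_i) + d_i 2^{aFC_g}}{2}
#'   \cdot 2^{x_i^\top \gamma_g} \cdot \ell_i, \qquad
#'   y_{gi} \sim \mathrm{NB}(\mu_{gi}, \phi_g)}
#' so the log2 ratio of homozygote group means equals the planted allelic
#' fold change exactly in expectation. Gene dispersions are log-normal and
#' relative library sizes log-normal (CV about 0.3).
#'
#' @param dosages Individuals x SNPs dosage matrix (column names = SNP ids).
#' @param gene_annotation Tibble with `gene_id`, `chrom`, `tss`.
#' @param planted_eqtls Tibble with `gene_id`, `evariant_id`, `true_aFC`,
#'   `window_offset_bp`. Every eVariant must lie within 1 Mb of its gene's
#'   TSS; `|true_aFC|` must not exceed `log2(100)` (the estimator cap).
#' @param covariate_design Optional list: `design` (individuals x covariates
#'   numeric matrix) and `effect_sd` (per-covariate SD of gene-specific log2
#'   effects, recycled).
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters for the
#'   per-gene NB dispersion.
#' @param libsize_sdlog SD of log relative library size.
#' @param base_meanlog,base_sdlog Log-normal parameters for baseline means.
#' @param seed Integer seed.
#' @return List: `counts` (genes x samples integer matrix), `mu` (expected
#'   counts), `truth` (planted eQTL tibble), `lib_rel`, `dispersion`,
#'   `covariate_effects`.
#' @export
simulate_expression <- function(dosages, gene_annotation, planted_eqtls,
                                covariate_design = NULL,
                                dispersion_meanlog = log(0.08),
                                dispersion_sdlog = 0.5,
                                libsize_sdlog = 0.3,
                                base_meanlog = log(200), base_sdlog = 1,
                                seed = 1L) {
  if (nrow(planted_eqtls) > 0) {
    if (any(abs(planted_eqtls$true_aFC) > AFC_CAP)) {
      stop("|aFC| exceeds the estimator cap log2(100) = ", round(AFC_CAP, 2))
    }
    miss <- setdiff(planted_eqtls$evariant_id, colnames(dosages))
    if (length(miss)) stop("planted eVariant(s) absent from dosages: ",
                           paste(miss, collapse = ", "))
    off <- abs(planted_eqtls$window_offset_bp %||%
                 rep(0, nrow(planted_eqtls)))
    if (any(off > 1e6)) stop("planted eVariant outside the 1 Mb cis window")
  }
  set.seed(derive_seed(seed, "expression"))
  n <- nrow(dosages)
  genes <- gene_annotation$gene_id
  g_n <- length(genes)
  base <- stats::rlnorm(g_n, base_meanlog, base_sdlog)
  disp <- stats::rlnorm(g_n, dispersion_meanlog, dispersion_sdlog)
  lib_rel <- stats::rlnorm(n, 0, libsize_sdlog)

  cov_eff <- NULL
  log2_cov <- matrix(0, g_n, n)
  if (!is.null(covariate_design)) {
    X <- covariate_design$design
    stopifnot(nrow(X) == n)
    esd <- rep(covariate_design$effect_sd, length.out = ncol(X))
    cov_eff <- matrix(stats::rnorm(g_n * ncol(X), 0, rep(esd, each = g_n)),
                      g_n, ncol(X), dimnames = list(genes, colnames(X)))
    log2_cov <- cov_eff %*% t(X)
  }

  mu <- matrix(rep(base, n), g_n, n) * 2^log2_cov *
    matrix(rep(lib_rel, each = g_n), g_n, n)
  if (nrow(planted_eqtls) > 0) {
    for (k in seq_len(nrow(planted_eqtls))) {
      gi <- match(planted_eqtls$gene_id[k], genes)
      d <- dosages[, planted_eqtls$evariant_id[k]]
      afc <- planted_eqtls$true_aFC[k]
      mu[gi, ] <- mu[gi, ] * ((2 - d) + d * 2^afc) / 2
    }
  }
  counts <- matrix(stats::rnbinom(g_n * n, mu = mu, size = rep(1 / disp, n)),
                   g_n, n, dimnames = list(genes, rownames(dosages)))
  list(counts = counts, mu = mu, truth = planted_eqtls,
       lib_rel = lib_rel, dispersion = stats::setNames(disp, genes),
       covariate_effects = cov_eff)
}
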