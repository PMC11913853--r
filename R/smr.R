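#' Stand-in behavioral QTL scan
#'
#' Per-SNP OLS of a behavior on alternate-allele dosage plus covariates
#' (default sex), reporting beta, se and z. This is the summary-statistic
#' source for SMR when no external GWAS is supplied.
#'
#' @param behavior_vector Numeric behavior values (non-constant).
#' @param dosages Individuals x SNPs dosage matrix.
#' @param covariates Samples x covariates numeric matrix (may be `NULL`).
#' @param behavior_name Label carried into the records.
#' @return Tibble: `variant_id`, `behavior`, `beta`, `se`, `z`, `p`.
#' @export
behavior_qtl_scan <- function(behavior_vector, dosages, covariates = NULL,
                              behavior_name = "behavior") {
  if (stats::var(behavior_vector) == 0) stop("behavior is constant")
  stopifnot(length(behavior_vector) == nrow(dosages))
  fr <- fw_residuals(behavior_vector, dosages, covariates)
  gss <- colSums(fr$G^2)
  ok <- gss > 0
  beta <- se <- rep(NA_real_, ncol(dosages))
  beta[ok] <- colSums(fr$G[, ok, drop = FALSE] * fr$y) / gss[ok]
  rss <- sum(fr$y^2) - (beta[ok]^2 * gss[ok])
  se[ok] <- sqrt(pmax(rss, 0) / fr$df / gss[ok])
  z <- beta / se
  tibble::tibble(
    variant_id = colnames(dosages), behavior = behavior_name,
    beta = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z))
  )
}

#' Summary-data-based Mendelian randomization statistic
#'
#' \deqn{T_{SMR} = \frac{z_{eQTL}^2 z_{GWAS}^2}{z_{eQTL}^2 + z_{GWAS}^2}}
#' with the p-value from the upper tail of chi-squared (df = 1);
#' \eqn{0/0} is defined as 0 (p = 1).
#'
#' @param z_eqtl,z_gwas Finite z-scores (vectorized).
#' @return Tibble: `t_smr`, `p`.
#' @export
smr_statistic <- function(z_eqtl, z_gwas) {
  stopifnot(all(is.finite(z_eqtl)), all(is.finite(z_gwas)))
  denom <- z_eqtl^2 + z_gwas^2
  t_smr <- ifelse(denom == 0, 0, z_eqtl^2 * z_gwas^2 / denom)
  tibble::tibble(t_smr = t_smr,
                 p = stats::pchisq(t_smr, df = 1, lower.tail = FALSE))
}

#' BH correction of SMR records, within behavior
#'
#' @param records Tibble with `behavior` and `p` columns.
#' @param per_behavior Correct within each behavior separately (default).
#' @return `records` with a `q` column.
#' @export
smr_fdr <- function(records, per_behavior = TRUE) {
  if (per_behavior) {
    records |>
      dplyr::group_by(.data$behavior) |>
      dplyr::mutate(q = bh_fdr(.data$p)) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(records, q = bh_fdr(.data$p))
  }
}

#' Directional SMR statistic
#'
#' Signed square root of T on the z-scale:
#' \eqn{\mathrm{sign}(\beta_{eQTL}\beta_{GWAS})\sqrt{T}}; positive predicts
#' expression up with behavior up. A zero beta gives sign 0 and flags the
#' record. `scale = "t"` returns the signed T itself instead.
#'
#' @param beta_eqtl,beta_gwas Effect estimates.
#' @param t_smr Non-negative SMR statistic.
#' @param scale `"sqrt"` (default, z-scale) or `"t"`.
#' @return Numeric vector of signed statistics.
#' @export
directional_t <- function(beta_eqtl, beta_gwas, t_smr, scale = c("sqrt", "t")) {
  scale <- match.arg(scale)
  stopifnot(all(t_smr >= 0))
  s <- sign(beta_eqtl * beta_gwas)
  s * if (scale == "sqrt") sqrt(t_smr) else t_smr
}

#' Run SMR for every eGene top eVariant against every behavior
#'
#' @param eqtl_records `eqtl_result` rows (rank 0 used).
#' @param gwas_records Output of [behavior_qtl_scan()] stacked over
#'   behaviors (or an external GWAS summary table with the same columns).
#' @param egenes_only Restrict to eGenes (default `TRUE`).
#' @return `smr_result` tibble: `gene_id`, `variant_id`, `behavior`,
#'   `z_eqtl`, `z_gwas`, `t_smr`, `p`, `q`, `signed_t`, `flag_zero_beta`.
#' @export
run_smr <- function(eqtl_records, gwas_records, egenes_only = TRUE) {
  top <- dplyr::filter(eqtl_records, .data$rank == 0)
  if (egenes_only) top <- dplyr::filter(top, .data$egene)
  j <- top |>
    dplyr::select("gene_id", "variant_id", beta_eqtl = "beta", t_eqtl = "t") |>
    dplyr::inner_join(
      dplyr::select(gwas_records, "variant_id", "behavior",
                    beta_gwas = "beta", z_gwas = "z"),
      by = "variant_id", relationship = "many-to-many")
  st <- smr_statistic(j$t_eqtl, j$z_gwas)
  out <- j |>
    dplyr::mutate(z_eqtl = .data$t_eqtl, t_smr = st$t_smr, p = st$p,
                  signed_t = directional_t(.data$beta_eqtl, .data$beta_gwas,
                                           st$t_smr),
                  flag_zero_beta = .data$beta_eqtl == 0 | .data$beta_gwas == 0) |>
    dplyr::select("gene_id", "variant_id", "behavior", "z_eqtl", "z_gwas",
                  "t_smr", "p", "signed_t", "flag_zero_beta")
  out <- smr_fdr(out)
  structure(out, class = c("smr_result", class(out)))
}

#' Correlate directional SMR statistics with behavioral DE
#'
#' Pearson correlation, over genes, of the signed SMR statistic for one
#' behavior with that behavior's differential-expression Log2FC; optionally
#' restricted to a validated subset of genes (e.g. segregation-congruent
#' pairs).
#'
#' @param smr_records `smr_result` rows for one behavior.
#' @param f2_de `de_result` for the same behavior.
#' @param subset_genes Optional gene-id filter.
#' @return One-row tibble: `pearson_r`, `p`, `n_genes`, plus the per-gene
#'   scatter table as a list column `scatter`.
#' @export
directional_concordance <- function(smr_records, f2_de, subset_genes = NULL) {
  j <- dplyr::inner_join(
    dplyr::select(smr_records, "gene_id", "signed_t"),
    dplyr::select(f2_de, "gene_id", "log2fc"), by = "gene_id")
  if (!is.null(subset_genes)) j <- dplyr::filter(j, .data$gene_id %in% subset_genes)
  if (!nrow(j)) stop("no overlapping genes")
  if (nrow(j) < 10) stop("fewer than 10 shared genes")
  ct <- stats::cor.test(j$signed_t, j$log2fc)
  tibble::tibble(pearson_r = unname(ct$estimate), p = ct$p.value,
                 n_genes = nrow(j), scatter = list(j))
}
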