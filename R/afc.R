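#' Estimate allelic fold change for one gene-eVariant pair
#'
#' Additive cis-regulatory model: expected expression at alternate dose
#' \eqn{d} is \eqn{\mu(d) = c_r (2 - d) + c_a d} with
#' \eqn{aFC = \log_2(c_a / c_r)}. The fit minimizes least squares in log2
#' space on `count + 1` with additive covariate terms, profiling the linear
#' parameters and optimizing aFC on the box `[-log2(100), log2(100)]`
#' (deterministic golden-section search). A cap flag is set when the bound
#' binds.
#'
#' @param raw_counts_gene Raw counts for the gene (one value per sample).
#' @param dosage Alternate-allele dosage vector (polymorphic).
#' @param covariate_design Optional samples x covariates numeric matrix.
#' @return One-row tibble: `afc`, `log2_c_ref`, `cap_flag`,
#'   `flag_undefined` (all-zero counts).
#' @export
estimate_afc <- function(raw_counts_gene, dosage, covariate_design = NULL) {
  stopifnot(length(raw_counts_gene) == length(dosage),
            all(raw_counts_gene >= 0))
  if (stats::var(dosage) == 0) stop("dosage is monomorphic")
  if (all(raw_counts_gene == 0)) {
    return(tibble::tibble(afc = NA_real_, log2_c_ref = NA_real_,
                          cap_flag = FALSE, flag_undefined = TRUE))
  }
  z <- log2(raw_counts_gene + 1)
  X <- cbind(matrix(1, length(z), 1), covariate_design)
  qx <- qr(X)
  rss <- function(afc) {
    off <- log2((2 - dosage) + dosage * 2^afc)
    sum(qr.resid(qx, z - off)^2)
  }
  opt <- stats::optimize(rss, interval = c(-AFC_CAP, AFC_CAP), tol = 1e-9)
  afc <- opt$minimum
  # optimize() never lands exactly on the bounds: probe them
  if (rss(AFC_CAP) < opt$objective) afc <- AFC_CAP
  if (rss(-AFC_CAP) < min(opt$objective, rss(AFC_CAP))) afc <- -AFC_CAP
  cap <- abs(afc) >= AFC_CAP - 1e-6
  if (cap) afc <- sign(afc) * AFC_CAP
  off <- log2((2 - dosage) + dosage * 2^afc)
  b <- qr.coef(qx, z - off)
  tibble::tibble(afc = afc, log2_c_ref = unname(b[1]),
                 cap_flag = cap, flag_undefined = FALSE)
}

#' Per-line founder alternate-allele frequencies
#'
#' @param founder_dosages Individuals x SNPs dosage matrix (NA = missing).
#' @param line_labels "bHR"/"bLR" per individual (both lines required).
#' @param variant_ids Variants to extract.
#' @return Tibble: `variant_id`, `p_bHR`, `p_bLR`, `n_bHR`, `n_bLR`
#'   (non-missing individuals), `ho_bHR`, `ho_bLR` (observed
#'   heterozygosity).
#' @export
founder_allele_freqs <- function(founder_dosages, line_labels, variant_ids) {
  stopifnot(all(c("bHR", "bLR") %in% line_labels))
  miss <- setdiff(variant_ids, colnames(founder_dosages))
  if (length(miss)) stop("variant(s) absent: ", paste(miss, collapse = ", "))
  per_line <- function(line) {
    d <- founder_dosages[line_labels == line, variant_ids, drop = FALSE]
    n <- colSums(!is.na(d))
    list(p = colSums(d, na.rm = TRUE) / (2 * n), n = n,
         ho = colMeans(d == 1, na.rm = TRUE))
  }
  a <- per_line("bHR"); b <- per_line("bLR")
  tibble::tibble(
    variant_id = variant_ids,
    p_bHR = unname(a$p), p_bLR = unname(b$p),
    n_bHR = unname(a$n), n_bLR = unname(b$n),
    ho_bHR = unname(a$ho), ho_bLR = unname(b$ho)
  )
}

#' Hedrick's standardized G'st for two populations
#'
#' Nei-Chesser small-sample estimators of within- and total expected
#' heterozygosity (harmonic-mean sample size, observed-heterozygosity
#' correction), Hedrick's (2005) standardization, clipped to `[0, 1]`.
#' Both lines monomorphic for the same allele give 0 by definition.
#'
#' @param p1,p2 Alternate-allele frequencies in the two populations.
#' @param n1,n2 Individuals sampled per population (>= 1).
#' @param ho1,ho2 Observed heterozygosities (default: Hardy-Weinberg
#'   expectation at the population frequency).
#' @return G'st in `[0, 1]` (vectorized).
#' @export
gst_prime <- function(p1, p2, n1, n2,
                      ho1 = 2 * p1 * (1 - p1), ho2 = 2 * p2 * (1 - p2)) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1),
            all(n1 >= 1), all(n2 >= 1))
  k <- 2
  n_harm <- k / (1 / n1 + 1 / n2)
  ho_bar <- (ho1 + ho2) / 2
  hexp <- 1 - (p1^2 + (1 - p1)^2 + p2^2 + (1 - p2)^2) / 2
  hs <- (n_harm / (n_harm - 1)) * (hexp - ho_bar / (2 * n_harm))
  p_bar <- (p1 + p2) / 2
  ht <- 1 - (p_bar^2 + (1 - p_bar)^2) + hs / (n_harm * k) - ho_bar / (2 * n_harm * k)
  gst <- ifelse(ht <= 0, 0, (ht - hs) / ht)
  gp <- ifelse(hs >= 1, 1, gst * (k - 1 + hs) / ((k - 1) * (1 - hs)))
  gp[p1 == p2 & ho1 == ho2] <- 0
  pmin(pmax(gp, 0), 1)
}

#' Subset segregation records above the G'st threshold
#'
#' Strict inequality: records at exactly the threshold are excluded.
#'
#' @param records Tibble with a `gst_prime` column.
#' @param threshold Default 0.27.
#' @return The subset tibble.
#' @export
segregated_evariants <- function(records, threshold = 0.27) {
  dplyr::filter(records, .data$gst_prime > threshold)
}

#' Sign the allelic fold change onto the bLR-vs-bHR axis
#'
#' Predicted bLR-vs-bHR Log2FC = aFC x sign(p_bLR - p_bHR): positive means
#' predicted upregulation in bLR. Variants with equal line frequencies have
#' no direction and return `NA`.
#'
#' @param afc Allelic fold change (log2, alternate vs reference allele).
#' @param p_bHR,p_bLR Founder alternate-allele frequencies per line.
#' @return Numeric vector of predicted Log2FC (NA where directionless).
#' @export
signed_prediction <- function(afc, p_bHR, p_bLR) {
  ifelse(p_bLR == p_bHR, NA_real_, afc * sign(p_bLR - p_bHR))
}

#' Build the segregation/prediction table for eVariants
#'
#' Combines founder allele frequencies, G'st (with observed-heterozygosity
#' correction from the founder genotypes), the bLR-enriched allele call, and
#' the signed aFC prediction for a set of eGene-eVariant pairs.
#'
#' @param eqtl_afc Tibble with `gene_id`, `variant_id`, `afc`.
#' @param founder_dosages,line_labels As in [founder_allele_freqs()].
#' @param threshold G'st segregation threshold (default 0.27, strict).
#' @return Tibble with per-pair frequencies, `gst_prime`, `segregated`,
#'   `blr_enriched_allele` (`alt`/`ref`/`none`), `predicted_log2fc`.
#' @export
segregation_table <- function(eqtl_afc, founder_dosages, line_labels,
                              threshold = 0.27) {
  fr <- founder_allele_freqs(founder_dosages, line_labels,
                             unique(eqtl_afc$variant_id))
  fr$gst_prime <- gst_prime(fr$p_bHR, fr$p_bLR, fr$n_bHR, fr$n_bLR,
                            fr$ho_bHR, fr$ho_bLR)
  eqtl_afc |>
    dplyr::left_join(fr, by = "variant_id") |>
    dplyr::mutate(
      segregated = .data$gst_prime > threshold,
      blr_enriched_allele = dplyr::case_when(
        .data$p_bLR > .data$p_bHR ~ "alt",
        .data$p_bLR < .data$p_bHR ~ "ref",
        TRUE ~ "none"
      ),
      predicted_log2fc = signed_prediction(.data$afc, .data$p_bHR, .data$p_bLR)
    )
}

#' Concordance of signed aFC predictions with observed line DE
#'
#' @param predictions Tibble with `gene_id` and `predicted_log2fc`.
#' @param observed_f0_de `de_result` tibble (`gene_id`, `log2fc`).
#' @return One-row tibble: `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `sign_concordance`, `n_pairs`, plus a `congruent_genes` list column.
#' @export
prediction_concordance <- function(predictions, observed_f0_de) {
  j <- dplyr::inner_join(
    predictions[!is.na(predictions$predicted_log2fc),
                c("gene_id", "predicted_log2fc")],
    observed_f0_de[, c("gene_id", "log2fc")], by = "gene_id")
  if (!nrow(j)) stop("no overlapping gene-variant pairs")
  if (nrow(j) < 10) stop("fewer than 10 shared gene-variant pairs")
  pe <- stats::cor.test(j$predicted_log2fc, j$log2fc)
  rho <- suppressWarnings(
    stats::cor(j$predicted_log2fc, j$log2fc, method = "spearman"))
  congruent <- j$gene_id[sign(j$predicted_log2fc) == sign(j$log2fc)]
  tibble::tibble(
    pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
    spearman_rho = rho,
    sign_concordance = length(congruent) / nrow(j),
    n_pairs = nrow(j), congruent_genes = list(congruent)
  )
}
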