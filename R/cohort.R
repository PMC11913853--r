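#' Simulate a complete two-line cross cohort
#'
#' Orchestrates the full synthetic study: founder lines, F1/F2 intercross,
#' planted cis-eQTL and behavioral QTL architectures, negative-binomial
#' counts for founders and F2s, correlated behaviors, technical covariates,
#' and truth tables for every planted effect.
#'
#' The default planted architecture comprises `n_pleiotropic` candidate
#' genes whose eVariant is a line-fixed SNP that also shifts every behavior
#' (the causal-candidate scenario), `n_eqtl_background` genes with
#' non-segregated eVariants, and `n_eqtl_partial` genes with partially
#' segregated eVariants confined to the last chromosome, which carries no
#' behavioral QTLs and so acts as a negative control for colocalization.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param genome A `genome_config` (default desk scale: 3 chromosomes x
#'   2,000 SNPs x 100 genes).
#' @param lines A `founder_spec` (default 10 founders per line).
#' @param n_f1,n_f2 Cross sizes (defaults 50 and 250).
#' @param n_pleiotropic Planted pleiotropic candidate genes (default 10).
#' @param n_eqtl_background,n_eqtl_partial Additional planted eQTL genes with
#'   background / partially segregated eVariants.
#' @param afc_pleiotropic,afc_other Absolute planted allelic fold changes.
#' @param qtl_effect_sd Behavioral QTL effect per alternate dose, in units of
#'   the behavior noise SD (default 0.5).
#' @param sex_effect,polygenic_sd,noise_sd Behavior model parameters.
#' @param covariate_effect_sd SD of gene-specific log2 technical covariate
#'   effects on expression.
#' @return A list of class `sim_cohort`; see Details.
#' @export
simulate_cohort <- function(seed = 1L,
                            genome = genome_config(seed = seed),
                            lines = founder_spec(),
                            n_f1 = 50, n_f2 = 250,
                            n_pleiotropic = 10,
                            n_eqtl_background = 20, n_eqtl_partial = 10,
                            afc_pleiotropic = 1, afc_other = 0.75,
                            qtl_effect_sd = 0.5,
                            sex_effect = NULL, polygenic_sd = 0.7,
                            noise_sd = 1,
                            covariate_effect_sd = 0.15) {
  founders <- simulate_founder_lines(genome, lines, seed = seed)
  cross <- simulate_cross(founders, genome, n_f1 = n_f1, n_f2 = n_f2, seed = seed)
  set.seed(derive_seed(seed, "architecture"))

  snps <- genome$snps |>
    dplyr::left_join(founders$allele_freq_truth, by = "snp_id")
  genes <- genome$genes
  qtl_chroms <- seq_len(max(1, genome$n_chrom - 1))
  ctrl_chrom <- genome$n_chrom

  nearest_snp <- function(gene_rows, snp_pool) {
    purrr::pmap_chr(gene_rows[, c("chrom", "tss")], function(chrom, tss) {
      cand <- snp_pool[snp_pool$chrom == chrom &
                         abs(snp_pool$pos_bp - tss) <= 1e6, ]
      if (!nrow(cand)) return(NA_character_)
      cand$snp_id[which.min(abs(cand$pos_bp - tss))]
    })
  }

  # pleiotropic candidates: fixed-divergent eVariants on the QTL chromosomes
  fx_pool <- snps[snps$class == "fixed_divergent" & snps$chrom %in% qtl_chroms, ]
  pl_cand <- genes[genes$chrom %in% qtl_chroms, ]
  pl_cand$evariant_id <- nearest_snp(pl_cand, fx_pool)
  pl_cand <- pl_cand[!is.na(pl_cand$evariant_id), ]
  pl_cand <- pl_cand[!duplicated(pl_cand$evariant_id), ]
  if (nrow(pl_cand) < n_pleiotropic) {
    stop("genome too sparse for ", n_pleiotropic, " pleiotropic candidates")
  }
  pleio <- pl_cand[sample.int(nrow(pl_cand), n_pleiotropic), ]
  pleio$true_aFC <- sample(c(-1, 1), n_pleiotropic, replace = TRUE) * afc_pleiotropic
  pleio$class <- "pleiotropic"

  # background-eVariant eQTL genes (informative F2 MAF, no line segregation)
  bg_pool <- snps[snps$class == "background" &
                    snps$freq_bHR >= 0.2 & snps$freq_bHR <= 0.8, ]
  bg_cand <- genes[!genes$gene_id %in% pleio$gene_id, ]
  bg_cand$evariant_id <- nearest_snp(bg_cand, bg_pool)
  bg_cand <- bg_cand[!is.na(bg_cand$evariant_id) &
                       !duplicated(bg_cand$evariant_id), ]
  bg <- bg_cand[sample.int(nrow(bg_cand), min(n_eqtl_background, nrow(bg_cand))), ]
  bg$true_aFC <- sample(c(-1, 1), nrow(bg), replace = TRUE) * afc_other
  bg$class <- "eqtl_background"

  # partially segregated eVariants on the control chromosome
  pt_pool <- snps[snps$class == "partially_segregated" & snps$chrom == ctrl_chrom, ]
  pt_cand <- genes[genes$chrom == ctrl_chrom &
                     !genes$gene_id %in% c(pleio$gene_id, bg$gene_id), ]
  pt_cand$evariant_id <- nearest_snp(pt_cand, pt_pool)
  pt_cand <- pt_cand[!is.na(pt_cand$evariant_id) &
                       !duplicated(pt_cand$evariant_id), ]
  pt <- pt_cand[sample.int(nrow(pt_cand), min(n_eqtl_partial, nrow(pt_cand))), ]
  pt$true_aFC <- sample(c(-1, 1), nrow(pt), replace = TRUE) * afc_other
  pt$class <- "eqtl_partial"

  planted_eqtls <- dplyr::bind_rows(pleio, bg, pt) |>
    dplyr::left_join(snps[, c("snp_id", "pos_bp", "freq_bHR", "freq_bLR")],
                     by = c(evariant_id = "snp_id")) |>
    dplyr::mutate(window_offset_bp = .data$pos_bp - .data$tss) |>
    dplyr::select("gene_id", "evariant_id", "true_aFC", "window_offset_bp",
                  eqtl_class = "class", "freq_bHR", "freq_bLR")

  # behavioral QTLs: the pleiotropic eVariants, alt-allele effect aligned to
  # the line that carries the alternate allele
  behaviors <- behavior_names()
  conv <- default_sign_convention()
  pleio_freq <- planted_eqtls[planted_eqtls$eqtl_class == "pleiotropic", ]
  planted_qtls <- tidyr::expand_grid(
    variant_id = pleio_freq$evariant_id, behavior_name = behaviors
  ) |>
    dplyr::left_join(pleio_freq[, c("evariant_id", "gene_id", "freq_bHR", "freq_bLR")],
                     by = c(variant_id = "evariant_id")) |>
    dplyr::mutate(
      effect_size = qtl_effect_sd * noise_sd *
        sign_multiplier(conv, .data$behavior_name) *
        ifelse(.data$freq_bLR > .data$freq_bHR, 1, -1),
      pleiotropic_gene = .data$gene_id
    ) |>
    dplyr::select("variant_id", "behavior_name", "effect_size", "pleiotropic_gene")

  # phenotype/covariate table for founders + F2
  all_ids <- c(founders$sample_id, cross$sample_id)
  n_all <- length(all_ids)
  set.seed(derive_seed(seed, "covariates"))
  pheno <- tibble::tibble(
    sample_id = all_ids,
    generation = rep(c("F0", "F2"), c(length(founders$sample_id), n_f2)),
    line = c(founders$line, rep(NA_character_, n_f2)),
    sex = sample(rep_len(c("M", "F"), n_all)),
    pct_rRNA = stats::rlnorm(n_all, log(2), 0.3),
    pct_intergenic = stats::rnorm(n_all, 30, 4),
    dissector = sample(c("D1", "D2"), n_all, replace = TRUE),
    stgt_experience = sample(c("yes", "no"), n_all, replace = TRUE),
    seq_batch = sample(paste0("B", 1:3), n_all, replace = TRUE)
  )

  if (is.null(sex_effect)) {
    sex_effect <- stats::setNames(c(0, rep(0.3, 4)), behaviors)
  }
  all_dosage <- rbind(founders$dosage, cross$dosage)
  behav <- simulate_behavior(
    all_dosage, planted_qtls, pheno$sex,
    sex_effect = sex_effect, polygenic_sd = polygenic_sd, noise_sd = noise_sd,
    sign_convention = conv, behaviors = behaviors, seed = seed
  )
  pheno <- dplyr::bind_cols(pheno, behav)

  # expression counts with technical covariate effects
  X <- cbind(
    sex = as.integer(pheno$sex == "F"),
    rRNA = as.numeric(scale(pheno$pct_rRNA)),
    intergenic = as.numeric(scale(pheno$pct_intergenic)),
    dissector = as.integer(pheno$dissector == "D2"),
    stgt = as.integer(pheno$stgt_experience == "yes"),
    batch2 = as.integer(pheno$seq_batch == "B2"),
    batch3 = as.integer(pheno$seq_batch == "B3")
  )
  expr <- simulate_expression(
    all_dosage, genes, planted_eqtls,
    covariate_design = list(design = X, effect_sd = covariate_effect_sd),
    seed = seed
  )

  planted_line_de <- planted_eqtls |>
    dplyr::filter(.data$eqtl_class != "eqtl_background") |>
    dplyr::mutate(expected_f0_log2fc = .data$true_aFC *
                    (.data$freq_bLR - .data$freq_bHR)) |>
    dplyr::select("gene_id", "evariant_id", "expected_f0_log2fc")

  structure(
    list(
      genome = genome, founders = founders, cross = cross,
      phenotypes = pheno, counts = expr$counts,
      gene_annotation = genes,
      truth = list(
        planted_eqtls = planted_eqtls,
        planted_qtls = planted_qtls,
        planted_line_de = planted_line_de,
        allele_freqs = founders$allele_freq_truth,
        expression = expr[c("lib_rel", "dispersion")]
      ),
      seed = seed
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic two-line cross cohort\n")
  cat("  founders:", length(x$founders$sample_id),
      " F2:", length(x$cross$sample_id), "\n")
  cat("  SNPs:", nrow(x$genome$snps), " genes:", nrow(x$gene_annotation), "\n")
  cat("  planted eQTLs:", nrow(x$truth$planted_eqtls),
      " (pleiotropic:", sum(x$truth$planted_eqtls$eqtl_class == "pleiotropic"),
      ")\n")
  invisible(x)
}
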