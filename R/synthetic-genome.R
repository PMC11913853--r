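#' Genome configuration for the synthetic cross
#'
#' Defines a small multi-chromosome coordinate frame: SNP positions (bp and
#' centimorgan, uniform genetic map) and gene transcription start sites drawn
#' uniformly, strictly inside chromosome bounds. All positions are 1-based.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length_bp Physical length of each chromosome in bp.
#' @param chrom_length_cM Genetic length of each chromosome in centimorgans.
#' @param n_snps_per_chrom SNPs per chromosome.
#' @param n_genes_per_chrom Genes per chromosome.
#' @param seed Integer seed; the layout is fully reproducible.
#' @return A list of class `genome_config` with `snps` and `genes` tibbles
#'   and the scalar parameters.
#' @export
genome_config <- function(n_chrom = 3, chrom_length_bp = 1e8,
                          chrom_length_cM = 100, n_snps_per_chrom = 2000,
                          n_genes_per_chrom = 100, seed = 1L) {
  stopifnot(n_chrom >= 1, n_snps_per_chrom >= 1, n_genes_per_chrom >= 1,
            chrom_length_bp > 0, chrom_length_cM > 0)
  rng <- local({ set.seed(derive_seed(seed, "genome")); NULL })
  snps <- purrr::map_dfr(seq_len(n_chrom), function(ch) {
    pos <- sort(sample.int(chrom_length_bp - 2L, n_snps_per_chrom)) + 1L
    tibble::tibble(
      snp_id = sprintf("chr%d:%d", ch, pos),
      chrom = ch, pos_bp = pos,
      pos_cM = pos / chrom_length_bp * chrom_length_cM
    )
  })
  genes <- purrr::map_dfr(seq_len(n_chrom), function(ch) {
    tss <- sort(sample.int(chrom_length_bp - 2L, n_genes_per_chrom)) + 1L
    tibble::tibble(
      gene_id = sprintf("gene_%d_%03d", ch, seq_len(n_genes_per_chrom)),
      chrom = ch, tss = tss,
      strand = sample(c("+", "-"), n_genes_per_chrom, replace = TRUE)
    )
  })
  structure(
    list(snps = snps, genes = genes, n_chrom = n_chrom,
         chrom_length_bp = chrom_length_bp, chrom_length_cM = chrom_length_cM,
         seed = seed),
    class = "genome_config"
  )
}

#' Founder-line specification
#'
#' Two selectively bred lines are modelled through per-SNP allele frequencies:
#' a fraction of SNPs fixed for opposite alleles, a fraction with large but
#' incomplete divergence (default line frequencies 0 vs 0.55, which places
#' their differentiation near the segregation threshold used downstream), and
#' the remainder sharing a single background frequency drawn from a Beta
#' distribution.
#'
#' @param n_per_line Founders genotyped per line (default 10).
#' @param frac_fixed_divergent Proportion of SNPs fixed for opposite alleles.
#' @param frac_partially_segregated Proportion with frequencies 0 vs
#'   `partial_freq`.
#' @param partial_freq Alternate-allele frequency in the enriched line for
#'   partially segregated SNPs.
#' @param background_shape Two Beta shape parameters for shared background
#'   frequencies.
#' @return A list of class `founder_spec`.
#' @export
founder_spec <- function(n_per_line = 10, frac_fixed_divergent = 0.05,
                         frac_partially_segregated = 0.10,
                         partial_freq = 0.55,
                         background_shape = c(0.8, 0.8)) {
  stopifnot(n_per_line >= 1,
            frac_fixed_divergent >= 0, frac_partially_segregated >= 0,
            frac_fixed_divergent + frac_partially_segregated <= 1,
            partial_freq > 0, partial_freq < 1)
  structure(
    list(n_per_line = n_per_line,
         frac_fixed_divergent = frac_fixed_divergent,
         frac_partially_segregated = frac_partially_segregated,
         partial_freq = partial_freq,
         background_shape = background_shape),
    class = "founder_spec"
  )
}

#' Simulate founder-line genotypes
#'
#' Assigns every SNP a divergence class (deterministic counts, randomized
#' placement), draws line-specific alternate-allele frequencies, and samples
#' phased founder genotypes under Hardy-Weinberg equilibrium within line.
#' For fixed-divergent SNPs one line is homozygous reference and the other
#' homozygous alternate, with the enriched line randomized per SNP.
#'
#' @param genome A `genome_config`.
#' @param lines A `founder_spec`.
#' @param seed Integer seed.
#' @return A list with phased haplotype matrices `hap1`/`hap2`
#'   (individuals x SNPs, 0/1), `dosage`, `line` labels (bHR/bLR),
#'   `sample_id`, and an `allele_freq_truth` tibble
#'   (snp_id, class, freq_bHR, freq_bLR).
#' @export
simulate_founder_lines <- function(genome, lines, seed = 1L) {
  stopifnot(inherits(genome, "genome_config"), inherits(lines, "founder_spec"))
  n_snp <- nrow(genome$snps)
  if (n_snp < 1 || lines$n_per_line < 1) {
    stop("configuration error: need at least one SNP and one individual per line")
  }
  set.seed(derive_seed(seed, "founders"))
  n_fix <- round(lines$frac_fixed_divergent * n_snp)
  n_part <- round(lines$frac_partially_segregated * n_snp)
  class <- rep("background", n_snp)
  idx <- sample.int(n_snp, n_fix + n_part)
  class[idx[seq_len(n_fix)]] <- "fixed_divergent"
  if (n_part > 0) class[idx[n_fix + seq_len(n_part)]] <- "partially_segregated"

  freq_bHR <- freq_bLR <- numeric(n_snp)
  bg <- class == "background"
  shared <- stats::rbeta(sum(bg), lines$background_shape[1], lines$background_shape[2])
  freq_bHR[bg] <- freq_bLR[bg] <- shared
  # randomize which line carries the alternate allele
  fx <- which(class == "fixed_divergent")
  alt_in_bLR_fx <- stats::rbinom(length(fx), 1, 0.5) == 1
  freq_bLR[fx] <- ifelse(alt_in_bLR_fx, 1, 0)
  freq_bHR[fx] <- ifelse(alt_in_bLR_fx, 0, 1)
  pt <- which(class == "partially_segregated")
  alt_in_bLR_pt <- stats::rbinom(length(pt), 1, 0.5) == 1
  freq_bLR[pt] <- ifelse(alt_in_bLR_pt, lines$partial_freq, 0)
  freq_bHR[pt] <- ifelse(alt_in_bLR_pt, 0, lines$partial_freq)

  n <- lines$n_per_line
  draw_haps <- function(freqs, n_ind) {
    matrix(stats::rbinom(n_ind * length(freqs), 1, rep(freqs, each = n_ind)),
           nrow = n_ind)
  }
  hap1 <- rbind(draw_haps(freq_bHR, n), draw_haps(freq_bLR, n))
  hap2 <- rbind(draw_haps(freq_bHR, n), draw_haps(freq_bLR, n))
  colnames(hap1) <- colnames(hap2) <- genome$snps$snp_id
  line <- rep(c("bHR", "bLR"), each = n)
  sample_id <- sprintf("F0_%s_%02d", line, c(seq_len(n), seq_len(n)))
  rownames(hap1) <- rownames(hap2) <- sample_id
  list(
    hap1 = hap1, hap2 = hap2, dosage = hap1 + hap2,
    line = line, sample_id = sample_id,
    allele_freq_truth = tibble::tibble(
      snp_id = genome$snps$snp_id, class = class,
      freq_bHR = freq_bHR, freq_bLR = freq_bLR
    )
  )
}
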