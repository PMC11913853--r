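# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Default desk-scale cohort (3 chromosomes x 2,000 SNPs, 300 genes,
# 10+10 founders, 250 F2, 10 planted pleiotropic candidates).
default_cohort <- function(seed = 1L) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- simulate_cohort(seed = seed)
  .fixtures[[key]]
}

# One full triangulation of the default cohort, reused by several tests.
default_triangulation <- function(seed = 1L) {
  key <- paste0("tri_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- triangulate(default_cohort(seed), n_perm = 1000,
                                    seed = seed)
  }
  .fixtures[[key]]
}

# A small cohort for fast structural tests.
small_cohort <- function(seed = 7L) {
  key <- paste0("small_", seed)
  if (is.null(.fixtures[[key]])) {
    g <- genome_config(n_chrom = 2, chrom_length_bp = 5e7, chrom_length_cM = 60,
                       n_snps_per_chrom = 300, n_genes_per_chrom = 25,
                       seed = seed)
    .fixtures[[key]] <- simulate_cohort(
      seed = seed, genome = g, n_f1 = 20, n_f2 = 80,
      n_pleiotropic = 4, n_eqtl_background = 6, n_eqtl_partial = 4
    )
  }
  .fixtures[[key]]
}

# Simulate NB counts for a plain two-group design (F0-scale power checks).
sim_two_group_counts <- function(n_genes, n_per_group, planted_idx = integer(0),
                                 log2fc = 1, base_meanlog = log(200),
                                 dispersion = 0.08, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  base <- stats::rlnorm(n_genes, base_meanlog, 1)
  group <- rep(0:1, each = n_per_group)
  mu <- matrix(rep(base, n), n_genes, n)
  if (length(planted_idx)) {
    mu[planted_idx, group == 1] <- mu[planted_idx, group == 1] * 2^log2fc
  }
  counts <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / dispersion),
                   n_genes, n,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   paste0("s", seq_len(n))))
  list(counts = counts, group = group)
}

# Phenotype table wrapper so run_de() can be exercised on plain two-group data.
two_group_phenotypes <- function(group, generation = "F0") {
  n <- length(group)
  set.seed(42)
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    generation = generation,
    line = ifelse(group == 1, "bLR", "bHR"),
    sex = rep_len(c("M", "F"), n),
    pct_rRNA = stats::rlnorm(n, log(2), 0.3),
    pct_intergenic = stats::rnorm(n, 30, 4),
    dissector = rep_len(c("D1", "D2"), n),
    stgt_experience = rep_len(c("yes", "no"), n),
    seq_batch = rep_len(paste0("B", 1:3), n)
  )
}
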