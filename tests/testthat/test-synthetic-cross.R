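test_that("founder simulation plants divergence classes at exact counts", {
  g <- genome_config(n_chrom = 1, n_snps_per_chrom = 1000,
                     n_genes_per_chrom = 10, seed = 3)
  f <- simulate_founder_lines(g, founder_spec(frac_fixed_divergent = 0.1,
                                              frac_partially_segregated = 0.2),
                              seed = 3)
  tr <- f$allele_freq_truth
  expect_equal(sum(tr$class == "fixed_divergent"), 100)
  expect_equal(sum(tr$class == "partially_segregated"), 200)
  fx <- tr[tr$class == "fixed_divergent", ]
  # opposite fixation in the two lines
  expect_true(all(abs(fx$freq_bHR - fx$freq_bLR) == 1))
  # realized genotypes honor fixation
  idx <- match(fx$snp_id, colnames(f$dosage))
  d_bHR <- f$dosage[f$line == "bHR", idx, drop = FALSE]
  expect_true(all(d_bHR == rep(2 * fx$freq_bHR, each = nrow(d_bHR))))
  # reproducible under seed
  f2 <- simulate_founder_lines(g, founder_spec(frac_fixed_divergent = 0.1,
                                               frac_partially_segregated = 0.2),
                               seed = 3)
  expect_identical(f$dosage, f2$dosage)
})

test_that("gametes follow the Haldane model", {
  # two markers 50 cM apart: recombinant fraction (1 - exp(-1)) / 2
  map <- data.frame(chrom = 1, pos_cM = c(0, 50))
  h1 <- c(0L, 0L); h2 <- c(1L, 1L)
  set.seed(11)
  n <- 20000
  rec <- vapply(seq_len(n), function(i) {
    g <- make_gamete(h1, h2, map)
    g[1] != g[2]
  }, logical(1))
  p_exp <- (1 - exp(-1)) / 2
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(mean(rec) - p_exp), 3 * se)

  # zero-length chromosome: intact parental haplotype
  map0 <- data.frame(chrom = 1, pos_cM = c(0, 0, 0))
  set.seed(1)
  g0 <- make_gamete(c(0L, 1L, 0L), c(1L, 0L, 1L), map0)
  expect_true(identical(g0, c(0L, 1L, 0L)) || identical(g0, c(1L, 0L, 1L)))

  # fully homozygous parent: gamete identical regardless of crossovers
  set.seed(2)
  expect_identical(make_gamete(c(1L, 1L), c(1L, 1L), map), c(1L, 1L))

  expect_error(make_gamete(NULL, c(1L), map), "phased")
})

test_that("F2 segregation at fixed-divergent SNPs is Mendelian 1:2:1", {
  g <- genome_config(n_chrom = 1, n_snps_per_chrom = 50,
                     n_genes_per_chrom = 5, seed = 5)
  f <- simulate_founder_lines(g, founder_spec(frac_fixed_divergent = 0.2),
                              seed = 5)
  cr <- simulate_cross(f, g, n_f1 = 30, n_f2 = 2000, seed = 5)
  fx <- f$allele_freq_truth$snp_id[f$allele_freq_truth$class == "fixed_divergent"]
  # all F1 heterozygous at fixed-divergent SNPs
  f1_dos <- cr$f1$hap1 + cr$f1$hap2
  colnames(f1_dos) <- colnames(cr$dosage)
  expect_true(all(f1_dos[, fx] == 1))
  # genotype frequencies 1:2:1 by chi-squared goodness of fit
  s <- fx[1]
  tab <- tabulate(cr$dosage[, s] + 1, 3)
  gof <- chisq.test(tab, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)
  # alt-allele frequency 0.5 within 3 binomial SE
  af <- mean(cr$dosage[, fx]) / 2
  expect_lt(abs(af - 0.5), 3 * sqrt(0.25 / (2 * 2000)))
  expect_error(simulate_cross(f, g, n_f1 = 1, n_f2 = 10), "two F1")
})

test_that("every F2 allele traces to a recorded F1 parental haplotype", {
  co <- small_cohort()
  cr <- co$cross
  f1_ids <- cr$f1$parents$f1_id
  for (k in sample(seq_along(cr$sample_id), 10)) {
    p1 <- match(cr$pedigree$parent1[k], f1_ids)
    p2 <- match(cr$pedigree$parent2[k], f1_ids)
    ok1 <- cr$hap1[k, ] == cr$f1$hap1[p1, ] | cr$hap1[k, ] == cr$f1$hap2[p1, ]
    ok2 <- cr$hap2[k, ] == cr$f1$hap1[p2, ] | cr$hap2[k, ] == cr$f1$hap2[p2, ]
    expect_true(all(ok1) && all(ok2))
  }
})

test_that("behavior generator recovers planted effects and correlations", {
  set.seed(9)
  n <- 2000
  dos <- matrix(rbinom(n * 2, 2, 0.5), n, 2,
                dimnames = list(NULL, c("v1", "v2")))
  sex <- rep_len(c("M", "F"), n)
  # all effects zero: pure noise, near-zero cross-behavior correlation
  b0 <- simulate_behavior(dos, tibble::tibble(variant_id = character(),
                                              behavior_name = character(),
                                              effect_size = numeric()),
                          sex, sex_effect = 0, polygenic_sd = 0, noise_sd = 1,
                          seed = 4)
  expect_lt(abs(sd(b0$LocoScore) - 1), 0.1)
  expect_lt(abs(cor(b0$LocoScore, b0$PavCA_Index)), 3 / sqrt(n))
  # single QTL with effect +1 per alt dose: OLS recovers slope 1
  q <- tibble::tibble(variant_id = "v1", behavior_name = "EPM_TimeImmobile",
                      effect_size = 1)
  b1 <- simulate_behavior(dos, q, sex, sex_effect = 0, polygenic_sd = 0,
                          noise_sd = 1, seed = 4)
  fit <- summary(lm(b1$EPM_TimeImmobile ~ dos[, "v1"]))$coefficients
  expect_lt(abs(fit[2, 1] - 1), 3 * fit[2, 2])
  # dominant shared factor drives |correlation| toward 1, sign per convention
  b2 <- simulate_behavior(dos, q[0, ], sex, sex_effect = 0, polygenic_sd = 20,
                          noise_sd = 1, seed = 4)
  expect_gt(cor(b2$EPM_TimeImmobile, b2$EPM_PctOpenArms), -1)
  expect_lt(cor(b2$EPM_TimeImmobile, b2$EPM_PctOpenArms), -0.95)
  expect_gt(cor(b2$LocoScore, b2$EPM_PctOpenArms), 0.95)
  expect_error(
    simulate_behavior(dos, tibble::tibble(variant_id = "v1",
                                          behavior_name = "NotABehavior",
                                          effect_size = 1), sex),
    "unknown behavior")
})

test_that("expression generator honors the allelic fold change closed form", {
  set.seed(21)
  n <- 3000
  dos <- matrix(sample(c(0L, 2L), n, replace = TRUE), n, 1,
                dimnames = list(NULL, "v1"))
  ann <- tibble::tibble(gene_id = "g1", chrom = 1, tss = 1000)
  eq <- tibble::tibble(gene_id = "g1", evariant_id = "v1", true_aFC = 1,
                       window_offset_bp = 0)
  sim <- simulate_expression(dos, ann, eq, libsize_sdlog = 0,
                             dispersion_meanlog = log(0.05), seed = 2)
  m2 <- mean(sim$counts[1, dos == 2]); m0 <- mean(sim$counts[1, dos == 0])
  expect_lt(abs(log2(m2 / m0) - 1), 0.1)
  # dispersion -> 0 gives Poisson-like variance/mean
  sim0 <- simulate_expression(dos, ann, eq[0, ], libsize_sdlog = 0,
                              dispersion_meanlog = log(1e-8),
                              dispersion_sdlog = 0, seed = 3)
  vm <- var(sim0$counts[1, ]) / mean(sim0$counts[1, ])
  expect_lt(abs(vm - 1), 0.2)
  # aFC cap enforced
  expect_error(
    simulate_expression(dos, ann,
                        tibble::tibble(gene_id = "g1", evariant_id = "v1",
                                       true_aFC = 7, window_offset_bp = 0),
                        seed = 1),
    "cap")
})

test_that("PavCA index composite and class boundaries", {
  # perfectly lever-biased animal
  top <- compute_pavca_index(1, 0, 30, 0, 0, 8)
  expect_equal(top$pavca_index, 1)
  expect_equal(top$class, "ST")
  # symmetric animal
  mid <- compute_pavca_index(0.5, 0.5, 10, 10, 4, 4)
  expect_equal(mid$pavca_index, 0)
  expect_equal(mid$class, "IN")
  # all three components exactly 0.5: boundary not exceeded -> IN
  bd <- compute_pavca_index(0.75, 0.25, 30, 10, 4, 8)
  expect_equal(bd$prob_difference, 0.5)
  expect_equal(bd$response_bias, 0.5)
  expect_equal(bd$latency_score, 0.5)
  expect_equal(bd$pavca_index, 0.5)
  expect_equal(bd$class, "IN")
  # zero contacts flag
  z <- compute_pavca_index(0, 0, 0, 0, 8, 0)
  expect_true(z$flag_undefined_bias)
  expect_true(is.na(z$pavca_index))
})

test_that("identical seeds give bit-identical cohorts", {
  g <- genome_config(n_chrom = 2, chrom_length_bp = 2e7, chrom_length_cM = 40,
                     n_snps_per_chrom = 300, n_genes_per_chrom = 10, seed = 2)
  a <- simulate_cohort(seed = 2, genome = g, n_f1 = 10, n_f2 = 40,
                       n_pleiotropic = 2, n_eqtl_background = 2,
                       n_eqtl_partial = 0)
  b <- simulate_cohort(seed = 2, genome = g, n_f1 = 10, n_f2 = 40,
                       n_pleiotropic = 2, n_eqtl_background = 2,
                       n_eqtl_partial = 0)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cross$dosage, b$cross$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
})
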