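test_that("residualization is orthogonal to covariates", {
  set.seed(61)
  n <- 50
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  E <- matrix(rnorm(20 * n), 20, n)
  R <- residualize(E, X)
  expect_lt(max(abs(R %*% cbind(1, X))), 1e-8)
  # intercept only: centered expression
  R0 <- residualize(E, NULL)
  expect_equal(R0, E - rowMeans(E), tolerance = 1e-12)
  # expression exactly linear in a covariate vanishes
  E2 <- matrix(rep(X[, 1], 3), 3, n, byrow = TRUE)
  expect_lt(max(abs(residualize(E2, X))), 1e-10)
  expect_error(residualize(E, cbind(X, X[, 1])), "rank deficient")
})

test_that("rank-based inverse normal transform uses Blom scores", {
  out <- rint(c(5, 1, 9))
  expect_equal(round(out, 4), c(0, -0.8694, 0.8694))
  # monotone-transform invariance
  x <- rnorm(31)
  expect_equal(rint(x), rint(exp(x)))
  # mean 0 for odd n without ties
  expect_lt(abs(mean(rint(rnorm(31)))), 1e-6)
  expect_error(rint(rep(1, 5)), "constant")
})

test_that("LD pruning matches a brute-force check on a hand-built instance", {
  set.seed(62)
  n <- 200
  base <- rbinom(n, 2, 0.5)
  noisy <- function(r) ifelse(runif(n) < r, base, rbinom(n, 2, 0.5))
  dos <- cbind(s1 = base, s2 = base, s3 = noisy(0.9), s4 = rbinom(n, 2, 0.4),
               s5 = rbinom(n, 2, 0.3))
  kept <- ld_prune(dos, window_snps = 5, step = 1, r2_threshold = 0.5)
  # brute-force: no retained pair exceeds the threshold
  r2 <- cor(dos[, kept])^2
  expect_true(all(r2[upper.tri(r2)] <= 0.5))
  # duplicated column: exactly one copy removed, the first kept
  expect_true("s1" %in% kept)
  expect_false("s2" %in% kept)
  # mutually independent SNPs all retained
  ind <- sapply(1:6, function(i) rbinom(n, 2, 0.5))
  colnames(ind) <- paste0("i", 1:6)
  expect_equal(ld_prune(ind), colnames(ind))
})

test_that("PC covariates capture planted structure and are orthonormal", {
  set.seed(63)
  n <- 80
  spike <- rnorm(n)
  E <- matrix(rnorm(100 * n, sd = 0.3), 100, n) +
    outer(rnorm(100), spike)
  G <- matrix(rbinom(n * 50, 2, 0.5), n, 50)
  pcs <- compute_pc_covariates(E, G, n_pcs = 5)
  expect_equal(dim(pcs), c(n, 10))
  expect_equal(unname(crossprod(pcs[, 1:5])), diag(5), tolerance = 1e-8)
  expect_gt(abs(cor(pcs[, "exprPC1"], spike)), 0.95)
  expect_error(compute_pc_covariates(E[, 1:3], G[1:3, ], n_pcs = 5),
               "fewer dimensions")
})

test_that("nominal scan is a covariate-adjusted per-SNP regression", {
  set.seed(64)
  n <- 245
  G <- sapply(1:40, function(i) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("v", 1:40)
  covs <- cbind(rnorm(n))
  y <- 0.5 * G[, 5] + covs[, 1] + rnorm(n)
  sc <- nominal_scan(rint(y), G, covs)
  expect_equal(nrow(sc), 40)
  expect_equal(sc$variant_id[which.min(sc$p)], "v5")
  # agrees with lm() for one SNP
  ref <- summary(lm(rint(y) ~ G[, 7] + covs))$coefficients[2, ]
  row <- sc[sc$variant_id == "v7", ]
  expect_equal(row$beta, unname(ref[1]), tolerance = 1e-10)
  expect_equal(row$se, unname(ref[2]), tolerance = 1e-10)
  expect_equal(row$p, unname(ref[4]), tolerance = 1e-10)
})

test_that("permutation pass fits the single-SNP uniform null", {
  set.seed(65)
  n <- 200
  G <- matrix(rbinom(n, 2, 0.4), n, 1, dimnames = list(NULL, "v1"))
  y <- rnorm(n)
  rec <- permutation_pass(rint(y), G, NULL, n_perm = 2000, seed = 5)
  # minima from a single SNP are Uniform(0,1): Beta(1,1) within 20%
  expect_lt(abs(rec$beta_a - 1), 0.2)
  expect_lt(abs(rec$beta_b - 1), 0.2)
  expect_equal(rec$n_tested_snps, 1)
  expect_error(permutation_pass(rint(y), G, NULL, n_perm = 50), "n_perm")
})

test_that("beta-approximated p agrees with the rank-based permutation p", {
  set.seed(66)
  n <- 150
  diffs <- vapply(1:15, function(i) {
    G <- sapply(1:25, function(j) rbinom(n, 2, runif(1, 0.1, 0.5)))
    colnames(G) <- paste0("v", 1:25)
    y <- rnorm(n) + 0.25 * G[, 1] * rbinom(1, 1, 0.5)
    yr <- rint(y)
    rec <- permutation_pass(yr, G, NULL, n_perm = 1000, seed = i)
    # independent rank-based oracle
    set.seed(1000 + i)
    minp <- vapply(1:1000, function(k) {
      min(nominal_scan(sample(yr), G, NULL)$p)
    }, numeric(1))
    direct <- (1 + sum(minp <= rec$p_nominal)) / 1001
    rec$p_beta - direct
  }, numeric(1))
  expect_lt(mean(abs(diffs)), 0.02)
})

test_that("eGene FDR controls nulls and conditional scan separates signals", {
  set.seed(67)
  n <- 245
  # two independent planted eVariants in one window
  make_window <- function() {
    G <- sapply(1:30, function(j) rbinom(n, 2, 0.4))
    colnames(G) <- paste0("v", 1:30)
    G
  }
  hits <- vapply(1:8, function(i) {
    G <- make_window()
    # keep the two causal SNPs nearly uncorrelated
    y <- 0.8 * scale(G[, 3]) + 0.8 * scale(G[, 20]) + rnorm(n)
    yr <- rint(as.numeric(y))
    rec <- permutation_pass(yr, G, NULL, n_perm = 500, seed = i)
    cs <- conditional_scan(yr, G, NULL, rec, alpha = 0.05, seed = i)
    found <- c(rec$variant_id, if (nrow(cs)) cs$variant_id)
    all(c("v3", "v20") %in% found)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # single causal SNP: conditional scan usually returns nothing
  extra <- vapply(1:10, function(i) {
    G <- make_window()
    y <- 0.8 * scale(G[, 3]) + rnorm(n)
    yr <- rint(as.numeric(y))
    rec <- permutation_pass(yr, G, NULL, n_perm = 500, seed = 100 + i)
    cs <- conditional_scan(yr, G, NULL, rec, alpha = 0.05, seed = i)
    nrow(cs)
  }, numeric(1))
  expect_gte(mean(extra == 0), 0.9)
  # a second signal in perfect LD with the first is never reported
  G <- make_window()
  G[, 21] <- G[, 3]
  y <- 1 * scale(G[, 3]) + rnorm(n)
  yr <- rint(as.numeric(y))
  rec <- permutation_pass(yr, G, NULL, n_perm = 500, seed = 9)
  cs <- conditional_scan(yr, G, NULL, rec, alpha = 0.05, seed = 9)
  extra_ids <- if (nrow(cs)) cs$variant_id else character(0)
  expect_false(any(c("v3", "v21") %in% extra_ids))
})

test_that("perfect-LD ties resolve uniformly and reproducibly", {
  picks <- vapply(1:1000, function(i) {
    resolve_perfect_ld(c("a", "b"), seed = i)
  }, character(1))
  p <- mean(picks == "a")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 1000))
  expect_identical(resolve_perfect_ld(c("a", "b"), seed = 7),
                   resolve_perfect_ld(c("a", "b"), seed = 7))
  expect_identical(resolve_perfect_ld("only", seed = 1), "only")
  expect_error(resolve_perfect_ld(character(0)), "empty")
})

test_that("cis mapping recovers planted eGenes and is sample-order invariant", {
  co <- small_cohort()
  ph <- co$phenotypes[co$phenotypes$generation == "F2", ]
  counts <- co$counts[, ph$sample_id]
  kept <- filter_low_expression(counts)
  lcpm <- log2_cpm(kept, tmm_factors(kept))
  X <- cbind(sex = as.integer(ph$sex == "F"))
  snps <- co$genome$snps[, c("snp_id", "chrom", "pos_bp")]
  res <- map_cis_eqtls(lcpm, co$cross$dosage, snps, co$gene_annotation,
                       covariate_design = X, n_perm = 200, n_pcs = 3,
                       seed = 1)
  truth <- co$truth$planted_eqtls
  top <- res[res$rank == 0, ]
  # pleiotropic genes carry |aFC| = 1 at MAF 0.5: high power even in the
  # small cohort; the weaker planted classes at least dominate chance
  pleio <- truth$gene_id[truth$eqtl_class == "pleiotropic"]
  expect_gte(mean(pleio %in% top$gene_id[top$egene]), 0.75)
  expect_gt(mean(truth$gene_id %in% top$gene_id[top$egene]), 0.5)
  # empirical p monotone in nominal p given (a, b): spot-check
  g1 <- top$gene_id[1]
  expect_true(all(top$p_beta >= 0 & top$p_beta <= 1))
  # consistent sample permutation: identical nominal stats, stable calls for
  # planted genes (the permutation null is re-drawn, so p_beta moves only
  # within Monte Carlo error)
  perm <- sample(nrow(co$cross$dosage))
  res2 <- map_cis_eqtls(lcpm[, perm], co$cross$dosage[perm, ], snps,
                        co$gene_annotation,
                        covariate_design = X[perm, , drop = FALSE],
                        n_perm = 200, n_pcs = 3, seed = 1)
  top2 <- res2[res2$rank == 0, ]
  m <- match(top$gene_id, top2$gene_id)
  expect_equal(top$p_nominal, top2$p_nominal[m], tolerance = 1e-8)
  expect_equal(top$variant_id, top2$variant_id[m])
  strong <- top$p_beta < 0.005
  expect_true(all(top2$egene[m][strong]))
})
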