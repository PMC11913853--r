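fake_de <- function(gene_id, log2fc, p = NULL, q = NULL, t = NULL) {
  tibble::tibble(gene_id = gene_id, log2fc = log2fc,
                 p = p %||% rep(0.5, length(gene_id)),
                 q = q %||% rep(0.5, length(gene_id)),
                 t = t %||% log2fc)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("Log2FC concordance matches by gene id, not order", {
  set.seed(41)
  g <- paste0("g", 1:50)
  a <- fake_de(g, rnorm(50))
  b <- a[sample(50), ]
  cc <- log2fc_concordance(a, b)
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$spearman_rho, 1)
  expect_equal(cc$n_shared_genes, 50)
  b2 <- a; b2$log2fc <- -b2$log2fc
  expect_equal(log2fc_concordance(a, b2)$pearson_r, -1)
  # two independent nulls
  c2 <- fake_de(g, rnorm(50))
  expect_lt(abs(log2fc_concordance(a, c2)$pearson_r), 3 / sqrt(50))
  expect_error(log2fc_concordance(a, fake_de("zz", 1)), "shared")
})

test_that("RRHO cells equal the exact hypergeometric tail", {
  set.seed(42)
  n <- 100
  g <- paste0("g", 1:n)
  s <- stats::setNames(rnorm(n), g)
  # identical rankings: top-10 vs top-10 overlap is 10
  m <- rrho_map(s, s, step = 10)
  cell <- m[m$rank_a == 10 & m$rank_b == 10, ]
  expect_equal(cell$overlap, 10)
  # oracle: P(X >= 10) with N=100, K=10, n=10
  p_oracle <- sum(dhyper(10, 10, 90, 10))
  expect_equal(cell$signed_log10p, -log10(p_oracle), tolerance = 1e-9)
  # self-map symmetric about the diagonal
  mat <- tidyr::pivot_wider(tibble::as_tibble(m)[, c("rank_a", "rank_b", "signed_log10p")],
                            names_from = "rank_b", values_from = "signed_log10p")
  mm <- unname(as.matrix(mat[, -1]))
  expect_equal(mm, t(mm), tolerance = 1e-9)
  # reversed ranking: overlaps fall to their minimum, so the map shows
  # strong depletion along the diagonal (the anti-concordance signature)
  rev_m <- rrho_map(s, -s, step = 10)
  corner <- rev_m[rev_m$rank_a == 10 & rev_m$rank_b == 10, ]
  expect_lt(corner$signed_log10p, 0)
  mid <- rev_m[rev_m$rank_a == 50 & rev_m$rank_b == 50, ]
  expect_lt(mid$signed_log10p, -10)
  expect_error(rrho_map(s, s, step = 0), "step")
})

test_that("independent rankings rarely exceed the Bonferroni threshold", {
  set.seed(43)
  n <- 200
  hits <- vapply(1:40, function(i) {
    a <- stats::setNames(rnorm(n), paste0("g", 1:n))
    b <- stats::setNames(rnorm(n), paste0("g", 1:n))
    m <- rrho_map(a, b, step = 20)
    thr <- -log10(0.05 / nrow(m))
    max(abs(m$signed_log10p)) > thr
  }, logical(1))
  expect_lt(mean(hits), 0.25)
})

test_that("DEG set applies the three-clause rule", {
  f0 <- fake_de(c("a", "b", "c", "d"), c(1, 1, -1, 1),
                p = c(0.001, 0.04, 0.04, 0.04),
                q = c(0.05, 0.4, 0.4, 0.4))
  meta <- fake_de(c("a", "b", "c", "d"), c(1, -1, -1, 1),
                  p = c(0.5, 0.04, 0.04, 0.2),
                  q = c(0.9, 0.4, 0.4, 0.4))
  deg <- define_deg_set(f0, meta)
  expect_setequal(deg$gene_id, c("a", "c"))
  expect_equal(deg$provenance[deg$gene_id == "a"], "FDR_F0")
  # b: nominal both but opposite signs -> excluded
  expect_false("b" %in% deg$gene_id)
  # c: nominal both, same sign
  expect_equal(deg$provenance[deg$gene_id == "c"], "nominal_both_consistent")
  # monotone: loosening thresholds never removes members
  deg_loose <- define_deg_set(f0, meta, fdr = 0.5, nominal = 0.3)
  expect_true(all(deg$gene_id %in% deg_loose$gene_id))
})

test_that("behavior concordance flags respect the sign convention", {
  deg <- tibble::tibble(gene_id = c("up1", "up2", "dn1"),
                        provenance = "FDR_F0", direction = c(1, 1, -1))
  mk <- function(tv, pv) fake_de(c("up1", "up2", "dn1"), tv, p = pv, t = tv)
  f2 <- list(
    # negative LocoScore association is bLR-like
    LocoScore = mk(c(-3, 0.1, 1), c(0.01, 0.9, 0.5)),
    EPM_DistanceTraveled = mk(c(0, 0, 0.5), c(0.9, 0.9, 0.9)),
    EPM_TimeImmobile = mk(c(0.2, 0, 0), c(0.6, 0.9, 0.9)),
    # positive open-arms association is bHR-like
    EPM_PctOpenArms = mk(c(0, 0, 2.5), c(0.9, 0.9, 0.03)),
    PavCA_Index = mk(c(0, 2.2, 0), c(0.9, 0.01, 0.9))
  )
  fl <- behavior_concordance_flags(deg, f2)
  expect_equal(fl$flag[fl$gene_id == "up1"], "bLR_like")
  # up2: only PavCA positive (bHR-like direction) -> discordant with bLR-up
  expect_equal(fl$flag[fl$gene_id == "up2"], "none")
  expect_equal(fl$flag[fl$gene_id == "dn1"], "bHR_like")
  expect_error(behavior_concordance_flags(deg, f2[-1]), "missing behavior")
})

test_that("overlap enrichment equals brute-force table enumeration", {
  universe <- paste0("g", 1:8)
  set1 <- universe[1:4]
  set2 <- universe[c(1:3, 5)]  # table (3,1;1,3)
  res <- overlap_enrichment(set1, set2, universe)
  expect_equal(res$odds_ratio, 9)
  expect_equal(res$p, 34 / 70, tolerance = 1e-12)
  # brute force over all tables with fixed margins (N <= 40 instances)
  brute_p <- function(k, K, n, N) {
    probs <- dhyper(0:min(K, n), K, N - K, n)
    sum(probs[probs <= dhyper(k, K, N - K, n) * (1 + 1e-7)])
  }
  set.seed(44)
  for (i in 1:20) {
    N <- sample(10:40, 1)
    u <- paste0("x", 1:N)
    s1 <- sample(u, sample(2:(N - 2), 1))
    s2 <- sample(u, sample(2:(N - 2), 1))
    r <- overlap_enrichment(s1, s2, u)
    expect_equal(r$p, brute_p(length(intersect(s1, s2)), length(s1),
                              length(s2), N), tolerance = 1e-9)
  }
  # degenerate case
  dg <- overlap_enrichment(universe, universe, universe)
  expect_true(dg$degenerate)
  expect_error(overlap_enrichment("a", "a", character(0)), "universe")
})

test_that("null overlap p-values are uniform", {
  set.seed(45)
  u <- paste0("g", 1:60)
  ps <- vapply(1:200, function(i) {
    overlap_enrichment(sample(u, 20), sample(u, 20), u)$p
  }, numeric(1))
  # exact-test p-values are discrete and conservative: the rejection rate at
  # any level must not exceed that level (within binomial error)
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_lte(mean(ps < 0.20), 0.20 + 3 * sqrt(0.2 * 0.8 / 200))
  expect_gt(mean(ps), 0.4)
})
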