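#' Residualize expression on technical covariates
#'
#' Per-gene OLS residuals against the covariate design (intercept added);
#' residuals are numerically orthogonal to every covariate column.
#'
#' @param expression_matrix Genes x samples matrix.
#' @param covariate_design Samples x covariates numeric matrix (no
#'   intercept column needed).
#' @return Genes x samples residual matrix.
#' @export
residualize <- function(expression_matrix, covariate_design) {
  n <- ncol(expression_matrix)
  X <- cbind(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
             covariate_design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate design is rank deficient")
  t(qr.resid(qx, t(expression_matrix)))
}

#' Greedy windowed linkage-disequilibrium pruning
#'
#' Slides a window of `window_snps` SNPs with step `step`; within each
#' window any pair with squared correlation above `r2_threshold` loses its
#' later member. Deterministic given the input column order.
#'
#' @param dosages Individuals x SNPs dosage matrix (>= 2 SNPs).
#' @param window_snps,step,r2_threshold Pruning parameters
#'   (defaults 50, 5, 0.5).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(dosages, window_snps = 50, step = 5, r2_threshold = 0.5) {
  p <- ncol(dosages)
  stopifnot(p >= 2)
  removed <- logical(p)
  start <- 1L
  repeat {
    end <- min(start + window_snps - 1L, p)
    idx <- setdiff(start:end, which(removed))
    if (length(idx) > 1) {
      r2 <- suppressWarnings(stats::cor(dosages[, idx, drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      for (a in seq_len(length(idx) - 1)) {
        if (removed[idx[a]]) next
        hits <- which(r2[a, ] > r2_threshold)
        hits <- hits[hits > a & !removed[idx[hits]]]
        removed[idx[hits]] <- TRUE
      }
    }
    if (end == p) break
    start <- start + step
  }
  colnames(dosages)[!removed]
}

#' Expression and genotype principal-component covariates
#'
#' Concatenates the top PCs of the (inverse-normal transformed) expression
#' matrix and of the centered LD-pruned dosage matrix; PC score vectors are
#' returned orthonormal.
#'
#' @param expression_rint Genes x samples matrix.
#' @param dosages_pruned Individuals x SNPs matrix after [ld_prune()].
#' @param n_pcs PCs from each matrix (default 5).
#' @return Samples x `2 * n_pcs` matrix, columns `exprPC*`/`genoPC*`.
#' @export
compute_pc_covariates <- function(expression_rint, dosages_pruned, n_pcs = 5) {
  e <- unit_pc_scores(t(expression_rint), n_pcs)
  g <- unit_pc_scores(dosages_pruned, n_pcs)
  colnames(e) <- paste0("expr", colnames(e))
  colnames(g) <- paste0("geno", colnames(g))
  cbind(e, g)
}

# project out covariates (with intercept) from y and genotype columns
fw_residuals <- function(y, G, covariates) {
  X <- cbind(matrix(1, length(y), 1), covariates)
  qx <- qr(X)
  list(y = qr.resid(qx, y), G = qr.resid(qx, G), df = length(y) - qx$rank - 1L)
}

#' Single-SNP nominal cis association scan
#'
#' OLS of the transformed phenotype on each SNP dosage plus covariates
#' (via covariate projection), with two-sided t p-values.
#'
#' @param y_rint Phenotype vector (inverse-normal transformed expression).
#' @param cis_dosages Individuals x SNPs dosage matrix for the window.
#' @param pc_covariates Samples x covariates matrix (may be `NULL`).
#' @return Tibble: `variant_id`, `beta`, `se`, `t`, `p`, `maf`.
#' @export
nominal_scan <- function(y_rint, cis_dosages, pc_covariates = NULL) {
  if (is.null(dim(cis_dosages)) || ncol(cis_dosages) == 0) {
    stop("empty cis window")
  }
  fr <- fw_residuals(y_rint, cis_dosages, pc_covariates)
  gss <- colSums(fr$G^2)
  stopifnot(all(gss > 0))  # monomorphic SNPs must be excluded upstream
  beta <- unname(colSums(fr$G * fr$y) / gss)
  rss <- sum(fr$y^2) - beta^2 * unname(gss)
  sigma2 <- pmax(rss, 0) / fr$df
  se <- sqrt(sigma2 / unname(gss))
  t <- beta / se
  af <- colMeans(cis_dosages) / 2
  tibble::tibble(
    variant_id = colnames(cis_dosages),
    beta = beta, se = se, t = t,
    p = 2 * stats::pt(-abs(t), fr$df),
    maf = pmin(af, 1 - af)
  )
}

#' Choose one variant among a perfectly linked tie
#'
#' @param tied_snps Character vector of variant ids (pairwise r^2 = 1).
#' @param seed Integer seed.
#' @return A single variant id.
#' @export
resolve_perfect_ld <- function(tied_snps, seed = 1L) {
  if (!length(tied_snps)) stop("empty tie set")
  if (length(tied_snps) == 1) return(tied_snps)
  set.seed(derive_seed(seed, paste0("ld_tie_", tied_snps[1])))
  sample(tied_snps, 1)
}

fit_beta_mle <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- stats::var(x)
  if (v <= 0) return(NULL)
  a0 <- max(m * (m * (1 - m) / v - 1), 1e-3)
  b0 <- max(a0 * (1 - m) / m, 1e-3)
  nll <- function(par) -sum(stats::dbeta(x, par[1], par[2], log = TRUE))
  fit <- try(stats::optim(c(a0, b0), nll, method = "L-BFGS-B",
                          lower = c(1e-3, 1e-3), upper = c(1e4, 1e6)),
             silent = TRUE)
  if (inherits(fit, "try-error")) c(a = a0, b = b0) else
    c(a = fit$par[1], b = fit$par[2])
}

#' Permutation pass with beta-approximated empirical p-value
#'
#' Permutes the covariate-residualized phenotype `n_perm` times, records the
#' minimum nominal p across the cis window per permutation, fits a Beta
#' distribution to the minima by maximum likelihood (moments
#' initialization), and evaluates the observed top-SNP p against its CDF.
#' Perfect-LD ties at the top are broken by a seeded uniform choice.
#' Degenerate minima fall back to the rank-based empirical p with a warning.
#'
#' @inheritParams nominal_scan
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return One-row tibble: `variant_id`, `beta`, `se`, `t`, `p_nominal`,
#'   `maf`, `beta_a`, `beta_b`, `p_beta`, `n_tested_snps`.
#' @export
permutation_pass <- function(y_rint, cis_dosages, pc_covariates = NULL,
                             n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  nom <- nominal_scan(y_rint, cis_dosages, pc_covariates)
  best_p <- min(nom$p)
  tied <- nom$variant_id[nom$p <= best_p * (1 + 1e-9)]
  if (length(tied) > 1) {
    cc <- abs(stats::cor(cis_dosages[, tied, drop = FALSE]))
    perfect <- tied[cc[1, ] > 1 - 1e-12]
    top_id <- if (length(perfect) == length(tied)) {
      resolve_perfect_ld(tied, seed)
    } else tied[1]
  } else top_id <- tied
  top <- nom[nom$variant_id == top_id, ]

  fr <- fw_residuals(y_rint, cis_dosages, pc_covariates)
  n <- length(fr$y)
  Gs <- scale(fr$G)
  Gs[!is.finite(Gs)] <- 0
  ys <- as.numeric(scale(fr$y))
  set.seed(derive_seed(seed, "perm_pass"))
  P <- vapply(seq_len(n_perm), function(i) ys[sample.int(n)],
              numeric(n))
  r <- crossprod(P, Gs) / (n - 1)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tstat <- r * sqrt(fr$df) / sqrt(1 - r^2)
  pmat <- 2 * stats::pt(-abs(tstat), fr$df)
  min_p <- apply(pmat, 1, min)

  ab <- fit_beta_mle(min_p)
  if (is.null(ab)) {
    warning("degenerate permutation minima: falling back to rank-based empirical p")
    p_beta <- (1 + sum(min_p <= best_p)) / (n_perm + 1)
    ab <- c(a = NA_real_, b = NA_real_)
  } else {
    p_beta <- stats::pbeta(top$p, ab["a"], ab["b"])
  }
  tibble::tibble(
    variant_id = top$variant_id, beta = top$beta, se = top$se, t = top$t,
    p_nominal = top$p, maf = top$maf,
    beta_a = unname(ab["a"]), beta_b = unname(ab["b"]),
    p_beta = unname(p_beta), n_tested_snps = nrow(nom)
  )
}

#' Gene-level FDR over top-SNP empirical p-values
#'
#' @param records Tibble with one row per gene and a `p_beta` column.
#' @param alpha eGene FDR threshold (default 0.05).
#' @return `records` with `q` and logical `egene` columns.
#' @export
egene_fdr <- function(records, alpha = 0.05) {
  if (!nrow(records)) {
    return(dplyr::mutate(records, q = numeric(0), egene = logical(0)))
  }
  dplyr::mutate(records, q = bh_fdr(.data$p_beta), egene = .data$q < alpha)
}

#' Forward stepwise scan for conditionally independent cis signals
#'
#' Conditions on the primary eVariant, rescans the window, and accepts a new
#' signal iff its nominal p falls below the gene's significance threshold —
#' the nominal p whose beta-approximated empirical p equals `alpha`, using
#' the Beta parameters from the primary permutation pass. Iterates until no
#' further signal; ranks are assigned in discovery order. Conditioning SNPs
#' that become collinear are dropped with a warning.
#'
#' @inheritParams nominal_scan
#' @param primary_record One-row tibble from [permutation_pass()].
#' @param alpha Gene-level significance level defining the nominal
#'   threshold (default 0.05).
#' @param max_rank Safety bound on discovered signals (default 5).
#' @param seed Integer seed (tie breaking).
#' @return Tibble of additional records (`variant_id`, `beta`, `se`, `t`,
#'   `p_nominal`, `maf`, `rank`), possibly empty.
#' @export
conditional_scan <- function(y_rint, cis_dosages, pc_covariates = NULL,
                             primary_record, alpha = 0.05, max_rank = 5,
                             seed = 1L) {
  if (!is.finite(primary_record$beta_a) || !is.finite(primary_record$beta_b)) {
    return(tibble::tibble())
  }
  p_thresh <- stats::qbeta(alpha, primary_record$beta_a, primary_record$beta_b)
  conditioning <- primary_record$variant_id
  out <- list()
  rank <- 1L
  repeat {
    cond_mat <- cis_dosages[, conditioning, drop = FALSE]
    keep <- qr(cbind(1, pc_covariates, cond_mat))$rank ==
      1 + NCOL(pc_covariates %||% matrix(nrow = length(y_rint), ncol = 0)) + ncol(cond_mat)
    if (!keep) {
      warning("collinear conditioning SNPs dropped")
      qrx <- qr(cbind(1, pc_covariates, cond_mat))
      conditioning <- conditioning[seq_len(max(0, qrx$rank - 1 - NCOL(pc_covariates %||% 0)))]
      cond_mat <- cis_dosages[, conditioning, drop = FALSE]
    }
    remaining <- setdiff(colnames(cis_dosages), conditioning)
    # drop remaining SNPs perfectly linked to the conditioning set
    if (!length(remaining)) break
    covs <- cbind(pc_covariates, cond_mat)
    G <- cis_dosages[, remaining, drop = FALSE]
    fr <- fw_residuals(y_rint, G, covs)
    ok <- colSums(fr$G^2) > 1e-10
    if (!any(ok)) break
    nom <- nominal_scan(y_rint, G[, ok, drop = FALSE], covs)
    top <- nom[which.min(nom$p), ]
    if (top$p >= p_thresh || rank > max_rank) break
    out[[rank]] <- dplyr::mutate(top, rank = rank)
    conditioning <- c(conditioning, top$variant_id)
    rank <- rank + 1L
  }
  dplyr::bind_rows(out) |>
    dplyr::rename(p_nominal = dplyr::any_of("p"))
}

#' Map cis-eQTLs across all genes
#'
#' The full mapping stage: residualize log2 CPM expression on technical
#' covariates, inverse-normal transform per gene, add expression and
#' genotype principal components as covariates, scan each gene's +/-1 Mb
#' cis window (MAF > `maf_min`), run the permutation pass, and apply
#' gene-level BH FDR. Optionally runs the conditional scan for eGenes.
#'
#' @param log2cpm Genes x samples expression matrix.
#' @param dosages Individuals x SNPs dosage matrix (aligned with samples).
#' @param snp_meta Tibble `snp_id`, `chrom`, `pos_bp`.
#' @param gene_annotation Tibble `gene_id`, `chrom`, `tss`.
#' @param covariate_design Technical covariate matrix (samples x terms) to
#'   residualize on before the inverse-normal transform; may be `NULL`.
#' @param cis_window_bp Window half-width around the TSS (default 1e6,
#'   inclusive).
#' @param maf_min Minimum minor-allele frequency (default 0.01, strict).
#' @param n_perm Permutations per gene (default 1000).
#' @param n_pcs Expression/genotype PCs (default 5; 0 disables).
#' @param alpha eGene FDR threshold (default 0.05).
#' @param conditional Also run the conditional scan for eGenes.
#' @param seed Integer seed.
#' @return `eqtl_result` tibble: one row per gene (rank 0) plus conditional
#'   rows; columns `gene_id`, `variant_id`, `tss_distance`, `maf`, `beta`,
#'   `se`, `t`, `p_nominal`, `beta_a`, `beta_b`, `p_beta`, `q`, `egene`,
#'   `rank`, `n_tested_snps`.
#' @export
map_cis_eqtls <- function(log2cpm, dosages, snp_meta, gene_annotation,
                          covariate_design = NULL, cis_window_bp = 1e6,
                          maf_min = 0.01, n_perm = 1000, n_pcs = 5,
                          alpha = 0.05, conditional = FALSE, seed = 1L) {
  stopifnot(ncol(log2cpm) == nrow(dosages))
  expr_res <- if (is.null(covariate_design)) {
    log2cpm - rowMeans(log2cpm)
  } else {
    residualize(log2cpm, covariate_design)
  }
  expr_rint <- t(apply(expr_res, 1, rint))
  pcs <- NULL
  if (n_pcs > 0) {
    pruned <- ld_prune(dosages)
    pcs <- compute_pc_covariates(expr_rint, dosages[, pruned, drop = FALSE],
                                 n_pcs = n_pcs)
  }
  af <- colMeans(dosages) / 2
  maf <- pmin(af, 1 - af)
  genes <- gene_annotation[gene_annotation$gene_id %in% rownames(log2cpm), ]
  records <- purrr::pmap_dfr(
    genes[, c("gene_id", "chrom", "tss")],
    function(gene_id, chrom, tss) {
      win <- snp_meta$snp_id[snp_meta$chrom == chrom &
                               abs(snp_meta$pos_bp - tss) <= cis_window_bp]
      win <- win[maf[win] > maf_min]
      if (!length(win)) return(tibble::tibble())
      rec <- permutation_pass(expr_rint[gene_id, ],
                              dosages[, win, drop = FALSE], pcs,
                              n_perm = n_perm,
                              seed = derive_seed(seed, gene_id))
      dplyr::mutate(rec, gene_id = gene_id, rank = 0L)
    })
  records <- egene_fdr(records, alpha = alpha)
  if (conditional && any(records$egene)) {
    extra <- purrr::map_dfr(records$gene_id[records$egene], function(g) {
      ga <- genes[genes$gene_id == g, ]
      win <- snp_meta$snp_id[snp_meta$chrom == ga$chrom &
                               abs(snp_meta$pos_bp - ga$tss) <= cis_window_bp]
      win <- win[maf[win] > maf_min]
      cs <- conditional_scan(expr_rint[g, ], dosages[, win, drop = FALSE],
                             pcs, records[records$gene_id == g, ],
                             alpha = alpha, seed = derive_seed(seed, g))
      if (nrow(cs)) dplyr::mutate(cs, gene_id = g, egene = TRUE) else cs
    })
    records <- dplyr::bind_rows(records, extra)
  }
  records <- records |>
    dplyr::left_join(gene_annotation[, c("gene_id", "tss")], by = "gene_id") |>
    dplyr::left_join(snp_meta[, c("snp_id", "pos_bp")],
                     by = c(variant_id = "snp_id")) |>
    dplyr::mutate(tss_distance = .data$pos_bp - .data$tss) |>
    dplyr::select("gene_id", "variant_id", "tss_distance", "maf", "beta",
                  "se", "t", "p_nominal", dplyr::any_of(c("beta_a", "beta_b",
                  "p_beta", "q", "egene", "n_tested_snps")), "rank") |>
    dplyr::arrange(.data$gene_id, .data$rank)
  structure(records, class = c("eqtl_result", class(records)),
            n_perm = n_perm, alpha = alpha)
}
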