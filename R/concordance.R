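#' Correlate Log2FC between two differential-expression results
#'
#' Pearson and Spearman correlations over the intersection of gene ids
#' (matched by id, not row order).
#'
#' @param de_a,de_b Tibbles with `gene_id` and `log2fc`.
#' @return One-row tibble: `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n_shared_genes`.
#' @export
log2fc_concordance <- function(de_a, de_b) {
  shared <- intersect(de_a$gene_id, de_b$gene_id)
  if (length(shared) == 0) stop("no shared genes between the two results")
  if (length(shared) < 10) stop("fewer than 10 shared genes")
  a <- de_a$log2fc[match(shared, de_a$gene_id)]
  b <- de_b$log2fc[match(shared, de_b$gene_id)]
  pe <- stats::cor.test(a, b, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  tibble::tibble(
    pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    n_shared_genes = length(shared)
  )
}

#' Rank-rank hypergeometric overlap map
#'
#' Both gene lists are ranked by their signed scores from most-up to
#' most-down. At each grid point (i, j), stepping through the ranks, the
#' overlap k of the top-i genes of A with the top-j genes of B is scored by
#' the hypergeometric tail; the signed value is `-log10 p(X >= k)` when the
#' overlap exceeds its expectation (enrichment) and `+log10 p(X <= k)`
#' when it falls short (depletion), so concordant signal falls on the
#' diagonal corners.
#'
#' @param scores_a,scores_b Named numeric vectors (gene id -> signed score)
#'   over the same gene universe.
#' @param step Rank step size (default `max(1, floor(N / 100))`).
#' @return Tibble with `rank_a`, `rank_b`, `overlap`, `expected`,
#'   `signed_log10p`; class `rrho_map`.
#' @export
rrho_map <- function(scores_a, scores_b, step = NULL) {
  genes <- intersect(names(scores_a), names(scores_b))
  if (!length(genes)) stop("no shared gene universe")
  n <- length(genes)
  step <- step %||% max(1L, floor(n / 100))
  if (step < 1) stop("step must be >= 1")
  ord_a <- genes[order(scores_a[genes], decreasing = TRUE)]
  ord_b <- genes[order(scores_b[genes], decreasing = TRUE)]
  # rank of each gene in list B, indexed by list-A order
  rank_in_b <- match(ord_a, ord_b)
  grid <- seq(step, n, by = step)
  res <- purrr::map_dfr(grid, function(i) {
    in_top_a <- rank_in_b[seq_len(i)]
    counts <- cumsum(tabulate(in_top_a, nbins = n))
    k <- counts[grid]
    expected <- i * grid / n
    p_over <- stats::phyper(k - 1, i, n - i, grid, lower.tail = FALSE)
    p_under <- stats::phyper(k, i, n - i, grid)
    tibble::tibble(
      rank_a = i, rank_b = grid, overlap = k, expected = expected,
      signed_log10p = ifelse(k >= expected, -log10(p_over), log10(p_under))
    )
  })
  structure(res, class = c("rrho_map", class(res)), n_genes = n, step = step)
}

#' Define the two-line differentially expressed gene (DEG) set
#'
#' A gene is a member iff it reaches FDR < `fdr` in either result, or
#' nominal p < `nominal` in both with a consistent direction of effect.
#' Provenance records which clause admitted it.
#'
#' @param de_f0 Primary line-contrast result (`gene_id`, `log2fc`, `p`, `q`).
#' @param de_meta Second line-contrast result (e.g. a meta-analysis); may be
#'   `NULL`, in which case only the first FDR clause can apply.
#' @param fdr FDR threshold (default 0.10).
#' @param nominal Nominal p threshold (default 0.05).
#' @return Tibble `gene_id`, `provenance`
#'   (`FDR_F0` / `FDR_meta` / `nominal_both_consistent`), `direction`
#'   (+1 up in bLR, -1 down) from the F0 result where available.
#' @export
define_deg_set <- function(de_f0, de_meta = NULL, fdr = 0.10, nominal = 0.05) {
  f0 <- tibble::tibble(gene_id = de_f0$gene_id, lfc0 = de_f0$log2fc,
                       p0 = de_f0$p, q0 = de_f0$q)
  if (is.null(de_meta)) {
    out <- f0 |>
      dplyr::filter(.data$q0 < fdr) |>
      dplyr::transmute(.data$gene_id, provenance = "FDR_F0",
                       direction = sign(.data$lfc0))
    return(out)
  }
  m <- tibble::tibble(gene_id = de_meta$gene_id, lfcm = de_meta$log2fc,
                      pm = de_meta$p, qm = de_meta$q)
  j <- dplyr::full_join(f0, m, by = "gene_id")
  j |>
    dplyr::mutate(
      provenance = dplyr::case_when(
        !is.na(.data$q0) & .data$q0 < fdr ~ "FDR_F0",
        !is.na(.data$qm) & .data$qm < fdr ~ "FDR_meta",
        !is.na(.data$p0) & !is.na(.data$pm) &
          .data$p0 < nominal & .data$pm < nominal &
          sign(.data$lfc0) == sign(.data$lfcm) ~ "nominal_both_consistent",
        TRUE ~ NA_character_
      ),
      direction = sign(dplyr::coalesce(.data$lfc0, .data$lfcm))
    ) |>
    dplyr::filter(!is.na(.data$provenance)) |>
    dplyr::select("gene_id", "provenance", "direction")
}

#' Flag DEG-set genes concordant with bLR-like or bHR-like behavior
#'
#' A bLR-upregulated DEG is flagged `bLR_like` iff at least one behavior
#' shows a nominal (p < `nominal`) association whose direction, after
#' applying the sign convention, is bLR-like; symmetrically for `bHR_like`.
#'
#' @param deg_set Output of [define_deg_set()].
#' @param f2_de_per_behavior Named list of `de_result` tibbles, one per
#'   behavior in the sign convention.
#' @param sign_convention Tibble from [default_sign_convention()].
#' @param nominal Nominal p threshold (default 0.05).
#' @return Tibble `gene_id`, `direction`, `flag` in
#'   `{bLR_like, bHR_like, none}`, `n_supporting_behaviors`.
#' @export
behavior_concordance_flags <- function(deg_set, f2_de_per_behavior,
                                       sign_convention = default_sign_convention(),
                                       nominal = 0.05) {
  needed <- behavior_names()
  miss <- setdiff(needed, names(f2_de_per_behavior))
  if (length(miss)) stop("missing behavior result(s): ", paste(miss, collapse = ", "))
  beh_long <- purrr::imap_dfr(f2_de_per_behavior[needed], function(de, b) {
    tibble::tibble(gene_id = de$gene_id, behavior = b,
                   blr_score = de$t * sign_multiplier(sign_convention, b),
                   p = de$p)
  })
  deg_set |>
    dplyr::left_join(beh_long, by = "gene_id", relationship = "many-to-many") |>
    dplyr::group_by(.data$gene_id, .data$direction) |>
    dplyr::summarise(
      n_supporting_behaviors = sum(
        .data$p < nominal & sign(.data$blr_score) == .data$direction[1],
        na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(flag = dplyr::case_when(
      .data$n_supporting_behaviors > 0 & .data$direction > 0 ~ "bLR_like",
      .data$n_supporting_behaviors > 0 & .data$direction < 0 ~ "bHR_like",
      TRUE ~ "none"
    ))
}

#' Fisher's exact test for overlap of two gene sets
#'
#' Builds the 2x2 membership table over the universe and runs the exact
#' conditional test; reports the sample (cross-product) odds ratio with the
#' conditional-MLE-inverted 95% CI.
#'
#' @param set1,set2 Character vectors of gene ids (subsets of `universe`).
#' @param universe Character vector: the gene universe.
#' @return One-row tibble: `odds_ratio`, `p`, `ci_low`, `ci_high`,
#'   `n_overlap`, `n_set1`, `n_set2`, `n_universe`, `degenerate`.
#' @export
overlap_enrichment <- function(set1, set2, universe) {
  if (!length(universe)) stop("empty universe")
  set1 <- intersect(set1, universe)
  set2 <- intersect(set2, universe)
  in1 <- universe %in% set1
  in2 <- universe %in% set2
  tab <- table(factor(in1, c(TRUE, FALSE)), factor(in2, c(TRUE, FALSE)))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(tibble::tibble(odds_ratio = NA_real_, p = 1, ci_low = NA_real_,
                          ci_high = NA_real_, n_overlap = sum(in1 & in2),
                          n_set1 = sum(in1), n_set2 = sum(in2),
                          n_universe = length(universe), degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  tibble::tibble(
    odds_ratio = or_sample, p = ft$p.value,
    ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
    n_overlap = sum(in1 & in2), n_set1 = sum(in1), n_set2 = sum(in2),
    n_universe = length(universe), degenerate = FALSE
  )
}
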