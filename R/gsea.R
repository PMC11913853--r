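#' Combined bLR-like ranking statistic
#'
#' Averages sign-harmonized t-statistics across the included analyses (line
#' contrasts and behaviors), so a positive score means bLR-like
#' upregulation. Genes missing from some analyses are averaged over the
#' available ones by default (`na_policy = "available"`), with the count of
#' contributing analyses recorded; `na_policy = "drop"` restricts to genes
#' present everywhere.
#'
#' @param de_results Named list of tibbles (`gene_id`, `t`); names must
#'   appear in the sign convention.
#' @param sign_convention Tibble from [default_sign_convention()].
#' @param variant `"directional"` (signed mean) or `"absolute"`.
#' @param na_policy `"available"` or `"drop"`.
#' @return Tibble `gene_id`, `score`, `n_analyses`; attribute `analyses`.
#' @export
combined_statistic <- function(de_results,
                               sign_convention = default_sign_convention(),
                               variant = c("directional", "absolute"),
                               na_policy = c("available", "drop")) {
  variant <- match.arg(variant)
  na_policy <- match.arg(na_policy)
  mult <- sign_multiplier(sign_convention, names(de_results))
  long <- purrr::imap_dfr(de_results, function(de, nm) {
    tibble::tibble(gene_id = de$gene_id, analysis = nm,
                   harmonized_t = de$t * mult[[match(nm, names(de_results))]])
  })
  out <- long |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(score = mean(.data$harmonized_t),
                     n_analyses = dplyr::n(), .groups = "drop")
  if (na_policy == "drop") {
    out <- dplyr::filter(out, .data$n_analyses == length(de_results))
  }
  if (!nrow(out)) stop("empty gene universe after combining analyses")
  if (variant == "absolute") out$score <- abs(out$score)
  structure(out, analyses = names(de_results), variant = variant)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic of preranked gene-set enrichment: walking down the
#' ranked list, hits increment by \eqn{|s|^w / \sum_{hits} |s|^w} and misses
#' decrement by \eqn{1/(N - n_{set})}; the ES is the maximum deviation from
#' zero, signed.
#'
#' @param ranked_scores Named numeric vector sorted in decreasing order
#'   (checked; names are gene ids).
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Weight on |score| (default 1).
#' @return Scalar ES in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked_scores, gene_set, weight_exponent = 1) {
  if (is.unsorted(rev(ranked_scores))) {
    ranked_scores <- sort(ranked_scores, decreasing = TRUE)
  }
  hit <- names(ranked_scores) %in% gene_set
  if (!any(hit)) return(0)
  n <- length(ranked_scores)
  w <- abs(ranked_scores)^weight_exponent
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / (n - sum(hit)))
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' For each set within the size bounds, the observed ES is compared against
#' `nperm` size-matched random gene sets drawn from the universe. NES is the
#' ES divided by the mean |null ES| of matching sign; the p-value counts
#' null sets at least as extreme in absolute ES, with the +1 pseudo-count
#' (`min p = 1/(1 + nperm)`); BH correction is across sets.
#'
#' @param statistic Tibble from [combined_statistic()] (`gene_id`, `score`).
#' @param collection Named list of gene-id vectors (e.g. [read_gmt()]).
#' @param nperm Permutations (>= 100; default 10,000).
#' @param min_size,max_size Set-size bounds after intersection with the
#'   universe (defaults 10 and 1,000).
#' @param weight_exponent Weight on |score| (default 1).
#' @param seed Integer seed.
#' @return `gsea_result` tibble: `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (list column).
#' @export
gsea_test <- function(statistic, collection, nperm = 10000,
                      min_size = 10, max_size = 1000,
                      weight_exponent = 1, seed = 1L) {
  if (nperm < 100) stop("nperm must be >= 100")
  scores <- stats::setNames(statistic$score, statistic$gene_id)
  if (stats::sd(scores) == 0) stop("ranking statistic has zero variance")
  ord <- sort(scores, decreasing = TRUE)
  genes <- names(ord)
  sizes <- vapply(collection, function(s) length(intersect(s, genes)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep)) {
    message(sum(!keep), " set(s) outside size bounds excluded")
  }
  collection <- collection[keep]
  sizes <- sizes[keep]
  set.seed(derive_seed(seed, "gsea"))
  null_cache <- new.env()
  null_for_size <- function(k) {
    key <- as.character(k)
    if (!is.null(null_cache[[key]])) return(null_cache[[key]])
    es <- vapply(seq_len(nperm), function(i) {
      enrichment_score(ord, sample(genes, k), weight_exponent)
    }, numeric(1))
    null_cache[[key]] <- es
    es
  }
  res <- purrr::imap_dfr(collection, function(set, nm) {
    set <- intersect(set, genes)
    es <- enrichment_score(ord, set, weight_exponent)
    null_es <- null_for_size(length(set))
    same_sign <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    p <- (1 + sum(abs(null_es) >= abs(es))) / (1 + nperm)
    hit_ranks <- which(genes %in% set)
    pk <- peak_rank(ord, set, weight_exponent)
    le <- if (es >= 0) genes[hit_ranks[hit_ranks <= pk]]
          else genes[hit_ranks[hit_ranks >= pk]]
    tibble::tibble(set = nm, size = length(set), es = es, nes = nes, p = p,
                   leading_edge = list(le))
  })
  res$q <- bh_fdr(res$p)
  structure(res[, c("set", "size", "es", "nes", "p", "q", "leading_edge")],
            class = c("gsea_result", class(res)), nperm = nperm)
}

# rank index at which the running sum attains its extreme
peak_rank <- function(ord, set, weight_exponent) {
  hit <- names(ord) %in% set
  w <- abs(ord)^weight_exponent
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / (length(ord) - sum(hit)))
  run <- cumsum(inc - dec)
  which.max(abs(run))
}
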