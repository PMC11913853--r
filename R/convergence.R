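#' Six-criterion convergence gate for candidate genes
#'
#' A gene is a top candidate iff it (1) is a two-line DEG, (2) has at least
#' one direction-consistent nominal behavioral association in the F2s,
#' (3) is an eGene whose top eVariant is line-segregated (G'st above
#' threshold), (4) has a signed-aFC prediction matching the sign of its
#' line-contrast Log2FC, (5) has SMR q below threshold for at least one
#' behavior, and (6) has, for such a behavior, a directional SMR statistic
#' whose sign matches that behavior's DE Log2FC. The audit trail retains
#' every per-criterion boolean.
#'
#' @param deg_set Output of [define_deg_set()].
#' @param behavior_flags Output of [behavior_concordance_flags()].
#' @param eqtl_records `eqtl_result` tibble.
#' @param segregation Output of [segregation_table()] (rank-0 eVariants).
#' @param f0_de Line-contrast `de_result`.
#' @param smr_records `smr_result` tibble.
#' @param f2_de Named list of per-behavior `de_result`s.
#' @param smr_fdr_threshold SMR FDR gate (default 0.10).
#' @return `candidate_ledger` tibble: `gene_id`, `crit1_deg` ..
#'   `crit6_smr_direction`, `pass`, `max_smr_neglog10p`, sorted by the
#'   latter among passing genes first.
#' @export
convergence_gate <- function(deg_set, behavior_flags, eqtl_records,
                             segregation, f0_de, smr_records, f2_de,
                             smr_fdr_threshold = 0.10) {
  for (nm in c("deg_set", "behavior_flags", "eqtl_records", "segregation",
               "f0_de", "smr_records")) {
    if (is.null(get(nm)) || !nrow(get(nm))) {
      if (nm %in% c("deg_set", "behavior_flags")) next
      stop("missing or empty upstream table: ", nm)
    }
  }
  genes <- unique(eqtl_records$gene_id[eqtl_records$rank == 0])
  top <- eqtl_records[eqtl_records$rank == 0, ]
  f2_long <- purrr::imap_dfr(f2_de, function(de, b) {
    tibble::tibble(gene_id = de$gene_id, behavior = b, log2fc = de$log2fc)
  })
  smr_sig <- smr_records |>
    dplyr::filter(.data$q < smr_fdr_threshold) |>
    dplyr::left_join(f2_long, by = c("gene_id", "behavior"))

  ledger <- tibble::tibble(gene_id = genes) |>
    dplyr::mutate(
      crit1_deg = .data$gene_id %in% deg_set$gene_id,
      crit2_behavior = .data$gene_id %in%
        behavior_flags$gene_id[behavior_flags$flag != "none"],
      crit3_segregated_egene = {
        i <- match(.data$gene_id, top$gene_id)
        s <- segregation$segregated[match(top$variant_id[i],
                                          segregation$variant_id)]
        top$egene[i] & !is.na(s) & s
      },
      crit4_afc_sign = {
        i <- match(.data$gene_id, segregation$gene_id)
        j <- match(.data$gene_id, f0_de$gene_id)
        !is.na(i) & !is.na(j) &
          !is.na(segregation$predicted_log2fc[i]) &
          sign(segregation$predicted_log2fc[i]) == sign(f0_de$log2fc[j])
      },
      crit5_smr = .data$gene_id %in% smr_sig$gene_id,
      crit6_smr_direction = .data$gene_id %in%
        smr_sig$gene_id[!is.na(smr_sig$log2fc) &
                          sign(smr_sig$signed_t) == sign(smr_sig$log2fc)],
      pass = .data$crit1_deg & .data$crit2_behavior &
        .data$crit3_segregated_egene & .data$crit4_afc_sign &
        .data$crit5_smr & .data$crit6_smr_direction
    )
  max_smr <- smr_records |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(max_smr_neglog10p = max(-log10(pmax(.data$p, 1e-300))),
                     .groups = "drop")
  ledger |>
    dplyr::left_join(max_smr, by = "gene_id") |>
    dplyr::arrange(dplyr::desc(.data$pass),
                   dplyr::desc(.data$max_smr_neglog10p))
}

#' Expected chance convergence under gene-label permutation
#'
#' Permutes the assignment of genes to differential-expression results (one
#' shared relabeling of the line-contrast and all behavioral DE tables per
#' permutation), re-runs the convergence gate with the genetic stages
#' (eQTL, segregation, SMR) fixed, and summarizes the pass count.
#'
#' @param deg_inputs List with `f0_de`, `de_meta` (may be `NULL`) and
#'   `f2_de` (named list), as used to build the gate inputs.
#' @param eqtl_records,segregation,smr_records Fixed genetic stages.
#' @param sign_convention Sign convention for the behavior flags.
#' @param n_permutations Number of permutations (>= 1; default 200).
#' @param seed Integer seed.
#' @param smr_fdr_threshold SMR FDR gate (default 0.10).
#' @return List: `mean_passes`, `q95_passes`, `pass_counts`.
#' @export
chance_expectation <- function(deg_inputs, eqtl_records, segregation,
                               smr_records,
                               sign_convention = default_sign_convention(),
                               n_permutations = 200, seed = 1L,
                               smr_fdr_threshold = 0.10) {
  if (n_permutations < 1) stop("need at least one permutation")
  f0 <- deg_inputs$f0_de
  meta <- deg_inputs$de_meta %||% NULL
  f2 <- deg_inputs$f2_de
  genes <- f0$gene_id
  set.seed(derive_seed(seed, "chance"))
  pass_counts <- vapply(seq_len(n_permutations), function(i) {
    perm <- sample(genes)
    relabel <- function(de) {
      de$gene_id <- perm[match(de$gene_id, genes)]
      de
    }
    f0p <- relabel(f0)
    metap <- if (!is.null(meta)) relabel(meta) else NULL
    f2p <- lapply(f2, relabel)
    degp <- define_deg_set(f0p, metap)
    flagsp <- if (nrow(degp)) {
      behavior_concordance_flags(degp, f2p, sign_convention)
    } else degp
    gate <- convergence_gate(degp, flagsp, eqtl_records, segregation,
                             f0p, smr_records, f2p,
                             smr_fdr_threshold = smr_fdr_threshold)
    sum(gate$pass)
  }, numeric(1))
  list(mean_passes = mean(pass_counts),
       q95_passes = unname(stats::quantile(pass_counts, 0.95)),
       pass_counts = pass_counts)
}
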