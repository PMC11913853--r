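#' Run the full triangulation pipeline on a cohort
#'
#' Chains every stage in dependency order: line-contrast and per-behavior
#' differential expression, DEG-set definition, behavior-concordance flags,
#' cis-eQTL mapping with permutation-based empirical p-values, allelic
#' fold-change estimation for eGenes, founder-line segregation scoring,
#' the behavioral QTL scan, SMR colocalization, and the convergence gate.
#'
#' @param cohort A `sim_cohort`, or an equivalent list with elements
#'   `counts`, `phenotypes`, `gene_annotation`, `genome$snps` (or
#'   `snp_meta`), `cross$dosage` (F2) and `founders` (`dosage`, `line`).
#' @param n_perm eQTL permutations per gene (default 1000).
#' @param deg_fdr DEG FDR threshold (default 0.10).
#' @param egene_fdr eGene FDR threshold (default 0.05).
#' @param smr_fdr SMR FDR gate (default 0.10).
#' @param gst_threshold G'st segregation threshold (default 0.27).
#' @param nominal Nominal p threshold (default 0.05).
#' @param n_pcs Expression/genotype PCs for eQTL covariates (default 5).
#' @param seed Master seed; stage seeds derive from it.
#' @return A list of class `triangulation` with components `f0_de`,
#'   `f2_de`, `deg_set`, `behavior_flags`, `eqtl`, `afc`, `segregation`,
#'   `gwas`, `smr`, `gate`, `prediction`, and `config`.
#' @export
triangulate <- function(cohort, n_perm = 1000, deg_fdr = 0.10,
                        egene_fdr = 0.05, smr_fdr = 0.10,
                        gst_threshold = 0.27, nominal = 0.05,
                        n_pcs = 5, seed = 1L) {
  counts <- cohort$counts
  pheno <- cohort$phenotypes
  snp_meta <- cohort$snp_meta %||%
    dplyr::rename(cohort$genome$snps[, c("snp_id", "chrom", "pos_bp")],
                  pos_bp = "pos_bp")
  conv <- default_sign_convention()

  f0_de <- run_de(counts, pheno, "f0_lineage")
  f2_de <- purrr::map(
    stats::setNames(behavior_names(), behavior_names()),
    ~ run_de(counts, pheno, "f2_behavior", behavior = .x))
  deg_set <- define_deg_set(f0_de, NULL, fdr = deg_fdr, nominal = nominal)
  flags <- behavior_concordance_flags(deg_set, f2_de, conv, nominal = nominal)

  # eQTL stage on F2 samples: technical covariates, no behavior term
  f2_ph <- pheno[pheno$generation == "F2", ]
  f2_counts <- counts[, f2_ph$sample_id, drop = FALSE]
  kept <- filter_low_expression(f2_counts)
  lcpm <- log2_cpm(kept, tmm_factors(kept))
  tech <- stats::model.matrix(
    ~ sex + pct_rRNA + pct_intergenic + dissector + stgt_experience + seq_batch,
    dplyr::mutate(f2_ph, sex = factor(.data$sex, c("M", "F")),
                  dissector = factor(.data$dissector),
                  stgt_experience = factor(.data$stgt_experience),
                  seq_batch = factor(.data$seq_batch)))[, -1, drop = FALSE]
  f2_dosage <- cohort$cross$dosage
  eqtl <- map_cis_eqtls(lcpm, f2_dosage, snp_meta, cohort$gene_annotation,
                        covariate_design = tech, n_perm = n_perm,
                        n_pcs = n_pcs, alpha = egene_fdr,
                        seed = derive_seed(seed, "eqtl"))

  top <- dplyr::filter(eqtl, .data$rank == 0, .data$egene)
  afc <- purrr::map2_dfr(top$gene_id, top$variant_id, function(g, v) {
    est <- estimate_afc(kept[g, ], f2_dosage[, v], tech)
    dplyr::mutate(est, gene_id = g, variant_id = v)
  })
  segregation <- if (nrow(afc)) {
    segregation_table(afc, cohort$founders$dosage, cohort$founders$line,
                      threshold = gst_threshold)
  } else tibble::tibble()

  prediction <- NULL
  seg_hits <- if (nrow(segregation)) segregated_evariants(segregation, gst_threshold) else segregation
  if (!is.null(nrow(seg_hits)) && nrow(seg_hits) >= 10) {
    prediction <- prediction_concordance(
      dplyr::select(seg_hits, "gene_id", "predicted_log2fc"), f0_de)
  }

  gwas <- purrr::map_dfr(behavior_names(), function(b) {
    behavior_qtl_scan(f2_ph[[b]],
                      f2_dosage[, unique(top$variant_id), drop = FALSE],
                      covariates = cbind(sex = as.integer(f2_ph$sex == "F")),
                      behavior_name = b)
  })
  smr <- run_smr(eqtl, gwas)
  gate <- convergence_gate(deg_set, flags, eqtl, segregation, f0_de, smr,
                           f2_de, smr_fdr_threshold = smr_fdr)
  structure(
    list(f0_de = f0_de, f2_de = f2_de, deg_set = deg_set,
         behavior_flags = flags, eqtl = eqtl, afc = afc,
         segregation = segregation, prediction = prediction,
         gwas = gwas, smr = smr, gate = gate,
         config = list(n_perm = n_perm, deg_fdr = deg_fdr,
                       egene_fdr = egene_fdr, smr_fdr = smr_fdr,
                       gst_threshold = gst_threshold, nominal = nominal,
                       n_pcs = n_pcs, seed = seed)),
    class = "triangulation"
  )
}

#' @export
print.triangulation <- function(x, ...) {
  cat("Triangulation run (seed ", x$config$seed, ")\n", sep = "")
  cat("  DEG set:", nrow(x$deg_set), "genes;",
      sum(x$behavior_flags$flag != "none"), "behavior-concordant\n")
  cat("  eGenes:", sum(x$eqtl$egene[x$eqtl$rank == 0]), "of",
      sum(x$eqtl$rank == 0), "tested genes\n")
  cat("  segregated eVariants:",
      if (nrow(x$segregation)) sum(x$segregation$segregated) else 0, "\n")
  cat("  SMR records q<", x$config$smr_fdr, ": ",
      sum(x$smr$q < x$config$smr_fdr), "\n", sep = "")
  cat("  gate passes:", sum(x$gate$pass), "\n")
  invisible(x)
}

#' Run the pipeline from a cohort directory and write all outputs
#'
#' File-based entry point: reads a directory written by [write_cohort()],
#' runs [triangulate()], writes every stage's table as TSV plus a JSON
#' manifest (config, seed, row counts per stage). Deterministic given the
#' config: identical seeds reproduce identical outputs.
#'
#' @param cohort_dir Directory from [write_cohort()].
#' @param outdir Output directory.
#' @param ... Passed to [triangulate()] (thresholds, `n_perm`, `seed`).
#' @return The `triangulation` object, invisibly.
#' @export
run_pipeline <- function(cohort_dir, outdir, ...) {
  if (!dir.exists(cohort_dir)) stop("missing input path: ", cohort_dir)
  raw <- read_cohort(cohort_dir)
  f0_ids <- raw$phenotypes$sample_id[raw$phenotypes$generation == "F0"]
  f2_ids <- raw$phenotypes$sample_id[raw$phenotypes$generation == "F2"]
  cohort <- list(
    counts = raw$counts, phenotypes = raw$phenotypes,
    gene_annotation = raw$gene_annotation,
    snp_meta = dplyr::rename(raw$vcf_meta, pos_bp = "pos"),
    cross = list(dosage = raw$dosage[f2_ids, , drop = FALSE]),
    founders = list(dosage = raw$dosage[f0_ids, , drop = FALSE],
                    line = raw$phenotypes$line[match(f0_ids, raw$phenotypes$sample_id)])
  )
  tri <- triangulate(cohort, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) readr::write_tsv(x, file.path(outdir, paste0(name, ".tsv")))
  wr(tibble::as_tibble(tri$f0_de), "de_f0_lineage")
  purrr::iwalk(tri$f2_de, ~ wr(tibble::as_tibble(.x), paste0("de_f2_", .y)))
  wr(tri$deg_set, "deg_set")
  wr(tri$behavior_flags, "behavior_flags")
  wr(tibble::as_tibble(tri$eqtl), "eqtl")
  wr(tri$afc, "afc")
  if (nrow(tri$segregation)) wr(tri$segregation, "segregation")
  wr(tri$gwas, "gwas")
  wr(tibble::as_tibble(tri$smr), "smr")
  wr(tri$gate, "candidate_ledger")
  manifest <- list(
    config = tri$config,
    stage_rows = list(
      f0_de = nrow(tri$f0_de), deg_set = nrow(tri$deg_set),
      eqtl = nrow(tri$eqtl), afc = nrow(tri$afc),
      segregation = nrow(tri$segregation), smr = nrow(tri$smr),
      gate_pass = sum(tri$gate$pass)
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tri)
}
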