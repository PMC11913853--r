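#' Read alternate-allele dosages from a VCF
#'
#' Parses GT fields of a VCF v4.2 into an individuals x SNPs dosage matrix;
#' missing genotypes (`./.`) become `NA`. Positions are kept 1-based.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return List with `dosage` (individuals x SNPs integer matrix) and `meta`
#'   tibble (snp_id, chrom, pos, ref, alt).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  allele_count <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  dos <- apply(gt, 2, allele_count)
  meta <- tibble::tibble(
    snp_id = v@fix[, "ID"],
    chrom = v@fix[, "CHROM"],
    pos = as.integer(v@fix[, "POS"]),
    ref = v@fix[, "REF"], alt = v@fix[, "ALT"]
  )
  dosage <- t(dos)
  colnames(dosage) <- meta$snp_id
  list(dosage = dosage, meta = meta)
}

write_vcf <- function(dosage, snps, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosage)), collapse = "\t")
  )
  gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L],
               nrow = nrow(dosage))
  gt[is.na(dosage)] <- "./."
  body <- vapply(seq_len(nrow(snps)), function(j) {
    paste(c(snps$chrom[j], snps$pos_bp[j], snps$snp_id[j], "A", "G",
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits genotypes (VCF v4.2 with GT), a genes x samples count TSV, a
#' phenotype/covariate TSV, a BED-like TSS annotation TSV, and one TSV per
#' truth table. Reading the files back reproduces dosages and counts exactly.
#'
#' @param cohort A `sim_cohort`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  all_dosage <- rbind(cohort$founders$dosage, cohort$cross$dosage)
  write_vcf(all_dosage, cohort$genome$snps, file.path(outdir, "genotypes.vcf"))
  counts <- tibble::as_tibble(cohort$counts, rownames = "gene_id")
  readr::write_tsv(counts, file.path(outdir, "counts.tsv"))
  readr::write_tsv(cohort$phenotypes, file.path(outdir, "phenotypes.tsv"))
  readr::write_tsv(
    cohort$gene_annotation[, c("chrom", "tss", "strand", "gene_id")],
    file.path(outdir, "gene_annotation.tsv")
  )
  readr::write_tsv(cohort$truth$planted_eqtls, file.path(outdir, "truth_eqtls.tsv"))
  readr::write_tsv(cohort$truth$planted_qtls, file.path(outdir, "truth_qtls.tsv"))
  readr::write_tsv(cohort$truth$planted_line_de,
                   file.path(outdir, "truth_line_de.tsv"))
  readr::write_tsv(cohort$truth$allele_freqs,
                   file.path(outdir, "truth_allele_freqs.tsv"))
  invisible(outdir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory path.
#' @return List with `dosage`, `vcf_meta`, `counts`, `phenotypes`,
#'   `gene_annotation`, and `truth` tables.
#' @export
read_cohort <- function(dir) {
  vcf <- read_vcf_dosages(file.path(dir, "genotypes.vcf"))
  counts_df <- readr::read_tsv(file.path(dir, "counts.tsv"),
                               show_col_types = FALSE)
  counts <- as.matrix(counts_df[, -1])
  rownames(counts) <- counts_df$gene_id
  list(
    dosage = vcf$dosage, vcf_meta = vcf$meta, counts = counts,
    phenotypes = readr::read_tsv(file.path(dir, "phenotypes.tsv"),
                                 show_col_types = FALSE),
    gene_annotation = readr::read_tsv(file.path(dir, "gene_annotation.tsv"),
                                      show_col_types = FALSE),
    truth = list(
      planted_eqtls = readr::read_tsv(file.path(dir, "truth_eqtls.tsv"),
                                      show_col_types = FALSE),
      planted_qtls = readr::read_tsv(file.path(dir, "truth_qtls.tsv"),
                                     show_col_types = FALSE),
      planted_line_de = readr::read_tsv(file.path(dir, "truth_line_de.tsv"),
                                        show_col_types = FALSE),
      allele_freqs = readr::read_tsv(file.path(dir, "truth_allele_freqs.tsv"),
                                     show_col_types = FALSE)
    )
  )
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(
    lapply(parts, function(p) unique(p[-(1:2)])),
    vapply(parts, `[[`, character(1), 1)
  )
}
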