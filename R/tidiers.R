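#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.de_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model"),
    term = attr(x, "term"),
    n_genes = nrow(x),
    n_samples = attr(x, "n_samples"),
    n_filtered = attr(x, "n_filtered"),
    n_sig_q10 = sum(x$q < 0.10, na.rm = TRUE),
    d0 = attr(x, "d0"),
    s0_2 = attr(x, "s0_2")
  )
}

#' @export
tidy.eqtl_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.eqtl_result <- function(x, ...) {
  top <- x[x$rank == 0, ]
  tibble::tibble(
    n_genes_tested = nrow(top),
    n_egenes = sum(top$egene),
    n_conditional = sum(x$rank > 0),
    n_perm = attr(x, "n_perm"),
    alpha = attr(x, "alpha")
  )
}

#' @export
tidy.gsea_result <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"leading_edge")
}

#' @export
glance.gsea_result <- function(x, ...) {
  tibble::tibble(n_sets = nrow(x), n_sig_q05 = sum(x$q < 0.05),
                 nperm = attr(x, "nperm"))
}

#' @export
glance.triangulation <- function(x, ...) {
  tibble::tibble(
    n_deg = nrow(x$deg_set),
    n_behavior_concordant = sum(x$behavior_flags$flag != "none"),
    n_egenes = sum(x$eqtl$egene[x$eqtl$rank == 0]),
    n_segregated = if (nrow(x$segregation)) sum(x$segregation$segregated) else 0L,
    n_smr_sig = sum(x$smr$q < x$config$smr_fdr),
    n_candidates = sum(x$gate$pass),
    prediction_r = if (!is.null(x$prediction)) x$prediction$pearson_r else NA_real_,
    seed = x$config$seed
  )
}
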