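#' Voom precision weights
#'
#' Gene-wise linear fits give a square-root residual-SD vs mean log2 count
#' trend (LOWESS, span 0.5); each observation's weight is the inverse fourth
#' power of the predicted square-root SD at its fitted log-count. With fewer
#' than 10 genes the trend is unreliable and unit weights are returned with
#' a warning.
#'
#' @param counts Genes x samples count matrix (post filtering).
#' @param design Full-rank design matrix.
#' @param lib_size Effective library sizes (default TMM-scaled column sums).
#' @param span LOWESS span (default 0.5).
#' @return Genes x samples matrix of positive weights.
#' @export
voom_weights <- function(counts, design,
                         lib_size = colSums(counts) * tmm_factors(counts),
                         span = 0.5) {
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  if (nrow(counts) < 10) {
    warning("fewer than 10 genes: mean-variance trend unreliable, using unit weights")
    return(matrix(1, nrow(counts), ncol(counts)))
  }
  v <- limma::voom(counts, design, lib.size = lib_size, span = span)
  v$weights
}

#' Per-gene weighted least-squares fits
#'
#' @param y_matrix Genes x samples response matrix (log2 CPM).
#' @param design Full-rank design matrix (samples x terms).
#' @param weights Optional genes x samples precision weights.
#' @return The `limma` `MArrayLM` fit augmented with
#'   ordinary t-statistics.
#' @export
fit_gene_models <- function(y_matrix, design, weights = NULL) {
  if (ncol(y_matrix) <= ncol(design)) {
    stop("need more samples (", ncol(y_matrix), ") than parameters (",
         ncol(design), ")")
  }
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(colnames(design)[qd$pivot[-seq_len(qd$rank)]], collapse = ", "))
  }
  fit <- limma::lmFit(y_matrix, design, weights = weights)
  fit$t_ordinary <- fit$coefficients / (fit$stdev.unscaled * fit$sigma)
  fit
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Fits a scaled F distribution to the residual variances (prior df `d0`,
#' prior variance `s0^2`), forms posterior variances
#' \eqn{\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, and returns
#' moderated t-statistics on \eqn{d_0 + d_g} df with two-sided p-values.
#'
#' @param fits An `MArrayLM` fit from [fit_gene_models()].
#' @return The fit augmented by `limma::eBayes` (components `t`, `p.value`,
#'   `df.prior`, `s2.prior`).
#' @export
ebayes_moderate <- function(fits) {
  limma::eBayes(fits)
}

build_design <- function(pheno, model, behavior = NULL, interaction = FALSE) {
  pheno$sex <- factor(pheno$sex, levels = c("M", "F"))
  if (model == "f0_lineage") {
    req <- c("line", "sex", "pct_rRNA", "pct_intergenic")
    miss <- setdiff(req, names(pheno))
    if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
    pheno$line <- factor(pheno$line, levels = c("bHR", "bLR"))
    X <- stats::model.matrix(~ line + sex + pct_rRNA + pct_intergenic, pheno)
    term <- "linebLR"
  } else {
    req <- c("sex", "pct_rRNA", "pct_intergenic", "dissector",
             "stgt_experience", "seq_batch")
    if (model == "f2_behavior") req <- c(behavior, req)
    miss <- setdiff(req, names(pheno))
    if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
    pheno$dissector <- factor(pheno$dissector)
    pheno$stgt_experience <- factor(pheno$stgt_experience)
    pheno$seq_batch <- factor(pheno$seq_batch)
    if (model == "f2_sex") {
      X <- stats::model.matrix(
        ~ sex + pct_rRNA + pct_intergenic + dissector + stgt_experience + seq_batch,
        pheno)
      term <- "sexF"
    } else {
      f <- stats::as.formula(paste0(
        "~ ", behavior, " + sex + pct_rRNA + pct_intergenic + dissector",
        " + stgt_experience + seq_batch",
        if (interaction) paste0(" + sex:", behavior) else ""))
      X <- stats::model.matrix(f, pheno)
      term <- if (interaction) paste0("sexF:", behavior) else behavior
    }
  }
  list(design = X, term = term)
}

#' Run a full differential-expression model
#'
#' Composes low-expression filtering, TMM normalization, log2 CPM, voom
#' weights, gene-wise weighted least squares, empirical-Bayes moderation and
#' BH FDR. Reference levels are bHR (line) and male (sex), so a positive
#' Log2FC in the line contrast means upregulation in bLR.
#'
#' Models: `"f0_lineage"` (line contrast, F0 samples; covariates sex, %rRNA,
#' %intergenic), `"f2_behavior"` (one continuous behavior, F2 samples;
#' additionally dissector, PavCA exposure, sequencing-batch dummies),
#' `"f2_sex"`, and the optional sex-by-behavior `interaction` term.
#'
#' @param counts Genes x samples count matrix.
#' @param phenotypes Tibble keyed by `sample_id`, with a `generation` column
#'   used to select F0 or F2 samples, covariates, and behaviors.
#' @param model One of `"f0_lineage"`, `"f2_behavior"`, `"f2_sex"`.
#' @param behavior Behavior column name (for `"f2_behavior"`).
#' @param interaction Add a sex-by-behavior interaction and report its term.
#' @param use_voom Apply voom precision weights (default `TRUE`).
#' @param filter_fraction Low-expression removal fraction (default 0.75).
#' @return A `de_result` tibble: `gene_id`, `log2fc`, `ave_expr`,
#'   `t_ordinary`, `t` (moderated), `p`, `q`; attributes `d0`, `s0_2`,
#'   `model`, `term`, `n_samples`, `n_filtered`.
#' @export
run_de <- function(counts, phenotypes, model = c("f0_lineage", "f2_behavior", "f2_sex"),
                   behavior = NULL, interaction = FALSE, use_voom = TRUE,
                   filter_fraction = 0.75) {
  model <- match.arg(model)
  gen <- if (model == "f0_lineage") "F0" else "F2"
  ph <- phenotypes[phenotypes$generation == gen, ]
  if (model == "f2_behavior" && is.null(behavior)) stop("behavior must be given")
  counts <- counts[, ph$sample_id, drop = FALSE]
  kept <- filter_low_expression(counts, fraction = filter_fraction)
  d <- build_design(ph, model, behavior, interaction)
  f <- tmm_factors(kept)
  lcpm <- log2_cpm(kept, f)
  w <- if (use_voom) voom_weights(kept, d$design, lib_size = colSums(kept) * f) else NULL
  fits <- fit_gene_models(lcpm, d$design, weights = w)
  eb <- ebayes_moderate(fits)
  ci <- match(d$term, colnames(eb$coefficients))
  if (is.na(ci)) stop("term of interest not found in design: ", d$term)
  res <- tibble::tibble(
    gene_id = rownames(kept),
    log2fc = eb$coefficients[, ci],
    ave_expr = eb$Amean,
    t_ordinary = fits$t_ordinary[, ci],
    t = eb$t[, ci],
    p = eb$p.value[, ci],
    q = bh_fdr(eb$p.value[, ci])
  )
  structure(res,
            class = c("de_result", class(res)),
            d0 = eb$df.prior, s0_2 = eb$s2.prior,
            model = model, term = d$term,
            behavior = behavior,
            n_samples = nrow(ph),
            n_filtered = attr(kept, "n_removed"))
}

#' Correlate top expression principal components with covariates
#'
#' Diagnostic backing covariate selection: reports Pearson correlations of
#' the top PCs of the log2 CPM matrix with each numeric covariate and with
#' dummy codings of each categorical covariate.
#'
#' @param log2cpm Genes x samples matrix.
#' @param phenotypes Covariate tibble, rows aligned with samples.
#' @param covariates Covariate column names to test.
#' @param n_pcs Number of PCs (default 5).
#' @return Tibble with `pc`, `covariate`, `level`, `r`.
#' @export
pca_diagnostics <- function(log2cpm, phenotypes, covariates, n_pcs = 5) {
  pcs <- unit_pc_scores(t(log2cpm), n_pcs)
  purrr::map_dfr(covariates, function(cv) {
    x <- phenotypes[[cv]]
    cols <- if (is.numeric(x)) {
      stats::setNames(list(x), cv)
    } else {
      lv <- unique(x)[-1]
      stats::setNames(lapply(lv, function(l) as.integer(x == l)),
                      paste0(cv, "=", lv))
    }
    purrr::imap_dfr(cols, function(v, nm) {
      tibble::tibble(pc = paste0("PC", seq_len(n_pcs)), covariate = cv,
                     level = nm, r = as.numeric(stats::cor(pcs, v)))
    })
  })
}
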