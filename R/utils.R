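#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the master seed plus the stage name, so a single integer reproduces
#' the whole run while stages stay independent.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master_seed) %% 1000003L) * 2047L + (h %% 65521L)) %% 2147483646L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment. `NA` p-values are excluded from
#' the ranking and propagated as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Rank-based inverse normal transformation
#'
#' Blom scores: \eqn{\Phi^{-1}((r_i - 3/8) / (n + 1/4))} with ties assigned
#' average ranks.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Numeric vector of normal scores.
#' @export
rint <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(unique(x)) < 2L) stop("rint() is undefined for a constant vector")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

# Column-center a matrix and return orthonormal left singular vectors of the
# centered data (unit-norm principal component scores).
unit_pc_scores <- function(x, n_pcs) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (min(dim(xc)) < n_pcs) {
    stop("fewer dimensions (", min(dim(xc)), ") than requested PCs (", n_pcs, ")")
  }
  sv <- svd(xc, nu = n_pcs, nv = 0)
  u <- sv$u[, seq_len(n_pcs), drop = FALSE]
  colnames(u) <- paste0("PC", seq_len(n_pcs))
  u
}
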