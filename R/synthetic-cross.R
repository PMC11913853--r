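#' Draw one gamete from a phased parent under the Haldane model
#'
#' Crossover counts per chromosome are Poisson with mean equal to the map
#' length in Morgans, crossover positions are uniform on the centimorgan map,
#' and there is no interference. The starting haplotype is chosen at random
#' per chromosome.
#'
#' @param hap1,hap2 Phased parental haplotypes (0/1 vectors, one entry per
#'   SNP, same order as `map`).
#' @param map Data frame with columns `chrom` and `pos_cM`, positions
#'   non-decreasing within chromosome.
#' @return Integer 0/1 vector: the transmitted haplotype.
#' @export
make_gamete <- function(hap1, hap2, map) {
  if (is.null(hap1) || is.null(hap2) || length(hap1) != length(hap2)) {
    stop("parent haplotypes must be phased (two allele vectors of equal length)")
  }
  stopifnot(length(hap1) == nrow(map))
  out <- integer(length(hap1))
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    cm <- map$pos_cM[i]
    if (is.unsorted(cm)) stop("map positions must be monotone within chromosome")
    len_morgan <- if (length(cm)) max(cm) / 100 else 0
    n_xo <- stats::rpois(1, len_morgan)
    start <- sample.int(2L, 1L)
    if (n_xo == 0 || length(cm) == 0 || max(cm) == 0) {
      phase <- rep(start, length(i))
    } else {
      xo <- sort(stats::runif(n_xo, 0, max(cm)))
      # parity of crossovers to the left decides the source haplotype
      n_left <- findInterval(cm, xo)
      phase <- 1L + (start - 1L + n_left) %% 2L
    }
    out[i] <- ifelse(phase == 1L, hap1[i], hap2[i])
  }
  out
}

#' Simulate an F0 x F0 -> F1 -> F2 intercross
#'
#' Each F1 has one parent from each founder line; F2s come from random
#' non-sib F1 x F1 pairs. Phase is tracked throughout so Mendelian
#' consistency is checkable, and a pedigree is recorded.
#'
#' @param founders Output of [simulate_founder_lines()].
#' @param genome A `genome_config` (supplies the genetic map).
#' @param n_f1 Number of F1 individuals (>= 2).
#' @param n_f2 Number of F2 individuals.
#' @param seed Integer seed.
#' @return A list with `hap1`/`hap2`/`dosage` for the F2s, `sample_id`,
#'   `pedigree` (f2 id, f1 mother/father ids, their founder parents), and the
#'   F1 haplotypes.
#' @export
simulate_cross <- function(founders, genome, n_f1 = 50, n_f2 = 250, seed = 1L) {
  if (n_f1 < 2) stop("need at least two F1 individuals to intercross")
  set.seed(derive_seed(seed, "cross"))
  map <- genome$snps[, c("chrom", "pos_cM")]
  idx_bHR <- which(founders$line == "bHR")
  idx_bLR <- which(founders$line == "bLR")

  f1_hap1 <- matrix(0L, n_f1, nrow(map))
  f1_hap2 <- matrix(0L, n_f1, nrow(map))
  f1_parents <- tibble::tibble(
    f1_id = sprintf("F1_%03d", seq_len(n_f1)),
    parent_bHR = founders$sample_id[sample(idx_bHR, n_f1, replace = TRUE)],
    parent_bLR = founders$sample_id[sample(idx_bLR, n_f1, replace = TRUE)]
  )
  for (k in seq_len(n_f1)) {
    pa <- match(f1_parents$parent_bHR[k], founders$sample_id)
    pb <- match(f1_parents$parent_bLR[k], founders$sample_id)
    f1_hap1[k, ] <- make_gamete(founders$hap1[pa, ], founders$hap2[pa, ], map)
    f1_hap2[k, ] <- make_gamete(founders$hap1[pb, ], founders$hap2[pb, ], map)
  }

  # random non-sib F1 pairs (re-drawn on the rare sib collision)
  pick_pair <- function() {
    repeat {
      pr <- sample.int(n_f1, 2L)
      sib <- f1_parents$parent_bHR[pr[1]] == f1_parents$parent_bHR[pr[2]] &&
        f1_parents$parent_bLR[pr[1]] == f1_parents$parent_bLR[pr[2]]
      if (!sib) return(pr)
    }
  }
  f2_hap1 <- matrix(0L, n_f2, nrow(map))
  f2_hap2 <- matrix(0L, n_f2, nrow(map))
  ped <- vector("list", n_f2)
  for (k in seq_len(n_f2)) {
    pr <- pick_pair()
    f2_hap1[k, ] <- make_gamete(f1_hap1[pr[1], ], f1_hap2[pr[1], ], map)
    f2_hap2[k, ] <- make_gamete(f1_hap1[pr[2], ], f1_hap2[pr[2], ], map)
    ped[[k]] <- tibble::tibble(
      f2_id = sprintf("F2_%03d", k),
      parent1 = f1_parents$f1_id[pr[1]], parent2 = f1_parents$f1_id[pr[2]]
    )
  }
  sample_id <- sprintf("F2_%03d", seq_len(n_f2))
  colnames(f2_hap1) <- colnames(f2_hap2) <- genome$snps$snp_id
  rownames(f2_hap1) <- rownames(f2_hap2) <- sample_id
  list(
    hap1 = f2_hap1, hap2 = f2_hap2, dosage = f2_hap1 + f2_hap2,
    sample_id = sample_id,
    pedigree = dplyr::bind_rows(ped) |>
      dplyr::left_join(f1_parents, by = c(parent1 = "f1_id")) |>
      dplyr::rename(p1_bHR = "parent_bHR", p1_bLR = "parent_bLR") |>
      dplyr::left_join(f1_parents, by = c(parent2 = "f1_id")) |>
      dplyr::rename(p2_bHR = "parent_bHR", p2_bLR = "parent_bLR"),
    f1 = list(hap1 = f1_hap1, hap2 = f1_hap2, parents = f1_parents)
  )
}
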