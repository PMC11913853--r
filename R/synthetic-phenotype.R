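#' Simulate correlated behaviors for a genotyped cohort
#'
#' Each behavior is a sum of planted QTL effects (per alternate-allele dose),
#' a sex term, a shared latent factor that couples the behaviors along the
#' bLR-like axis, and independent Gaussian noise:
#' \deqn{y_{ib} = \sum_q d_{iq} e_{qb} + s_b \,\mathrm{I}(\mathrm{female}_i)
#'   + m_b \,\sigma_{poly} g_i + \sigma_b \epsilon_{ib}}
#' where \eqn{m_b} is the behavior's bLR-axis multiplier, so the shared factor
#' induces the correlation structure observed between temperament measures
#' (e.g. locomotion and immobility anticorrelated).
#'
#' @param dosages Individuals x SNPs dosage matrix with SNP-id column names.
#' @param planted_qtls Tibble with `variant_id`, `behavior_name`,
#'   `effect_size` (per-dose shift, behavior units), optional
#'   `pleiotropic_gene`.
#' @param sex Character/factor vector ("M"/"F") per individual.
#' @param sex_effect Named vector of per-behavior female-minus-male shifts
#'   (recycled scalar allowed).
#' @param polygenic_sd SD of the shared latent factor contribution.
#' @param noise_sd Independent noise SD (scalar or per-behavior named).
#' @param sign_convention Tibble from [default_sign_convention()].
#' @param behaviors Character vector of behavior names to generate.
#' @param seed Integer seed.
#' @return Tibble: one row per individual, one column per behavior.
#' @export
simulate_behavior <- function(dosages, planted_qtls, sex,
                              sex_effect = 0, polygenic_sd = 1, noise_sd = 1,
                              sign_convention = default_sign_convention(),
                              behaviors = behavior_names(), seed = 1L) {
  stopifnot(nrow(dosages) == length(sex))
  if (nrow(planted_qtls) > 0) {
    bad <- setdiff(planted_qtls$behavior_name, behaviors)
    if (length(bad)) stop("unknown behavior name(s): ", paste(bad, collapse = ", "))
    missing_v <- setdiff(planted_qtls$variant_id, colnames(dosages))
    if (length(missing_v)) stop("QTL variant id(s) not in dosage matrix: ",
                                paste(missing_v, collapse = ", "))
  }
  set.seed(derive_seed(seed, "behavior"))
  n <- nrow(dosages)
  mult <- sign_multiplier(sign_convention, behaviors)
  sex_eff <- if (length(sex_effect) == 1) stats::setNames(rep(sex_effect, length(behaviors)), behaviors) else sex_effect
  noise <- if (length(noise_sd) == 1) stats::setNames(rep(noise_sd, length(behaviors)), behaviors) else noise_sd
  g <- stats::rnorm(n)
  female <- as.integer(sex == "F")
  out <- matrix(0, n, length(behaviors), dimnames = list(NULL, behaviors))
  for (b in seq_along(behaviors)) {
    y <- polygenic_sd * mult[b] * g +
      sex_eff[behaviors[b]] * female +
      noise[behaviors[b]] * stats::rnorm(n)
    q <- planted_qtls[planted_qtls$behavior_name == behaviors[b], ]
    if (nrow(q)) {
      y <- y + as.numeric(dosages[, q$variant_id, drop = FALSE] %*% q$effect_size)
    }
    out[, b] <- y
  }
  tibble::as_tibble(out)
}

#' Pavlovian conditioned approach (PavCA) composite index
#'
#' The index is the mean of three components: the probability difference
#' (lever contact minus magazine entry probability), the response bias
#' ((lever - magazine contacts) / (lever + magazine contacts)), and the
#' latency score ((magazine latency - lever latency) / CS duration).
#' Animals with index > 0.5 are classed sign-trackers (ST), < -0.5
#' goal-trackers (GT), otherwise intermediate (IN); the class bounds are not
#' themselves exceeded at equality.
#'
#' @param prob_lever,prob_magazine Contact probabilities in `[0, 1]`.
#' @param n_lever_contacts,n_magazine_entries Non-negative counts.
#' @param latency_lever_s,latency_magazine_s Latencies in `[0, cs_duration_s]`.
#' @param cs_duration_s Conditioned-stimulus duration in seconds (default 8).
#' @return Tibble with `prob_difference`, `response_bias`, `latency_score`,
#'   `pavca_index`, `class` (ST/IN/GT), and `flag_undefined_bias` where the
#'   response bias has a zero denominator.
#' @export
compute_pavca_index <- function(prob_lever, prob_magazine,
                                n_lever_contacts, n_magazine_entries,
                                latency_lever_s, latency_magazine_s,
                                cs_duration_s = 8) {
  stopifnot(all(prob_lever >= 0 & prob_lever <= 1),
            all(prob_magazine >= 0 & prob_magazine <= 1),
            all(n_lever_contacts >= 0), all(n_magazine_entries >= 0),
            all(latency_lever_s >= 0 & latency_lever_s <= cs_duration_s),
            all(latency_magazine_s >= 0 & latency_magazine_s <= cs_duration_s))
  prob_diff <- prob_lever - prob_magazine
  tot <- n_lever_contacts + n_magazine_entries
  bias <- ifelse(tot == 0, NA_real_, (n_lever_contacts - n_magazine_entries) / tot)
  latency <- (latency_magazine_s - latency_lever_s) / cs_duration_s
  idx <- (prob_diff + bias + latency) / 3
  tibble::tibble(
    prob_difference = prob_diff,
    response_bias = bias,
    latency_score = latency,
    pavca_index = idx,
    class = dplyr::case_when(
      is.na(idx) ~ NA_character_,
      idx > 0.5 ~ "ST",
      idx < -0.5 ~ "GT",
      TRUE ~ "IN"
    ),
    flag_undefined_bias = tot == 0
  )
}
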