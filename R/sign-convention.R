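#' Default sign convention for the bLR-like axis
#'
#' Each analysis gets a multiplier mapping its t-statistic / Log2FC onto an
#' axis where positive means "bLR-like up": the bred Low-Responder (bLR)
#' phenotype is inhibited and anxious, so lower locomotion, lower distance
#' traveled, less open-arm time and a lower Pavlovian conditioned approach
#' (PavCA) index are bLR-like, while more time immobile is bLR-like. The
#' bLR-vs-bHR contrast itself is already on that axis.
#'
#' @return A tibble with columns `analysis` and `multiplier` (+1 or -1).
#' @export
default_sign_convention <- function() {
  tibble::tibble(
    analysis = c("F0_lineage", "meta", "LocoScore", "EPM_DistanceTraveled",
                 "EPM_TimeImmobile", "EPM_PctOpenArms", "PavCA_Index"),
    multiplier = c(1, 1, -1, -1, 1, -1, -1)
  )
}

#' Behavior names used by the synthetic cohort and the convergence pipeline
#' @return Character vector of the five adult behaviors.
#' @export
behavior_names <- function() {
  c("LocoScore", "EPM_DistanceTraveled", "EPM_TimeImmobile",
    "EPM_PctOpenArms", "PavCA_Index")
}

sign_multiplier <- function(sign_convention, analysis) {
  m <- sign_convention$multiplier[match(analysis, sign_convention$analysis)]
  if (any(is.na(m))) {
    stop("no sign-convention entry for: ",
         paste(analysis[is.na(m)], collapse = ", "))
  }
  m
}
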