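# Plate-count arithmetic for laboratory survival-rate determination.

#' Baseline viability of the as-received formulation
#'
#' Colony-forming units per tablet-equivalent of uncompressed formulation.
#' @export
SB_DEFAULT <- 3.9e7

#' Viable count per tablet from a plate count
#'
#' `S = NP * VI / (r * VF)`: the colony count is scaled by the initial
#' suspension volume over the product of the cumulative dilution fraction
#' and the plated volume (standard plate-count convention).
#'
#' @param NP colony count on the plate (CFU, non-negative).
#' @param VI initial suspension volume, ml.
#' @param r cumulative dilution fraction (e.g. `1e-3`), in `(0, 1]`.
#' @param VF plated volume, ml.
#' @return viable count per tablet, CFU.
#' @examples
#' cfu_per_tablet(78, VI = 50, r = 1e-3, VF = 0.1)  # 3.9e7
#' @export
cfu_per_tablet <- function(NP, VI, r, VF) {
  if (any(NP < 0)) stop("colony count NP cannot be negative")
  if (any(VI <= 0) || any(VF <= 0))
    stop("volumes VI and VF must be positive")
  if (any(r <= 0) || any(r > 1))
    stop("dilution fraction r must be in (0, 1]")
  NP * VI / (r * VF)
}

#' Survival rate relative to the baseline formulation
#'
#' `SR = 100 * S / Sb` (percent); values above 100 are possible for
#' gentle conditions.
#'
#' @param S viable count per tablet, CFU.
#' @param Sb baseline viability per tablet, CFU (default
#'   [SB_DEFAULT]).
#' @return survival rate, percent.
#' @export
survival_rate <- function(S, Sb = SB_DEFAULT) {
  if (any(Sb <= 0)) stop("baseline viability Sb must be positive")
  if (any(S < 0)) stop("viable count S cannot be negative")
  100 * S / Sb
}

#' Survival rates from a plate-count table
#'
#' Reads records with columns `sample_id, NP, VI_ml, r, VF_ml`, averages
#' duplicate plates sharing a `sample_id`, and computes per-sample viable
#' counts and survival rates.
#'
#' @param records data.frame or path to a CSV file with the columns
#'   above.
#' @param Sb baseline viability per tablet, CFU.
#' @return data.frame with one row per `sample_id`: `S_cfu`,
#'   `survival_pct`.
#' @export
plate_survival <- function(records, Sb = SB_DEFAULT) {
  if (is.character(records)) records <- utils::read.csv(records)
  need <- c("sample_id", "NP", "VI_ml", "r", "VF_ml")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  ids <- unique(records$sample_id)
  out <- lapply(ids, function(id) {
    g <- records[records$sample_id == id, , drop = FALSE]
    s <- mean(cfu_per_tablet(g$NP, g$VI_ml, g$r, g$VF_ml))
    data.frame(sample_id = id, S_cfu = s,
               survival_pct = survival_rate(s, Sb))
  })
  do.call(rbind, out)
}
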