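#' Bioactivity exposure ratio
#'
#' `BER = AED / exposure` on the arithmetic scale and
#' `log10BER = log10(AED) - log10(exposure)` on the log scale; the two
#' representations are exact transforms of each other.
#'
#' @param aed Administered equivalent dose, mg/kg bw/day (> 0).
#' @param exposure Human exposure estimate, mg/kg bw/day (> 0).
#' @return Tibble with columns `ber` and `log10ber` (vectorized).
#' @export
compute_ber <- function(aed, exposure) {
  if (any(aed <= 0, na.rm = TRUE)) stop("AED must be positive")
  if (any(exposure <= 0, na.rm = TRUE)) stop("exposure must be positive")
  tibble::tibble(ber = aed / exposure, log10ber = log10(aed) - log10(exposure))
}

#' Priority band from a log10 BER
#'
#' The bands partition the log10BER line: below 0 (exposure exceeds the
#' bioactivity-derived dose), 0 to 2 (BER under 100, the conventional
#' priority flag), 2 to 3, and 3 or more.
#'
#' @param log10ber Numeric.
#' @return Factor with levels `ber_lt_0`, `0_to_2`, `2_to_3`, `gt_3`.
#' @export
ber_band <- function(log10ber) {
  cut(log10ber,
    breaks = c(-Inf, 0, 2, 3, Inf),
    labels = c("ber_lt_0", "0_to_2", "2_to_3", "gt_3"),
    right = FALSE
  )
}

#' Rank chemicals by BER and tally priority bands
#'
#' Chemicals without a finite log10BER (missing or zero exposure) are
#' excluded from ranking and reported separately rather than given an
#' infinite ratio.
#'
#' @param records Tibble with columns `casrn` and `log10ber` (e.g. from
#'   [compute_ber()] bound to identifiers); extra columns are carried along.
#' @return List with `ranked` (ascending `log10ber`, ties broken by `casrn`,
#'   with a `band` column), `band_counts` (tibble of counts per band), and
#'   `excluded` (rows without a finite log10ber).
#' @export
rank_and_band <- function(records) {
  ok <- is.finite(records$log10ber)
  ranked <- records[ok, , drop = FALSE]
  ranked <- ranked[order(ranked$log10ber, ranked$casrn), , drop = FALSE]
  ranked$band <- ber_band(ranked$log10ber)
  band_counts <- ranked |>
    dplyr::count(.data$band, .drop = FALSE, name = "n")
  list(
    ranked = tibble::as_tibble(ranked),
    band_counts = band_counts,
    excluded = tibble::as_tibble(records[!ok, , drop = FALSE])
  )
}

#' Compare an AED with traditional in vivo points of departure
#'
#' For one chemical, the minimum POD overall and within each study type, and
#' the log10 difference `log10(min POD) - log10(AED)`; a positive difference
#' means the bioactivity-derived dose is protective (lower than the
#' traditional POD).
#'
#' @param aed AED in mg/kg bw/day.
#' @param pods Tibble with columns `pod_mg_kg_day` (> 0) and `study_type`
#'   (`"cancer"` or `"genetox"`).
#' @return Tibble with one row per basis (`overall`, `cancer`, `genetox`)
#'   and columns `min_pod`, `log10_difference`; bases without PODs are absent.
#' @export
pod_comparison <- function(aed, pods) {
  if (is.null(pods) || nrow(pods) == 0) {
    return(tibble::tibble(
      basis = character(), min_pod = numeric(), log10_difference = numeric()
    ))
  }
  if (any(pods$pod_mg_kg_day <= 0)) stop("PODs must be positive")
  one <- function(basis, sub) {
    if (!nrow(sub)) {
      return(NULL)
    }
    m <- min(sub$pod_mg_kg_day)
    tibble::tibble(
      basis = basis, min_pod = m, log10_difference = log10(m) - log10(aed)
    )
  }
  dplyr::bind_rows(
    one("overall", pods),
    one("cancer", pods[pods$study_type == "cancer", , drop = FALSE]),
    one("genetox", pods[pods$study_type == "genetox", , drop = FALSE])
  )
}

#' Fraction of a cohort where the AED is protective
#'
#' @param log10_differences Per-chemical `log10(min POD) - log10(AED)` values.
#' @return Fraction strictly greater than zero.
#' @export
protective_fraction <- function(log10_differences) {
  x <- log10_differences[!is.na(log10_differences)]
  if (!length(x)) {
    return(NA_real_)
  }
  mean(x > 0)
}
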