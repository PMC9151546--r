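#' Per-well endpoint percentage from gated event counts
#'
#' A flow-cytometric endpoint (micronucleated or hypodiploid events) is
#' expressed as a percent frequency of the nucleated events acquired in the
#' same well.
#'
#' @param events_in_gate Non-negative event count inside the endpoint gate.
#' @param nucleated_events Positive count of nucleated events in the well.
#' @return Percentage on the 0-100 scale (vectorized).
#' @examples
#' percent_endpoint(2, 100)   # 2
#' percent_endpoint(0, 5000)  # 0
#' @export
percent_endpoint <- function(events_in_gate, nucleated_events) {
  if (any(events_in_gate < 0, na.rm = TRUE)) {
    stop("`events_in_gate` must be non-negative")
  }
  if (any(nucleated_events <= 0, na.rm = TRUE)) {
    stop("endpoint percentage is undefined when `nucleated_events` is zero")
  }
  events_in_gate / nucleated_events * 100
}

#' Relative survival from nuclei-to-bead ratios
#'
#' The cytotoxicity metric of the assay: the treated well's nuclei:counting-bead
#' ratio divided by the vehicle-control ratio, times 100. Values above 100
#' occur in real data (proliferative responses) and are deliberately not
#' clipped.
#'
#' @param sample_ratio Nuclei:bead ratio of the treated well.
#' @param control_ratio Nuclei:bead ratio of the vehicle control (> 0).
#' @return Relative survival in percent (vectorized).
#' @export
relative_survival <- function(sample_ratio, control_ratio) {
  if (any(control_ratio <= 0, na.rm = TRUE)) {
    stop("control nuclei:bead ratio must be positive")
  }
  sample_ratio / control_ratio * 100
}

#' Fold change of an endpoint over its concurrent solvent control
#'
#' Returns `NA` (with a message) where the control percentage is zero, since
#' the ratio is undefined; missingness propagates downstream rather than
#' erroring.
#'
#' @param treated_percent Endpoint percentage in the treated well.
#' @param concurrent_control_percent Endpoint percentage of the concurrent
#'   control.
#' @return Ratio, or `NA` where the baseline is zero.
#' @export
fold_change <- function(treated_percent, concurrent_control_percent) {
  out <- treated_percent / concurrent_control_percent
  zero <- !is.na(concurrent_control_percent) & concurrent_control_percent == 0
  if (any(zero)) {
    message(sum(zero), " fold-change value(s) undefined (zero control); set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' Cytotoxicity category from relative survival
#'
#' Concentrations are categorized as `cytotoxic` (relative survival below 40
#' percent), `adequate` (40 to 60 percent, both bounds included so the three
#' categories partition the survival axis), or `non_cytotoxic` (above 60
#' percent). Only the non-cytotoxic and adequate categories enter trend
#' testing and concentration-response modeling.
#'
#' @param relative_survival Relative survival in percent (>= 0).
#' @return Factor with levels `cytotoxic`, `adequate`, `non_cytotoxic`.
#' @examples
#' classify_cytotoxicity(c(39.99, 40, 60, 100))
#' @export
classify_cytotoxicity <- function(relative_survival) {
  if (any(relative_survival < 0, na.rm = TRUE)) {
    stop("relative survival cannot be negative")
  }
  cut(relative_survival,
    breaks = c(-Inf, 40, 60, Inf),
    labels = c("cytotoxic", "adequate", "non_cytotoxic"),
    right = FALSE
  ) -> cat
  ## cut(right = FALSE) puts 40 in [40,60) and 60 in [60,Inf); pull 60 back so
  ## both quoted bounds land in "adequate".
  cat[!is.na(relative_survival) & relative_survival == 60] <- "adequate"
  cat
}

#' Fill in missing fold-change columns from concurrent controls
#'
#' Pre-computed fold changes in the input are trusted and passed through.
#' Where absent, the baseline for a treatment well is the chemical's own
#' concentration-zero well on the same plate and S9 condition; when that well
#' is missing, the mean of the plate's solvent-control wells is used.
#'
#' @param study Study table (see [read_plate_table()]).
#' @return The table with `mn_fold_change` and `hypo_fold_change` populated.
#' @export
add_fold_changes <- function(study) {
  baseline_for <- function(df) {
    own <- df$concentration == 0 & df$role == "treatment"
    list(
      mn = if (any(own)) mean(df$mn_percent[own]) else NA_real_,
      hypo = if (any(own)) mean(df$hypo_percent[own]) else NA_real_
    )
  }
  plate_dmso <- study |>
    dplyr::filter(.data$role == "solvent_control") |>
    dplyr::group_by(.data$plate_id, .data$s9) |>
    dplyr::summarise(
      dmso_mn = mean(.data$mn_percent),
      dmso_hypo = mean(.data$hypo_percent),
      .groups = "drop"
    )
  study |>
    dplyr::group_by(.data$chemical_id, .data$plate_id, .data$s9) |>
    dplyr::group_modify(function(df, key) {
      if (all(df$role != "treatment")) {
        return(df)
      }
      base <- baseline_for(df)
      dm <- plate_dmso[plate_dmso$plate_id == key$plate_id &
        plate_dmso$s9 == key$s9, ]
      mn_base <- if (!is.na(base$mn)) base$mn else if (nrow(dm)) dm$dmso_mn else NA_real_
      hypo_base <- if (!is.na(base$hypo)) base$hypo else if (nrow(dm)) dm$dmso_hypo else NA_real_
      trt <- df$role == "treatment" & df$concentration > 0
      fill <- trt & is.na(df$mn_fold_change)
      if (any(fill) && !is.na(mn_base)) {
        df$mn_fold_change[fill] <- fold_change(df$mn_percent[fill], mn_base)
      }
      fill <- trt & is.na(df$hypo_fold_change)
      if (any(fill) && !is.na(hypo_base)) {
        df$hypo_fold_change[fill] <- fold_change(df$hypo_percent[fill], hypo_base)
      }
      df
    }) |>
    dplyr::ungroup()
}
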