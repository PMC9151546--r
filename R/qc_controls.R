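#' Batch reference threshold for a control endpoint
#'
#' The upper p-th percentile (default 95) of the solvent-control distribution
#' of an endpoint within one batch date, using the linearly interpolated
#' type-7 quantile estimator. These thresholds are what each treated
#' concentration is compared against in the decision tree.
#'
#' @param values Numeric endpoint values (percent) of one pooled control group.
#' @param p Percentile, 0-100.
#' @param batch Optional batch label used in error messages.
#' @return The threshold (scalar).
#' @examples
#' batch_reference(c(1, 2, 3, 4, 5)) # 4.8
#' @export
batch_reference <- function(values, p = 95, batch = NULL) {
  if (length(values) == 0) {
    stop("no control wells for batch ", if (is.null(batch)) "<unnamed>" else batch)
  }
  if (any(!is.finite(values))) stop("non-finite control endpoint value")
  if (length(values) == 1) {
    warning("batch ", if (is.null(batch)) "" else paste0(batch, " "),
      "has a single control well; percentile equals that value")
    return(values)
  }
  unname(quantile(values, p / 100, type = 7))
}

#' Batch reference table for a study
#'
#' Computes the per-batch, per-S9 reference percentiles of solvent-control
#' %MN and %hypodiploid from the wells surviving QC exclusions.
#'
#' @param study Study table (after [apply_exclusions()]).
#' @param p Percentile, 0-100.
#' @return Tibble with columns `batch_date`, `s9`, `mn_p95`, `hypo_p95`,
#'   `n_controls`.
#' @export
batch_references <- function(study, p = 95) {
  ctrl <- study[study$role == "solvent_control", , drop = FALSE]
  if (nrow(ctrl) == 0) stop("study has no solvent-control wells")
  ctrl |>
    dplyr::group_by(.data$batch_date, .data$s9) |>
    dplyr::summarise(
      mn_p95 = batch_reference(.data$mn_percent, p, batch = .data$batch_date[1]),
      hypo_p95 = batch_reference(.data$hypo_percent, p, batch = .data$batch_date[1]),
      n_controls = dplyr::n(),
      .groups = "drop"
    )
}

#' Wide batch-reference export
#'
#' One row per batch date with the four threshold columns side by side
#' (minus/plus S9 for each endpoint), the layout used for reporting.
#'
#' @param refs Output of [batch_references()].
#' @return Wide tibble.
#' @export
reference_table <- function(refs) {
  refs |>
    dplyr::mutate(cond = ifelse(.data$s9, "plus_s9", "minus_s9")) |>
    dplyr::select(-"s9", -"n_controls") |>
    tidyr::pivot_wider(
      names_from = "cond",
      values_from = c("mn_p95", "hypo_p95")
    ) |>
    dplyr::arrange(.data$batch_date)
}

#' Flag outlying control wells (advisory)
#'
#' Robust screen mechanizing visual outlier inspection of pooled control
#' distributions: a well is flagged when its absolute deviation from the
#' group median exceeds `k` times the scaled MAD. Flags never remove data;
#' removals go through the explicit exclusion list.
#'
#' @param values Numeric endpoint values.
#' @param k Robust-z cutoff (default 3.5).
#' @return Logical vector of flags (all `FALSE` when fewer than 3 wells or the
#'   spread is zero).
#' @export
flag_outlier_controls <- function(values, k = 3.5) {
  n <- length(values)
  if (n < 3) {
    if (n > 0) warning("fewer than 3 wells; outlier screen not applied")
    return(rep(FALSE, n))
  }
  s <- mad(values) # 1.4826 * MAD, consistent for the normal
  if (s == 0) {
    return(rep(FALSE, n))
  }
  abs(values - median(values)) / s > k
}

#' Positive-control summaries per concentration
#'
#' Mean and SD of %MN and relative survival for each positive-control agent,
#' concentration, and batch, with advisory outlier flags computed within each
#' (agent, concentration) pool across batches — mirroring scatter-plot QC of
#' %MN against relative survival.
#'
#' @param study Study table.
#' @return Tibble with one row per (agent, concentration, batch) and columns
#'   `n`, `mn_mean`, `mn_sd`, `rs_mean`, `rs_sd`, `n_outliers`.
#' @export
positive_control_summary <- function(study) {
  pc <- study[study$role == "positive_control", , drop = FALSE]
  if (nrow(pc) == 0) {
    return(tibble::tibble(
      chemical_id = character(), s9 = logical(), concentration = numeric(),
      batch_date = character(), n = integer(),
      mn_mean = numeric(), mn_sd = numeric(),
      rs_mean = numeric(), rs_sd = numeric(), n_outliers = integer()
    ))
  }
  pc <- pc |>
    dplyr::group_by(.data$chemical_id, .data$s9, .data$concentration) |>
    dplyr::mutate(.outlier = flag_outlier_controls(.data$mn_percent)) |>
    dplyr::ungroup()
  pc |>
    dplyr::group_by(
      .data$chemical_id, .data$s9, .data$concentration, .data$batch_date
    ) |>
    dplyr::summarise(
      n = dplyr::n(),
      mn_mean = mean(.data$mn_percent),
      mn_sd = sd(.data$mn_percent),
      rs_mean = mean(.data$relative_survival),
      rs_sd = sd(.data$relative_survival),
      n_outliers = sum(.data$.outlier),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chemical_id, .data$s9, .data$concentration, .data$batch_date)
}
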