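#' Default 19-point concentration series
#'
#' Geometric series with ratio 1.25 ending at 200 uM, the wide screening
#' range that lets benchmark-concentration modeling replace replicate-based
#' designs (n = 1 well per concentration).
#'
#' @return Numeric vector of 19 concentrations in uM.
#' @export
default_concentration_series <- function() {
  c(
    3.60, 4.50, 5.63, 7.04, 8.80, 11.0, 13.7, 17.2, 21.5, 26.8,
    33.6, 41.9, 52.4, 65.5, 81.9, 102, 128, 160, 200
  )
}

#' Default ground-truth chemical set
#'
#' Twenty synthetic chemicals: ten clastogens (Hill-shaped %MN increases with
#' plateaus 3-6 fold over background, two of them requiring metabolic
#' activation), two aneugens (strong %hypodiploid induction, 20-25 fold, with
#' a moderate %MN rise), and eight inactives (four of which are cytotoxic at
#' the top of the range so their negatives are conclusive, four non-cytotoxic
#' so the decision tree must return inconclusive).
#'
#' @return Tibble with one row per chemical: `chemical_id`, `class`
#'   (`clastogen`/`aneugen`/`inactive`), Hill parameters `mn_b`, `mn_c`,
#'   `mn_d`, `hypo_b`, `hypo_c`, `hypo_d`, survival curve `surv_ec50` (uM)
#'   and `surv_slope`, and `s9_dependent`.
#' @export
default_truth <- function() {
  clast <- tibble::tibble(
    chemical_id = sprintf("CLAST-%02d", 1:10),
    class = "clastogen",
    mn_b = c(8, 12, 18, 25, 35, 50, 15, 22, 30, 40),
    mn_c = c(3, 4, 5, 6, 3.5, 4.5, 5.5, 3, 4, 6),
    mn_d = c(1.5, 2, 2.5, 3, 1.5, 2, 2.5, 3, 2, 2),
    hypo_b = 30, hypo_c = 1.2, hypo_d = 1,
    surv_ec50 = c(120, 140, 100, 160, 130, 110, 150, 125, 135, 145),
    surv_slope = 4,
    s9_dependent = c(rep(FALSE, 8), TRUE, TRUE)
  )
  aneu <- tibble::tibble(
    chemical_id = sprintf("ANEU-%02d", 1:2),
    class = "aneugen",
    mn_b = c(25, 35), mn_c = 5, mn_d = 2,
    hypo_b = c(25, 35), hypo_c = c(25, 20), hypo_d = 2,
    surv_ec50 = 150, surv_slope = 4,
    s9_dependent = FALSE
  )
  inac <- tibble::tibble(
    chemical_id = sprintf("INACT-%02d", 1:8),
    class = "inactive",
    mn_b = 30, mn_c = 1, mn_d = 1,
    hypo_b = 30, hypo_c = 1, hypo_d = 1,
    surv_ec50 = c(rep(170, 4), rep(Inf, 4)),
    surv_slope = 4,
    s9_dependent = FALSE
  )
  dplyr::bind_rows(clast, aneu, inac)
}

#' Simulation configuration for a plate-structured study
#'
#' The defaults encode the emulated study conditions: the 19-point 1.25x
#' concentration series to 200 uM; eight solvent-control and six
#' positive-control wells per plate plus four chemicals of 19 concentrations
#' and a concurrent control each; solvent-control dispersion of one SD of
#' roughly 30 percent of the mean for %MN and 60 percent for %hypodiploid
#' (which is what motivates the endpoint BMRs of 0.30 and 0.60); modest
#' multiplicative batch-to-batch variation of control levels; and
#' concentration-dependent survival declines. Endpoint noise is
#' multiplicative lognormal at the same coefficients of variation, matching
#' the dose-response error model.
#'
#' @param n_batches Number of batch dates.
#' @param concentration_series Strictly increasing uM series.
#' @param control_mn_mean,control_hypo_mean Named `c(minus=, plus=)` control
#'   means in percent for the two S9 conditions.
#' @param control_mn_cv,control_hypo_cv Lognormal coefficients of variation.
#' @param survival_cv CV of the multiplicative survival noise.
#' @param batch_effect_sd Lognormal sd of the per-batch control-level
#'   multiplier.
#' @param truth Ground-truth chemical table (see [default_truth()]).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return Named list of class `simulation_config`.
#' @export
simulation_config <- function(n_batches = 2,
                              concentration_series = default_concentration_series(),
                              control_mn_mean = c(minus = 1.2, plus = 1.1),
                              control_mn_cv = 0.30,
                              control_hypo_mean = c(minus = 0.35, plus = 0.20),
                              control_hypo_cv = 0.60,
                              survival_cv = 0.08,
                              batch_effect_sd = 0.10,
                              truth = default_truth(),
                              seed = 20240101) {
  if (any(diff(concentration_series) <= 0)) {
    stop("concentration series must be strictly increasing")
  }
  if (any(c(control_mn_cv, control_hypo_cv, survival_cv, batch_effect_sd) < 0)) {
    stop("dispersion parameters cannot be negative")
  }
  structure(
    list(
      n_batches = n_batches,
      concentration_series = concentration_series,
      control_mn_mean = control_mn_mean, control_mn_cv = control_mn_cv,
      control_hypo_mean = control_hypo_mean, control_hypo_cv = control_hypo_cv,
      survival_cv = survival_cv, batch_effect_sd = batch_effect_sd,
      truth = truth, seed = seed
    ),
    class = "simulation_config"
  )
}

## lognormal draw with arithmetic mean m and coefficient of variation cv
.rln <- function(n, m, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

.truth_mn_curve <- function(row, x, a, s9) {
  c_eff <- if (row$s9_dependent && !s9) 1 else row$mn_c
  .dr_curve("hill5", x, a, row$mn_b, max(c_eff, 1 + 1e-9), row$mn_d)
}

.truth_hypo_curve <- function(row, x, a, s9) {
  c_eff <- if (row$s9_dependent && !s9) 1 else row$hypo_c
  .dr_curve("hill5", x, a, row$hypo_b, max(c_eff, 1 + 1e-9), row$hypo_d)
}

.truth_survival <- function(row, x) {
  if (!is.finite(row$surv_ec50)) {
    return(rep(100, length(x)))
  }
  100 / (1 + (x / row$surv_ec50)^row$surv_slope)
}

.positive_control_spec <- function(s9) {
  if (s9) {
    list(agent = "cyclophosphamide", conc = c(1.25, 2.5, 5))
  } else {
    list(agent = "vinblastine", conc = c(0.00625, 0.0125, 0.025))
  }
}

## Draw every well of one plate (one S9 condition) from the current RNG
## stream. Layout: 8 DMSO wells, 6 positive-control wells (3 concentrations
## in duplicate), then up to 4 chemicals x (19 concentrations + 1 concurrent
## control well).
.simulate_plate_wells <- function(config, batch_date, plate_id, s9, chemicals,
                                  batch_offset) {
  cond <- if (s9) "plus" else "minus"
  mn0 <- config$control_mn_mean[[cond]] * batch_offset
  hypo0 <- config$control_hypo_mean[[cond]] * batch_offset
  xs <- config$concentration_series

  well <- function(chemical_id, role, conc, mn_mean, hypo_mean, surv_mean) {
    tibble::tibble(
      chemical_id = chemical_id, plate_id = plate_id, batch_date = batch_date,
      s9 = s9, role = role, concentration = conc,
      mn_percent = pmin(.rln(length(conc), mn_mean, config$control_mn_cv), 100),
      hypo_percent = pmin(.rln(length(conc), hypo_mean, config$control_hypo_cv), 100),
      relative_survival = .rln(length(conc), surv_mean, config$survival_cv),
      mn_fold_change = NA_real_, hypo_fold_change = NA_real_
    )
  }

  out <- list(well("DMSO", "solvent_control", rep(0, 8), mn0, hypo0, 100))

  pc <- .positive_control_spec(s9)
  pc_fold <- c(2, 3, 4)
  pc_surv <- c(85, 70, 55)
  for (i in seq_along(pc$conc)) {
    out[[length(out) + 1]] <- well(
      pc$agent, "positive_control", rep(pc$conc[i], 2),
      mn0 * pc_fold[i], hypo0, pc_surv[i]
    )
  }

  for (ci in seq_len(nrow(chemicals))) {
    row <- chemicals[ci, ]
    out[[length(out) + 1]] <- well(
      row$chemical_id, "treatment", 0, mn0, hypo0, 100
    )
    out[[length(out) + 1]] <- well(
      row$chemical_id, "treatment", xs,
      .truth_mn_curve(row, xs, mn0, s9),
      .truth_hypo_curve(row, xs, hypo0, s9),
      .truth_survival(row, xs)
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate one plate
#'
#' Standalone, seeded version of the per-plate generator; mostly useful for
#' layout and determinism checks. [simulate_study()] manages batch offsets
#' and seeds across plates.
#'
#' @param config [simulation_config()].
#' @param batch_date Batch-date string.
#' @param s9 Logical condition.
#' @param chemicals Up to 4 rows of the truth table (defaults to the first 4).
#' @param seed Integer seed.
#' @param batch_offset Multiplier on the control means (default 1).
#' @param plate_id Plate identifier.
#' @return Study-table tibble for one plate.
#' @export
simulate_plate <- function(config, batch_date = "20240101", s9 = FALSE,
                           chemicals = utils::head(config$truth, 4),
                           seed = config$seed, batch_offset = 1,
                           plate_id = "plate01") {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  .simulate_plate_wells(config, batch_date, plate_id, s9, chemicals, batch_offset)
}

#' Simulate a full multi-batch study with known ground truth
#'
#' Chemicals are laid out four per plate; each plate is run under both S9
#' conditions; plates are assigned round-robin to batch dates, and each
#' batch carries a lognormal offset on its control levels. The truth table
#' reports each chemical's class, its planted benchmark concentrations
#' (closed-form inversion of the planted Hill parameters at BMR 0.30 for %MN
#' and 0.60 for %hypodiploid), and whether its activity requires S9.
#'
#' @param config [simulation_config()].
#' @return List with `wells` (canonical study table) and `truth` (tibble:
#'   `chemical_id`, `class`, `true_bmc30`, `true_bmc60`, `s9_dependent`).
#' @export
simulate_study <- function(config) {
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  truth <- config$truth
  n_groups <- ceiling(nrow(truth) / 4)
  batch_dates <- sprintf("202401%02d", seq_len(config$n_batches))
  offsets <- .rln(config$n_batches, 1, config$batch_effect_sd)

  plates <- list()
  for (g in seq_len(n_groups)) {
    chems <- truth[((g - 1) * 4 + 1):min(g * 4, nrow(truth)), , drop = FALSE]
    b <- ((g - 1) %% config$n_batches) + 1
    for (s9 in c(FALSE, TRUE)) {
      plates[[length(plates) + 1]] <- .simulate_plate_wells(
        config, batch_dates[b], sprintf("plate%02d", g), s9, chems, offsets[b]
      )
    }
  }
  wells <- dplyr::bind_rows(plates)

  hill_bmc <- function(b, c, d, bmr) {
    ifelse(c > 1 + bmr, b * (bmr / ((c - 1) - bmr))^(1 / d), NA_real_)
  }
  truth_out <- tibble::tibble(
    chemical_id = truth$chemical_id,
    class = truth$class,
    true_bmc30 = hill_bmc(truth$mn_b, truth$mn_c, truth$mn_d, 0.30),
    true_bmc60 = hill_bmc(truth$hypo_b, truth$hypo_c, truth$hypo_d, 0.60),
    s9_dependent = truth$s9_dependent
  )
  list(wells = wells, truth = truth_out)
}
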