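#' Default human physiology for steady-state IVIVE
#'
#' Point-estimate physiological constants for the three-compartment
#' steady-state model, all overridable: glomerular filtration rate (L/h/kg
#' body weight), liver blood flow (L/h/kg), microsomal protein content (32 mg
#' per g liver) and hepatocellularity (99 million cells per g liver) used for
#' clearance scaling, liver mass per kg body weight, blood:plasma ratio, and
#' a floor on the fraction unbound that keeps hepatic and renal clearance
#' away from zero for extensively bound chemicals.
#'
#' @param gfr Glomerular filtration rate, L/h/kg bw.
#' @param liver_blood_flow L/h/kg bw.
#' @param microsomal_protein_per_g_liver mg/g.
#' @param cells_per_g_liver 10^6 cells/g.
#' @param liver_mass_per_kg_bw g/kg.
#' @param blood_plasma_ratio Dimensionless.
#' @param fup_floor Minimum fraction unbound.
#' @return Named list of class `physiology_params`.
#' @export
default_physiology <- function(gfr = 0.31,
                               liver_blood_flow = 5.4,
                               microsomal_protein_per_g_liver = 32,
                               cells_per_g_liver = 99,
                               liver_mass_per_kg_bw = 24.5,
                               blood_plasma_ratio = 1,
                               fup_floor = 1e-4) {
  phys <- list(
    gfr = gfr, liver_blood_flow = liver_blood_flow,
    microsomal_protein_per_g_liver = microsomal_protein_per_g_liver,
    cells_per_g_liver = cells_per_g_liver,
    liver_mass_per_kg_bw = liver_mass_per_kg_bw,
    blood_plasma_ratio = blood_plasma_ratio,
    fup_floor = fup_floor
  )
  if (any(unlist(phys) <= 0)) stop("all physiology parameters must be positive")
  structure(phys, class = "physiology_params")
}

#' Scale microsomal intrinsic clearance to hepatocellularity units
#'
#' Converts human liver microsomal intrinsic clearance (uL/min/mg microsomal
#' protein) to per-million-hepatocyte units using 32 mg microsomal protein
#' per g liver and 99 million cells per g liver:
#' `Clint = HLM_Clint x 32 / 99` (uL/min/10^6 cells).
#'
#' @param hlm_clint uL/min/mg microsomal protein (>= 0).
#' @param microsomal_protein_per_g_liver mg/g (default 32).
#' @param cells_per_g_liver 10^6 cells/g (default 99).
#' @return uL/min/10^6 cells (vectorized).
#' @examples
#' scale_clint(99) # 32
#' @export
scale_clint <- function(hlm_clint, microsomal_protein_per_g_liver = 32,
                        cells_per_g_liver = 99) {
  if (any(hlm_clint < 0, na.rm = TRUE)) stop("intrinsic clearance cannot be negative")
  hlm_clint * microsomal_protein_per_g_liver / cells_per_g_liver
}

#' Steady-state plasma concentration at a unit infusion dose
#'
#' Three-compartment steady-state model: a constant infusion of 1 mg/kg
#' bw/day is cleared by hepatic metabolism (well-stirred liver model) and
#' renal filtration of the unbound fraction. Whole-liver intrinsic clearance
#' is assembled from the scaled microsomal clearance, hepatocellularity, and
#' liver mass; hepatic clearance is
#' `Q_l * fup * CLint_L / (Q_l + fup * CLint_L / Rb)` with liver blood flow
#' `Q_l` and blood:plasma ratio `Rb`, and renal clearance is `GFR * fup`.
#' The resulting Css in mg/L is converted to uM via the molecular weight.
#'
#' @param molecular_weight g/mol.
#' @param fup Fraction unbound in plasma (clamped below at
#'   `phys$fup_floor`).
#' @param hlm_clint uL/min/mg microsomal protein.
#' @param phys [default_physiology()] list.
#' @return Css in uM at 1 mg/kg bw/day (vectorized over chemicals).
#' @export
css_unit_infusion <- function(molecular_weight, fup, hlm_clint,
                              phys = default_physiology()) {
  if (any(molecular_weight <= 0, na.rm = TRUE)) stop("molecular weight must be positive")
  if (any(fup <= 0 | fup > 1, na.rm = TRUE)) stop("fup must lie in (0, 1]")
  fup <- pmax(fup, phys$fup_floor)
  clint_cell <- scale_clint(
    hlm_clint, phys$microsomal_protein_per_g_liver, phys$cells_per_g_liver
  )
  ## uL/min/10^6 cells -> L/h/kg bw
  clint_l <- clint_cell * phys$cells_per_g_liver * phys$liver_mass_per_kg_bw *
    60 * 1e-6
  cl_h <- phys$liver_blood_flow * fup * clint_l /
    (phys$liver_blood_flow + fup * clint_l / phys$blood_plasma_ratio)
  cl_r <- phys$gfr * fup
  total <- cl_r + cl_h
  if (any(total <= 0, na.rm = TRUE)) {
    stop("total clearance is zero; Css unbounded (check fup_floor)")
  }
  css_mg_l <- (1 / 24) / total # 1 mg/kg/day infusion, mg/L
  css_mg_l * 1000 / molecular_weight # uM
}

#' Administered equivalent dose from a benchmark concentration
#'
#' Linear IVIVE: the external dose rate whose steady-state plasma
#' concentration equals the in vitro benchmark concentration,
#' `AED = BMC (uM) / Css(uM at 1 mg/kg bw/day)` in mg/kg bw/day.
#'
#' @param bmc Benchmark concentration, uM (> 0).
#' @param css_unit Css at unit infusion, uM (> 0).
#' @return AED in mg/kg bw/day (vectorized).
#' @export
compute_aed <- function(bmc, css_unit) {
  if (any(css_unit <= 0, na.rm = TRUE)) stop("unit-dose Css must be positive")
  if (any(bmc <= 0, na.rm = TRUE)) stop("BMC must be positive")
  bmc / css_unit
}

#' AED table for a set of chemicals
#'
#' Joins chemical toxicokinetic parameters to BMCs and returns per-chemical
#' Css and AED.
#'
#' @param tk Tibble with columns `casrn`, `molecular_weight`, `fup`,
#'   `hlm_clint` (and optionally `log_p`, unused by the steady-state model
#'   but carried through).
#' @param bmc_table Tibble with columns `casrn` and `bmc` (uM).
#' @param phys [default_physiology()] list.
#' @return Tibble with `casrn`, `bmc`, `css_unit_uM`, `aed_mg_kg_day`;
#'   chemicals lacking kinetics or a BMC are dropped with a message.
#' @export
aed_table <- function(tk, bmc_table, phys = default_physiology()) {
  merged <- dplyr::inner_join(bmc_table, tk, by = "casrn")
  dropped <- nrow(bmc_table) - nrow(merged)
  if (dropped > 0) message(dropped, " chemical(s) lack toxicokinetic parameters")
  merged <- merged[!is.na(merged$bmc) & merged$bmc > 0, , drop = FALSE]
  merged$css_unit_uM <- css_unit_infusion(
    merged$molecular_weight, merged$fup, merged$hlm_clint, phys
  )
  merged$aed_mg_kg_day <- compute_aed(merged$bmc, merged$css_unit_uM)
  merged[, c("casrn", "bmc", "css_unit_uM", "aed_mg_kg_day")]
}
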