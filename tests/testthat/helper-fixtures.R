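# In-code fixtures: small study tables built programmatically.

well_row <- function(chemical_id, role, conc, mn, hypo = 0.3, rs = 100,
                     plate = "p1", batch = "b1", s9 = FALSE,
                     mn_fc = NA_real_, hypo_fc = NA_real_) {
  tibble::tibble(
    chemical_id = chemical_id, plate_id = plate, batch_date = batch,
    s9 = s9, role = role, concentration = conc, mn_percent = mn,
    hypo_percent = hypo, relative_survival = rs,
    mn_fold_change = mn_fc, hypo_fold_change = hypo_fc
  )
}

# one chemical's test: concurrent control + the concentration series
chemical_wells <- function(conc, mn, rs, chemical = "X", control_mn = 1,
                           hypo = NULL, control_hypo = 0.3,
                           plate = "p1", batch = "b1", s9 = FALSE) {
  if (is.null(hypo)) hypo <- rep(control_hypo, length(conc))
  dplyr::bind_rows(
    well_row(chemical, "treatment", 0, control_mn, control_hypo,
      100, plate, batch, s9),
    well_row(chemical, "treatment", conc, mn, hypo, rs, plate, batch, s9)
  )
}

# plate of solvent controls around a mean
dmso_wells <- function(mn, hypo = rep(0.3, length(mn)), plate = "p1",
                       batch = "b1", s9 = FALSE) {
  well_row("DMSO", "solvent_control", rep(0, length(mn)), mn, hypo,
    100, plate, batch, s9)
}

# small two-batch study: DMSO controls + two chemicals per batch
toy_study <- function() {
  conc <- c(5, 10, 20, 40, 80, 160)
  dplyr::bind_rows(
    dmso_wells(c(0.8, 1.0, 1.2, 0.9, 1.1, 1.0, 0.95, 1.05),
      plate = "p1", batch = "b1"),
    dmso_wells(c(1.1, 1.3, 1.2, 1.4, 1.0, 1.2, 1.25, 1.15),
      plate = "p2", batch = "b2"),
    chemical_wells(conc,
      mn = c(1.0, 1.5, 2.5, 3.5, 4.0, 4.2),
      rs = c(98, 95, 88, 72, 55, 35),
      chemical = "CHEM-A", plate = "p1", batch = "b1"
    ),
    chemical_wells(conc,
      mn = rep(1.0, 6), rs = c(100, 99, 98, 97, 96, 95),
      chemical = "CHEM-B", plate = "p2", batch = "b2"
    )
  )
}

# hill-type response used by dose-response tests
hill_response <- function(x, a, b, c, d) a * (1 + (c - 1) * x^d / (b^d + x^d))
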