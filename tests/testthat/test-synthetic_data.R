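test_that("a fixed seed reproduces the study byte for byte", {
  cfg <- simulation_config(seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$wells, s2$wells)
  expect_identical(s1$truth, s2$truth)

  p1 <- simulate_plate(cfg, seed = 7)
  p2 <- simulate_plate(cfg, seed = 7)
  expect_identical(p1, p2)
})

test_that("each plate carries the emulated layout", {
  cfg <- simulation_config()
  plate <- simulate_plate(cfg)
  expect_equal(sum(plate$role == "solvent_control"), 8L)
  expect_equal(sum(plate$role == "positive_control"), 6L)
  trt <- plate[plate$role == "treatment", ]
  expect_equal(length(unique(trt$chemical_id)), 4L)
  per_chem <- table(trt$chemical_id)
  expect_true(all(per_chem == 20L)) # 19 concentrations + concurrent control
  expect_equal(
    sort(unique(trt$concentration[trt$concentration > 0])),
    default_concentration_series()
  )
  # positive-control agent follows the S9 condition
  expect_true(all(plate$chemical_id[plate$role == "positive_control"] == "vinblastine"))
  plus <- simulate_plate(cfg, s9 = TRUE)
  expect_true(all(plus$chemical_id[plus$role == "positive_control"] == "cyclophosphamide"))
})

test_that("control dispersion converges to the configured coefficients of variation", {
  draws_mn <- mnscreen:::.rln(1e4, 1.2, 0.30)
  expect_equal(sd(draws_mn) / mean(draws_mn), 0.30, tolerance = 0.05)
  expect_equal(mean(draws_mn), 1.2, tolerance = 0.02)
  draws_hypo <- mnscreen:::.rln(1e4, 0.35, 0.60)
  expect_equal(sd(draws_hypo) / mean(draws_hypo), 0.60, tolerance = 0.05)
})

test_that("inactive chemicals exceed the batch reference at roughly the nominal rate", {
  inactive <- default_truth()
  inactive <- inactive[inactive$class == "inactive" & !is.finite(inactive$surv_ec50), ]
  inactive <- dplyr::bind_rows(lapply(1:7, function(i) {
    dplyr::mutate(inactive, chemical_id = paste0(.data$chemical_id, "-", i))
  }))
  cfg <- simulation_config(truth = inactive, n_batches = 2, seed = 99)
  sim <- simulate_study(cfg)
  refs <- batch_references(sim$wells)
  trt <- sim$wells[sim$wells$role == "treatment" & sim$wells$concentration > 0, ]
  trt <- dplyr::left_join(trt, refs, by = c("batch_date", "s9"))
  frac <- mean(trt$mn_percent > trt$mn_p95)
  expect_gt(nrow(trt), 1000)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.12)
})

test_that("planted potencies equal the closed-form inversion of the planted curves", {
  sim <- simulate_study(simulation_config(seed = 5))
  truth_in <- default_truth()
  for (i in which(truth_in$class == "clastogen")) {
    fit <- structure(
      list(
        family = "hill5", a = 1, b = truth_in$mn_b[i], c = truth_in$mn_c[i],
        d = truth_in$mn_d[i], converged = TRUE
      ),
      class = "dose_response_fit"
    )
    expect_equal(
      sim$truth$true_bmc30[sim$truth$chemical_id == truth_in$chemical_id[i]],
      bmc_from_fit(fit, 0.30),
      tolerance = 1e-12
    )
  }
  expect_true(all(is.na(sim$truth$true_bmc30[sim$truth$class == "inactive"])))
  expect_true(all(!is.na(sim$truth$true_bmc60[sim$truth$class == "aneugen"])))
})

test_that("the zero-noise limit returns the truth curves exactly", {
  cfg <- simulation_config(
    control_mn_cv = 0, control_hypo_cv = 0, survival_cv = 0,
    batch_effect_sd = 0, seed = 1
  )
  sim <- simulate_study(cfg)
  w <- sim$wells
  clast <- w[w$chemical_id == "CLAST-01" & !w$s9 & w$concentration > 0, ]
  expected <- hill_response(clast$concentration, a = 1.2, b = 8, c = 3, d = 1.5)
  expect_equal(clast$mn_percent, expected, tolerance = 1e-12)
  dmso <- w[w$role == "solvent_control" & !w$s9, ]
  expect_true(all(dmso$mn_percent == 1.2))
})
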