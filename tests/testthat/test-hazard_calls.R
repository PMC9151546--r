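series <- default_concentration_series()

# deterministic strong clastogen: Hill %MN rise, survival declining through
# the cytotoxic range at the top of the series
strong_clastogen <- function() {
  mn <- hill_response(series, a = 1, b = 15, c = 4, d = 2)
  rs <- 100 / (1 + (series / 120)^4)
  chemical_wells(series, mn = mn, rs = rs, control_mn = 1)
}

test_that("a strong concentration-responsive clastogen is called positive with no reasons", {
  call <- evaluate_dataset(strong_clastogen(), reference = 1.6, endpoint = "mn")
  expect_s3_class(call, "dataset_call")
  expect_equal(call$verdict, "positive")
  expect_length(call$reasons, 0)
  expect_false(is.na(call$bmc_used))
  expect_lte(call$bmc_used, max(series))
})

test_that("flat responses split into negative or inconclusive by achieved cytotoxicity", {
  flat45 <- chemical_wells(series,
    mn = rep(1, 19),
    rs = c(rep(95, 18), 45) # top concentration 'adequate'
  )
  c1 <- evaluate_dataset(flat45, reference = 1.6, endpoint = "mn")
  expect_equal(c1$verdict, "negative")
  expect_equal(c1$reasons, "no_two_consecutive_exceedances")

  flat90 <- chemical_wells(series, mn = rep(1, 19), rs = rep(90, 19))
  c2 <- evaluate_dataset(flat90, reference = 1.6, endpoint = "mn")
  expect_equal(c2$verdict, "inconclusive")
  expect_equal(c2$reasons, "top_conc_not_cytotoxic")
})

test_that("exceedances confined to overtly cytotoxic concentrations are negative", {
  rs <- c(rep(95, 15), 30, 25, 20, 15) # last four cytotoxic
  mn <- c(rep(1, 15), 5, 6, 7, 8) # increase only there
  call <- evaluate_dataset(
    chemical_wells(series, mn = mn, rs = rs),
    reference = 1.6, endpoint = "mn"
  )
  expect_equal(call$verdict, "negative")
  expect_equal(call$reasons, "increase_only_at_cytotoxic")
})

test_that("a fully cytotoxic series cannot be interpreted", {
  call <- evaluate_dataset(
    chemical_wells(series, mn = rep(2, 19), rs = rep(20, 19)),
    reference = 1.6, endpoint = "mn"
  )
  expect_equal(call$verdict, "inconclusive")
  expect_equal(call$reasons, "all_concentrations_cytotoxic")
})

test_that("a monotone rise failing the BMC bound is negative with the trail recorded", {
  # plateau below the benchmark response: exceedances + trend but no BMC
  mn <- hill_response(series, a = 1.5, b = 10, c = 1.25, d = 2)
  rs <- c(rep(95, 18), 50)
  call <- evaluate_dataset(
    chemical_wells(series, mn = mn, rs = rs, control_mn = 1.5),
    reference = 1.55, endpoint = "mn"
  )
  expect_equal(call$verdict, "negative")
  expect_true(any(c("bmc_absent", "no_dose_response") %in% call$reasons))
})

test_that("the two-fold filter is strict and reclassifies sub-doubling responses", {
  expect_true(twofold_exceeded(c(1.0, 1.9, 2.1), 1.0))
  expect_false(twofold_exceeded(c(1.0, 1.5, 2.0), 1.0)) # exactly 2x fails
  expect_message(res <- twofold_exceeded(c(3, 4), 0), "undefined")
  expect_false(res)

  # sub-doubling but exceeding the reference: positive without the filter,
  # negative with it
  mn <- hill_response(series, a = 1, b = 15, c = 1.9, d = 2)
  rs <- c(rep(95, 18), 50)
  wells <- chemical_wells(series, mn = mn, rs = rs, control_mn = 1)
  on <- evaluate_dataset(wells, reference = 1.3, endpoint = "mn", twofold_filter = TRUE)
  off <- evaluate_dataset(wells, reference = 1.3, endpoint = "mn", twofold_filter = FALSE)
  expect_equal(off$verdict, "positive")
  expect_equal(on$verdict, "negative")
  expect_equal(on$reasons, "twofold_filter_fail")
})

test_that("the fold-change aneugen rule needs both thresholds at one concentration", {
  expect_equal(bryce_call(3.5, 12), "positive")
  expect_equal(bryce_call(c(3.5, 3.5), c(9, 9)), "negative")
  expect_equal(bryce_call(3.0, 15), "negative") # strictly greater than 3
  expect_equal(bryce_call(c(2, 4), c(12, 9)), "negative") # never joint
  expect_equal(bryce_call(c(NA, 4), c(12, 11)), "positive") # NA skipped
  expect_error(bryce_call(c(1, 2), 1), "aligned")
})

test_that("condition combination follows either/both/otherwise and commutes", {
  expect_equal(combine_conditions("positive", "negative")$verdict, "positive")
  expect_equal(combine_conditions("negative", "negative")$verdict, "negative")
  expect_equal(combine_conditions("inconclusive", "negative")$verdict, "inconclusive")
  expect_equal(combine_conditions("inconclusive", "inconclusive")$verdict, "inconclusive")
  verdicts <- c("positive", "negative", "inconclusive")
  for (a in verdicts) {
    for (b in verdicts) {
      expect_equal(
        combine_conditions(a, b)$verdict,
        combine_conditions(b, a)$verdict
      )
    }
  }
  single <- combine_conditions("positive", NA)
  expect_equal(single$verdict, "positive")
  expect_true(single$single_condition)
  expect_error(combine_conditions(NA, NA), "no condition")
})

test_that("replicate tests aggregate as any-positive, then any-negative", {
  expect_equal(combine_replicates(c("negative", "positive")), "positive")
  expect_equal(combine_replicates(c("inconclusive", "negative")), "negative")
  expect_equal(combine_replicates(c("inconclusive", "inconclusive")), "inconclusive")
  expect_true(is.na(combine_replicates(character(0))))
})

test_that("dataset evaluation is deterministic and its reason trail replays the verdict", {
  wells <- strong_clastogen()
  c1 <- evaluate_dataset(wells, reference = 1.6, endpoint = "mn")
  c2 <- evaluate_dataset(wells, reference = 1.6, endpoint = "mn")
  expect_identical(c1[c("verdict", "reasons", "bmc_used", "trend_p")],
    c2[c("verdict", "reasons", "bmc_used", "trend_p")])

  # every non-positive verdict carries at least one machine-readable reason
  cases <- list(
    evaluate_dataset(chemical_wells(series, rep(1, 19), c(rep(95, 18), 45)),
      reference = 1.6, endpoint = "mn"),
    evaluate_dataset(chemical_wells(series, rep(1, 19), rep(90, 19)),
      reference = 1.6, endpoint = "mn")
  )
  for (cl in cases) {
    expect_gt(length(cl$reasons), 0)
  }
})
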