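test_that("percentages are computed from raw counts when only counts are given", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "chemical_id,plate_id,batch_date,s9,role,concentration,mn_events,hypo_events,nucleated_events",
    "X,p1,b1,FALSE,treatment,0,2,1,100",
    "X,p1,b1,FALSE,treatment,10,5,2,200",
    "X,p1,b1,FALSE,treatment,20,30,3,300"
  ), path)
  tbl <- read_plate_table(path)
  expect_equal(tbl$mn_percent, c(2, 2.5, 10))
  expect_equal(tbl$hypo_percent, c(1, 1, 1))
  expect_equal(tbl$chemical_id, rep("X", 3)) # row order preserved
})

test_that("pre-computed percentages and fold changes pass through unchanged", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste0("chemical_id,plate_id,batch_date,s9,role,concentration,",
      "mn_percent,hypo_percent,relative_survival,mn_fold_change,hypo_fold_change"),
    "X,p1,b1,TRUE,treatment,10,2.47,0.81,87.3,2.1,1.4",
    "DMSO,p1,b1,TRUE,solvent_control,0,1.18,0.58,100,,"
  ), path)
  tbl <- read_plate_table(path)
  expect_equal(tbl$mn_percent, c(2.47, 1.18))
  expect_equal(tbl$relative_survival[1], 87.3)
  expect_equal(tbl$mn_fold_change, c(2.1, NA))
})

test_that("column maps rename source columns; schema errors name the column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("Chemical", "Plate", "Date", "S9", "Type", "Conc uM", "MN %",
      "Hypo %", "RS %", sep = "\t"),
    paste("X", "p1", "b1", "0", "treatment", "10", "2.0", "0.4", "95", sep = "\t")
  ), path)
  map <- c(
    chemical_id = "Chemical", plate_id = "Plate", batch_date = "Date",
    s9 = "S9", role = "Type", concentration = "Conc uM",
    mn_percent = "MN %", hypo_percent = "Hypo %", relative_survival = "RS %"
  )
  tbl <- read_plate_table(path, column_map = map)
  expect_equal(tbl$mn_percent, 2.0)
  expect_false(tbl$s9)

  expect_error(
    read_plate_table(path, column_map = c(map, mn_fold_change = "FC")),
    "FC"
  )
})

test_that("non-numeric endpoint values raise a row-level error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "chemical_id,plate_id,batch_date,s9,role,concentration,mn_percent,hypo_percent,relative_survival",
    "X,p1,b1,FALSE,treatment,10,2.0,0.4,95",
    "X,p1,b1,FALSE,treatment,20,oops,0.4,90"
  ), path)
  expect_error(read_plate_table(path), "row 2")
})

test_that("write + read round trip preserves every field", {
  study <- toy_study()
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(study, path)
  back <- read_plate_table(path)
  expect_equal(as.data.frame(back), as.data.frame(study))
})

test_that("exclusions remove whole plates, warn on unknown ones, and are idempotent", {
  study <- toy_study()
  ex <- data.frame(batch_date = "b1", plate_id = "p1")
  out <- suppressMessages(apply_exclusions(study, ex))
  expect_false(any(out$plate_id == "p1" & out$batch_date == "b1"))
  expect_equal(attr(out, "n_excluded"), sum(study$plate_id == "p1"))

  # idempotent on the records; the re-application warns because the plate is
  # no longer present
  again <- suppressWarnings(suppressMessages(apply_exclusions(out, ex)))
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)
  expect_equal(attr(again, "n_excluded"), 0L)

  expect_warning(
    suppressMessages(
      apply_exclusions(study, data.frame(batch_date = "b9", plate_id = "p9"))
    ),
    "unknown"
  )
  expect_equal(
    as.data.frame(apply_exclusions(study, NULL)),
    as.data.frame(study),
    ignore_attr = TRUE
  )
})

test_that("pooled controls partition the matching wells by batch", {
  study <- toy_study()
  groups <- suppressMessages(pool_controls(study, "solvent_control", s9 = FALSE))
  expect_named(groups, c("b1", "b2"))
  expect_equal(unname(vapply(groups, nrow, integer(1))), c(8L, 8L))

  pooled <- dplyr::bind_rows(groups)
  direct <- study[study$role == "solvent_control" & !study$s9, ]
  expect_equal(nrow(pooled), nrow(direct))
  expect_setequal(pooled$mn_percent, direct$mn_percent)
  # disjoint: each well lands in exactly one group
  expect_equal(sum(vapply(groups, nrow, integer(1))), nrow(direct))

  pc <- dplyr::bind_rows(
    well_row("VINB", "positive_control", c(0.00625, 0.0125, 0.025), 2:4),
    toy_study()
  )
  pcg <- suppressMessages(pool_controls(pc, "positive_control", s9 = FALSE))
  expect_equal(sort(pcg[["b1"]]$concentration), c(0.00625, 0.0125, 0.025))
})
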