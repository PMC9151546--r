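#' Run the full hazard-to-risk pipeline
#'
#' Orchestrates the four stages end to end: (1) QC — plate exclusions and
#' batch-specific solvent-control reference percentiles; (2) decision-tree
#' hazard classification of %MN (clastogenicity, BMR 0.30) and %hypodiploid
#' (aneugenicity, BMR 0.60), plus the fold-change aneugen rule; (3) IVIVE of
#' the per-chemical benchmark concentration (the lower of the positive
#' +/- S9 BMCs) to an administered equivalent dose; (4) bioactivity exposure
#' ratios against exposure estimates, with priority bands and optional
#' traditional-POD comparisons. Per-chemical failures are collected, not
#' fatal.
#'
#' @param study Canonical study table (see [read_plate_table()] /
#'   [simulate_study()]).
#' @param exclusions Optional plate exclusions (see [apply_exclusions()]).
#' @param tk Optional toxicokinetic parameter tibble (`casrn`,
#'   `molecular_weight`, `fup`, `hlm_clint`); `casrn` must match
#'   `chemical_id` values.
#' @param exposure Optional exposure tibble (`casrn`, `median_mg_kg_day`,
#'   `p95_mg_kg_day`).
#' @param pods Optional traditional-POD tibble (`casrn`, `pod_mg_kg_day`,
#'   `study_type`).
#' @param twofold_filter Apply the optional two-fold filter in the MN and
#'   hypodiploidy decision trees.
#' @param alpha Trend-test significance level.
#' @param p Reference percentile (default 95).
#' @param aic_margin AIC margin for model selection.
#' @param phys Physiology for IVIVE.
#' @return List of class `mn_pipeline_result`: `references`, `mn`, `hypo`
#'   (each a [hazard_classification()] bundle), `bryce`
#'   ([bryce_classification()] bundle), `aed` (tibble), `ber_median` /
#'   `ber_p95` ([rank_and_band()] bundles, when exposure given),
#'   `pod_summary`, and `manifest` (counts at every stage).
#' @export
run_pipeline <- function(study, exclusions = NULL, tk = NULL, exposure = NULL,
                         pods = NULL, twofold_filter = FALSE, alpha = 0.05,
                         p = 95, aic_margin = 2, phys = default_physiology()) {
  n_read <- nrow(study)
  study <- apply_exclusions(study, exclusions)
  n_excluded <- attr(study, "n_excluded")

  refs <- batch_references(study, p = p)
  study <- add_fold_changes(study)

  mn <- hazard_classification(study, refs,
    endpoint = "mn", bmr = 0.30,
    twofold_filter = twofold_filter, alpha = alpha, aic_margin = aic_margin
  )
  hypo <- hazard_classification(study, refs,
    endpoint = "hypo", bmr = 0.60,
    twofold_filter = twofold_filter, alpha = alpha, aic_margin = aic_margin
  )
  bryce <- bryce_classification(study)

  aed <- NULL
  ber_median <- ber_p95 <- NULL
  pod_summary <- NULL
  if (!is.null(tk)) {
    bmc_tbl <- mn$chemical_calls |>
      dplyr::filter(.data$verdict == "positive", !is.na(.data$bmc_used)) |>
      dplyr::transmute(casrn = .data$chemical_id, bmc = .data$bmc_used)
    aed <- aed_table(tk = tk, bmc_table = bmc_tbl, phys = phys)
    if (!is.null(exposure)) {
      joined <- dplyr::inner_join(aed, exposure, by = "casrn")
      mk <- function(col) {
        ok <- !is.na(joined[[col]]) & joined[[col]] > 0
        recs <- joined[ok, , drop = FALSE]
        b <- compute_ber(recs$aed_mg_kg_day, recs[[col]])
        rank_and_band(dplyr::bind_cols(
          recs[, c("casrn", "aed_mg_kg_day")], b
        ))
      }
      ber_median <- mk("median_mg_kg_day")
      ber_p95 <- mk("p95_mg_kg_day")
    }
    if (!is.null(pods)) {
      pod_summary <- aed |>
        dplyr::rowwise() |>
        dplyr::reframe(
          casrn = .data$casrn,
          pod_comparison(
            .data$aed_mg_kg_day,
            pods[pods$casrn == .data$casrn, , drop = FALSE]
          )
        )
    }
  }

  verdict_counts <- function(calls) {
    as.list(table(factor(calls$verdict,
      levels = c("positive", "negative", "inconclusive")
    )))
  }
  manifest <- list(
    n_wells_read = n_read,
    n_wells_excluded = n_excluded,
    n_batches = length(unique(refs$batch_date)),
    n_chemicals = nrow(mn$chemical_calls),
    n_datasets_mn = nrow(mn$dataset_calls),
    mn_chemical = verdict_counts(mn$chemical_calls),
    hypo_chemical = verdict_counts(hypo$chemical_calls),
    bryce_positive = sum(bryce$chemical_calls$verdict == "positive"),
    n_failures = nrow(mn$failures) + nrow(hypo$failures),
    twofold_filter = twofold_filter,
    alpha = alpha, p = p, aic_margin = aic_margin
  )

  structure(
    list(
      references = refs, mn = mn, hypo = hypo, bryce = bryce, aed = aed,
      ber_median = ber_median, ber_p95 = ber_p95, pod_summary = pod_summary,
      manifest = manifest
    ),
    class = "mn_pipeline_result"
  )
}

#' @export
print.mn_pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("<mn_pipeline_result>\n")
  cat("  wells: ", m$n_wells_read, " read, ", m$n_wells_excluded, " excluded; ",
    m$n_batches, " batch(es); ", m$n_chemicals, " chemical(s)\n", sep = "")
  cat(sprintf(
    "  MN calls:   %d positive / %d negative / %d inconclusive\n",
    m$mn_chemical$positive, m$mn_chemical$negative, m$mn_chemical$inconclusive
  ))
  cat(sprintf(
    "  hypo calls: %d positive / %d negative / %d inconclusive\n",
    m$hypo_chemical$positive, m$hypo_chemical$negative,
    m$hypo_chemical$inconclusive
  ))
  cat("  fold-change aneugens:", m$bryce_positive, "\n")
  if (!is.null(x$aed)) cat("  AEDs derived:", nrow(x$aed), "\n")
  invisible(x)
}

#' Write the pipeline result bundle to CSV files
#'
#' @param result [run_pipeline()] output.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && nrow(x)) {
      readr::write_csv(x, file.path(dir, name), progress = FALSE)
    }
  }
  w(reference_table(result$references), "batch_references.csv")
  w(result$mn$dataset_calls, "mn_dataset_calls.csv")
  w(result$mn$chemical_calls, "mn_chemical_calls.csv")
  w(result$hypo$dataset_calls, "hypo_dataset_calls.csv")
  w(result$hypo$chemical_calls, "hypo_chemical_calls.csv")
  w(result$bryce$chemical_calls, "bryce_chemical_calls.csv")
  w(result$aed, "aed.csv")
  if (!is.null(result$ber_median)) {
    w(result$ber_median$ranked, "ber_median_ranked.csv")
    w(result$ber_p95$ranked, "ber_p95_ranked.csv")
  }
  if (!is.null(result$pod_summary)) w(result$pod_summary, "pod_comparison.csv")
  writeLines(
    jsonlite_safe(result$manifest),
    file.path(dir, "manifest.json")
  )
  invisible(dir)
}

## minimal JSON writer for the manifest so the core package does not depend
## on a JSON library; values are scalars or flat named lists of scalars
jsonlite_safe <- function(x) {
  enc <- function(v) {
    if (is.list(v)) {
      paste0("{", paste(
        sprintf("\"%s\": %s", names(v), vapply(v, enc, character(1))),
        collapse = ", "
      ), "}")
    } else if (is.character(v)) {
      sprintf("\"%s\"", v)
    } else if (is.logical(v)) {
      tolower(as.character(v))
    } else {
      format(v, digits = 15)
    }
  }
  enc(x)
}
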