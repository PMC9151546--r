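#' Decision-tree evaluation of one chemical x S9 dataset
#'
#' Implements the hazard decision tree for a single test (one chemical under
#' one metabolic-activation condition, the 19-concentration series plus its
#' concurrent control). A positive call requires, in order:
#'
#' * (a) two consecutive concentrations whose endpoint percentage exceeds the
#'   batch-specific solvent-control reference percentile, both at
#'   non-cytotoxic or adequate cytotoxicity;
#' * (b) the increase occurs at non-cytotoxic/adequate levels (exceedances at
#'   overtly cytotoxic concentrations, relative survival below 40 percent, do
#'   not count and alone yield a negative);
#' * the optional two-fold filter (at least one usable concentration more
#'   than twice the concurrent control), when enabled;
#' * (c) an increasing concentration-response trend
#'   ([jonckheere_test()] p-value at most `alpha`, control included as the
#'   lowest group); and
#' * (d) a benchmark concentration at the endpoint's BMR no greater than the
#'   highest concentration entering the modeling.
#'
#' When (a) fails, the call is negative provided the top tested concentration
#' reached at least adequate cytotoxicity, and inconclusive otherwise (the
#' test never stressed the cells enough to rule the chemical out).
#'
#' @param wells Study-table rows for one chemical and S9 condition, including
#'   the concentration-zero concurrent control well(s).
#' @param reference Scalar reference threshold (the batch p95 for the chosen
#'   endpoint and S9 condition).
#' @param endpoint `"mn"` or `"hypo"`.
#' @param bmr Benchmark response (default 0.30 for `"mn"`, 0.60 for
#'   `"hypo"`).
#' @param twofold_filter Apply the optional two-fold-over-control filter.
#' @param alpha One-sided significance level for the trend test.
#' @param aic_margin AIC margin for [select_model()].
#' @return Object of class `dataset_call`: list with `chemical_id`, `s9`,
#'   `endpoint`, `verdict` (`"positive"`/`"negative"`/`"inconclusive"`),
#'   `reasons` (rule codes; empty for positives), `bmc_used`, `trend_p`,
#'   `n_modeled`.
#' @export
evaluate_dataset <- function(wells, reference, endpoint = c("mn", "hypo"),
                             bmr = NULL, twofold_filter = FALSE,
                             alpha = 0.05, aic_margin = 2) {
  endpoint <- match.arg(endpoint)
  if (is.null(bmr)) bmr <- if (endpoint == "mn") 0.30 else 0.60
  if (!is.finite(reference)) stop("missing batch reference threshold")
  value_col <- if (endpoint == "mn") "mn_percent" else "hypo_percent"

  chem <- unique(wells$chemical_id[wells$role == "treatment"])
  if (length(chem) != 1) stop("wells must cover exactly one chemical")
  s9 <- unique(wells$s9)
  if (length(s9) != 1) stop("wells must cover exactly one S9 condition")

  trt <- wells[wells$role == "treatment" & wells$concentration > 0, , drop = FALSE]
  ctl <- wells[wells$concentration == 0, , drop = FALSE]
  trt <- trt[order(trt$concentration), , drop = FALSE]
  if (nrow(trt) < 3 || all(is.na(trt$relative_survival))) {
    stop("need at least 3 treated concentrations with survival data")
  }

  mk_call <- function(verdict, reasons, bmc = NA_real_, p = NA_real_, nmod = NA_integer_) {
    structure(
      list(
        chemical_id = chem, s9 = s9, endpoint = endpoint, verdict = verdict,
        reasons = reasons, bmc_used = bmc, trend_p = p, n_modeled = nmod
      ),
      class = "dataset_call"
    )
  }

  category <- classify_cytotoxicity(trt$relative_survival)
  usable <- category != "cytotoxic"
  values <- trt[[value_col]]

  if (!any(usable)) {
    return(mk_call("inconclusive", "all_concentrations_cytotoxic"))
  }

  exceed_raw <- values > reference
  exceed <- exceed_raw & usable
  consecutive <- any(exceed[-length(exceed)] & exceed[-1])

  if (!consecutive) {
    if (any(exceed_raw) && !any(exceed)) {
      return(mk_call("negative", "increase_only_at_cytotoxic"))
    }
    top_cat <- as.character(category[length(category)])
    if (top_cat %in% c("cytotoxic", "adequate")) {
      return(mk_call("negative", "no_two_consecutive_exceedances"))
    }
    return(mk_call("inconclusive", "top_conc_not_cytotoxic"))
  }

  baseline <- if (nrow(ctl)) mean(ctl[[value_col]]) else NA_real_
  if (twofold_filter) {
    ok <- twofold_exceeded(values[usable], baseline)
    if (!isTRUE(ok)) {
      return(mk_call("negative", "twofold_filter_fail"))
    }
  }

  ## conditions (c) and (d) on the surviving (non-cytotoxic + adequate)
  ## concentrations, with the concurrent control anchoring both analyses
  mod_conc <- c(rep(0, nrow(ctl)), trt$concentration[usable])
  mod_resp <- c(ctl[[value_col]], values[usable])

  groups <- c(
    list(ctl[[value_col]]),
    split(values[usable], trt$concentration[usable])
  )
  trend <- tryCatch(jonckheere_test(groups), error = function(e) NULL)
  trend_p <- if (is.null(trend)) NA_real_ else trend$p_value

  dr <- fit_dose_response(mod_conc, mod_resp, bmr = bmr, aic_margin = aic_margin)
  bmc <- dr$bmc
  top_modeled <- max(mod_conc)

  reasons <- character(0)
  if (is.na(trend_p) || trend_p > alpha) reasons <- c(reasons, "trend_fail")
  if (dr$selection$no_response) {
    reasons <- c(reasons, "no_dose_response")
  } else if (is.na(bmc)) {
    reasons <- c(reasons, "bmc_absent")
  } else if (bmc > top_modeled) {
    reasons <- c(reasons, "bmc_above_top")
  }

  if (!length(reasons)) {
    mk_call("positive", character(0), bmc, trend_p, length(mod_conc))
  } else {
    mk_call("negative", reasons, bmc, trend_p, length(mod_conc))
  }
}

#' @export
print.dataset_call <- function(x, ...) {
  cat("<dataset_call> ", x$chemical_id, if (x$s9) " +S9" else " -S9",
    " [", x$endpoint, "]: ", x$verdict, "\n", sep = "")
  if (length(x$reasons)) cat("  reasons: ", paste(x$reasons, collapse = ", "), "\n")
  if (!is.na(x$bmc_used)) cat(sprintf("  BMC = %.4g uM\n", x$bmc_used))
  invisible(x)
}

#' Two-fold-over-control filter
#'
#' `TRUE` when at least one response is strictly greater than twice the
#' concurrent solvent-control baseline. A zero or missing baseline fails the
#' filter (the fold change is undefined) with a message.
#'
#' @param responses Endpoint percentages at the usable concentrations.
#' @param baseline Concurrent control percentage.
#' @return Logical.
#' @export
twofold_exceeded <- function(responses, baseline) {
  if (is.na(baseline) || baseline <= 0) {
    message("two-fold filter: undefined baseline (<= 0); filter fails")
    return(FALSE)
  }
  any(responses > 2 * baseline)
}

#' Fold-change rule for aneugenicity
#'
#' Binary aneugen call from pre-computed fold changes: positive when some
#' concentration shows both a %MN fold change strictly greater than 3 and a
#' %hypodiploid fold change strictly greater than 10 relative to the
#' concurrent control. Concentrations with a missing fold change are skipped.
#'
#' @param mn_fold_change,hypo_fold_change Numeric vectors aligned by
#'   concentration.
#' @return `"positive"` or `"negative"`.
#' @export
bryce_call <- function(mn_fold_change, hypo_fold_change) {
  if (length(mn_fold_change) != length(hypo_fold_change)) {
    stop("fold-change vectors must be aligned by concentration")
  }
  ok <- !is.na(mn_fold_change) & !is.na(hypo_fold_change)
  hit <- any(mn_fold_change[ok] > 3 & hypo_fold_change[ok] > 10)
  if (hit) "positive" else "negative"
}

#' Combine the two metabolic-activation conditions into a chemical call
#'
#' Positive when either condition is positive; negative only when both are
#' negative; inconclusive otherwise. With a single available condition the
#' combined call equals it and is flagged.
#'
#' @param call_minus_s9,call_plus_s9 Verdict strings or `dataset_call`
#'   objects; either may be `NULL`/`NA` when that condition was not tested.
#' @return List with `verdict`, `minus_s9`, `plus_s9`, `single_condition`.
#' @export
combine_conditions <- function(call_minus_s9, call_plus_s9) {
  v <- function(x) {
    if (is.null(x) || (length(x) == 1 && is.na(x))) {
      return(NA_character_)
    }
    if (inherits(x, "dataset_call")) x$verdict else as.character(x)
  }
  a <- v(call_minus_s9)
  b <- v(call_plus_s9)
  if (is.na(a) && is.na(b)) stop("no condition-level calls supplied")
  single <- is.na(a) || is.na(b)
  pair <- c(a, b)[!is.na(c(a, b))]
  verdict <- if (any(pair == "positive")) {
    "positive"
  } else if (all(pair == "negative")) {
    "negative"
  } else {
    "inconclusive"
  }
  list(verdict = verdict, minus_s9 = a, plus_s9 = b, single_condition = single)
}

#' Aggregate replicate tests of one chemical x condition
#'
#' Some chemicals appear on more than one plate; a condition is positive when
#' any replicate test is positive, otherwise negative when any is negative,
#' otherwise inconclusive.
#'
#' @param verdicts Character vector of test verdicts.
#' @return A single verdict string.
#' @export
combine_replicates <- function(verdicts) {
  if (!length(verdicts)) {
    return(NA_character_)
  }
  if (any(verdicts == "positive")) {
    return("positive")
  }
  if (any(verdicts == "negative")) {
    return("negative")
  }
  "inconclusive"
}

#' Decision-tree hazard classification for a whole study
#'
#' Runs [evaluate_dataset()] for every test (chemical x S9 x plate), looks
#' up each test's batch reference threshold, aggregates replicates within a
#' condition via [combine_replicates()], and combines the two conditions via
#' [combine_conditions()].
#'
#' @param study Study table (after exclusions).
#' @param references [batch_references()] output.
#' @param endpoint `"mn"` or `"hypo"`.
#' @param bmr Benchmark response (endpoint default when `NULL`).
#' @param twofold_filter,alpha,aic_margin Passed to [evaluate_dataset()].
#' @return List with `dataset_calls` (tibble of per-test calls),
#'   `chemical_calls` (tibble with per-condition and combined verdicts), and
#'   `failures` (tibble of tests that errored, with messages).
#' @export
hazard_classification <- function(study, references, endpoint = c("mn", "hypo"),
                                  bmr = NULL, twofold_filter = FALSE,
                                  alpha = 0.05, aic_margin = 2) {
  endpoint <- match.arg(endpoint)
  ref_col <- if (endpoint == "mn") "mn_p95" else "hypo_p95"
  trt <- study[study$role == "treatment", , drop = FALSE]
  keys <- unique(trt[, c("chemical_id", "s9", "plate_id", "batch_date")])

  rows <- list()
  fails <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    wells <- trt[trt$chemical_id == k$chemical_id & trt$s9 == k$s9 &
      trt$plate_id == k$plate_id, , drop = FALSE]
    ref <- references[references$batch_date == k$batch_date &
      references$s9 == k$s9, ][[ref_col]]
    res <- tryCatch(
      evaluate_dataset(wells,
        reference = if (length(ref)) ref[1] else NA_real_,
        endpoint = endpoint, bmr = bmr, twofold_filter = twofold_filter,
        alpha = alpha, aic_margin = aic_margin
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- tibble::tibble(
        chemical_id = k$chemical_id, s9 = k$s9, plate_id = k$plate_id,
        message = conditionMessage(res)
      )
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chemical_id = res$chemical_id, s9 = res$s9, plate_id = k$plate_id,
        batch_date = k$batch_date, endpoint = endpoint,
        verdict = res$verdict,
        reasons = paste(res$reasons, collapse = ";"),
        bmc_used = res$bmc_used, trend_p = res$trend_p
      )
    }
  }
  dataset_calls <- dplyr::bind_rows(rows)
  failures <- dplyr::bind_rows(fails)

  cond <- dataset_calls |>
    dplyr::group_by(.data$chemical_id, .data$s9) |>
    dplyr::summarise(
      verdict = combine_replicates(.data$verdict),
      bmc_min = ifelse(all(is.na(.data$bmc_used)), NA_real_,
        min(.data$bmc_used, na.rm = TRUE)),
      .groups = "drop"
    )
  chemical_calls <- cond |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::summarise(
      verdict_minus_s9 = .cond_verdict(.data$verdict, .data$s9, FALSE),
      verdict_plus_s9 = .cond_verdict(.data$verdict, .data$s9, TRUE),
      bmc_minus_s9 = .cond_bmc(.data$bmc_min, .data$verdict, .data$s9, FALSE),
      bmc_plus_s9 = .cond_bmc(.data$bmc_min, .data$verdict, .data$s9, TRUE),
      .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      verdict = combine_conditions(
        .data$verdict_minus_s9, .data$verdict_plus_s9
      )$verdict,
      ## potency for downstream IVIVE: the lower BMC across positive conditions
      bmc_used = {
        cand <- c(
          if (identical(.data$verdict_minus_s9, "positive")) .data$bmc_minus_s9,
          if (identical(.data$verdict_plus_s9, "positive")) .data$bmc_plus_s9
        )
        cand <- cand[!is.na(cand)]
        if (length(cand)) min(cand) else NA_real_
      }
    ) |>
    dplyr::ungroup()

  list(
    dataset_calls = dataset_calls,
    chemical_calls = chemical_calls,
    failures = failures
  )
}

.cond_verdict <- function(verdicts, s9, want) {
  hit <- s9 == want
  if (!any(hit)) {
    return(NA_character_)
  }
  verdicts[hit][1]
}

.cond_bmc <- function(bmc, verdicts, s9, want) {
  hit <- s9 == want
  if (!any(hit)) {
    return(NA_real_)
  }
  bmc[hit][1]
}

#' Fold-change (aneugen) classification for a whole study
#'
#' Applies [bryce_call()] to every test and combines replicates and
#' conditions (positive in either condition makes the chemical positive;
#' the rule itself is binary, so chemicals are otherwise negative).
#'
#' @param study Study table with fold-change columns populated (see
#'   [add_fold_changes()]).
#' @return List with `dataset_calls` and `chemical_calls` tibbles.
#' @export
bryce_classification <- function(study) {
  trt <- study[study$role == "treatment" & study$concentration > 0, , drop = FALSE]
  dataset_calls <- trt |>
    dplyr::group_by(.data$chemical_id, .data$s9, .data$plate_id) |>
    dplyr::summarise(
      verdict = bryce_call(.data$mn_fold_change, .data$hypo_fold_change),
      .groups = "drop"
    )
  chemical_calls <- dataset_calls |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::summarise(
      verdict = ifelse(any(.data$verdict == "positive"), "positive", "negative"),
      positive_plus_s9_only = any(.data$verdict == "positive" & .data$s9) &&
        !any(.data$verdict == "positive" & !.data$s9),
      .groups = "drop"
    )
  list(dataset_calls = dataset_calls, chemical_calls = chemical_calls)
}
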