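#' Read a per-well MNvit plate table
#'
#' Reads a delimited text export of a plate-structured micronucleus study (one
#' row per well) into the canonical tidy layout used throughout the package:
#' `chemical_id`, `plate_id`, `batch_date`, `s9`, `role`, `concentration`
#' (uM), `mn_percent`, `hypo_percent`, `relative_survival`, `mn_fold_change`,
#' `hypo_fold_change`. Spreadsheet sources are expected to be converted to
#' CSV/TSV beforehand; the delimiter is inferred from the file extension
#' unless `delim` is given.
#'
#' Endpoint percentages may be supplied directly, or derived from raw counts:
#' when a percentage column is absent but `mn_events`/`hypo_events` and
#' `nucleated_events` are present, percentages are computed as
#' events / nucleated x 100. Likewise `relative_survival` is computed from a
#' `nuclei_to_bead` column against the mean solvent-control ratio of the same
#' plate and S9 condition. Columns already present are passed through
#' unchanged (pre-computed values are trusted). Fold-change columns are
#' optional; [add_fold_changes()] fills them in later when needed.
#'
#' @param path Path to a CSV/TSV file.
#' @param column_map Optional named character vector mapping canonical names
#'   (the names) to the file's column names (the values), e.g.
#'   `c(mn_percent = "MN %")`.
#' @param delim Field delimiter; default inferred from extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return A tibble, one row per well, in file order.
#' @export
read_plate_table <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      stop(
        "mapped column(s) not found in ", path, ": ",
        paste(missing_src, collapse = ", ")
      )
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }

  required <- c("chemical_id", "plate_id", "batch_date", "s9", "role", "concentration")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }

  num_col <- function(name) {
    if (!name %in% names(raw)) {
      return(rep(NA_real_, nrow(raw)))
    }
    x <- trimws(raw[[name]])
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & x != "NA" & is.na(out))
    if (length(bad)) {
      stop(
        "non-numeric value in column '", name, "' at row ",
        bad[1], ": '", x[bad[1]], "'"
      )
    }
    out
  }

  tbl <- tibble::tibble(
    chemical_id = as.character(raw$chemical_id),
    plate_id = as.character(raw$plate_id),
    batch_date = as.character(raw$batch_date),
    s9 = .parse_s9(raw$s9),
    role = .parse_role(raw$role),
    concentration = num_col("concentration"),
    mn_percent = num_col("mn_percent"),
    hypo_percent = num_col("hypo_percent"),
    relative_survival = num_col("relative_survival"),
    mn_fold_change = num_col("mn_fold_change"),
    hypo_fold_change = num_col("hypo_fold_change")
  )

  nucleated <- num_col("nucleated_events")
  if (all(is.na(tbl$mn_percent)) && "mn_events" %in% names(raw)) {
    tbl$mn_percent <- percent_endpoint(num_col("mn_events"), nucleated)
  }
  if (all(is.na(tbl$hypo_percent)) && "hypo_events" %in% names(raw)) {
    tbl$hypo_percent <- percent_endpoint(num_col("hypo_events"), nucleated)
  }
  if (all(is.na(tbl$relative_survival)) && "nuclei_to_bead" %in% names(raw)) {
    ratio <- num_col("nuclei_to_bead")
    ctrl <- tapply(
      ratio[tbl$role == "solvent_control"],
      paste(tbl$plate_id, tbl$s9)[tbl$role == "solvent_control"], mean
    )
    key <- paste(tbl$plate_id, tbl$s9)
    tbl$relative_survival <- relative_survival(ratio, unname(ctrl[key]))
  }

  if (any(tbl$concentration < 0, na.rm = TRUE)) stop("negative concentration")
  for (p in c("mn_percent", "hypo_percent")) {
    bad <- which(tbl[[p]] < 0 | tbl[[p]] > 100)
    if (length(bad)) stop("'", p, "' outside [0, 100] at row ", bad[1])
  }
  tbl
}

.parse_s9 <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "+", "+s9", "plus")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "-", "-s9", "minus")] <- FALSE
  if (anyNA(out)) stop("unparseable s9 value: '", x[which(is.na(out))[1]], "'")
  out
}

.parse_role <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("dmso", "vehicle", "negative_control", "solvent")] <- "solvent_control"
  x[x %in% c("positive", "pos")] <- "positive_control"
  x[x %in% c("test", "chemical")] <- "treatment"
  bad <- setdiff(unique(x), .mn_roles)
  if (length(bad)) stop("unknown role value(s): ", paste(bad, collapse = ", "))
  x
}

#' Write a study table in the canonical CSV dialect
#'
#' @param study Study table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(study, path) {
  readr::write_csv(study[, .mn_canonical_cols], path, progress = FALSE)
  invisible(path)
}

#' Remove excluded plates from a study table
#'
#' QC exclusions are always explicit (batch date, plate id) pairs decided by
#' the analyst; outlier flags elsewhere in the package are advisory and never
#' remove data on their own. Exclusions naming unknown plates produce a
#' warning, not an error, and the operation is idempotent.
#'
#' @param study Study table.
#' @param exclusions A data frame with columns `batch_date` and `plate_id`, a
#'   list of length-2 vectors `c(batch_date, plate_id)`, or `NULL`.
#' @return The table without wells on excluded plates; the number of removed
#'   wells is reported via `message()` and stored in attribute `"n_excluded"`.
#' @export
apply_exclusions <- function(study, exclusions = NULL) {
  if (is.null(exclusions) || (is.data.frame(exclusions) && nrow(exclusions) == 0) ||
    (!is.data.frame(exclusions) && length(exclusions) == 0)) {
    attr(study, "n_excluded") <- 0L
    return(study)
  }
  if (!is.data.frame(exclusions)) {
    exclusions <- do.call(rbind, lapply(exclusions, function(e) {
      data.frame(batch_date = e[[1]], plate_id = e[[2]])
    }))
  }
  keys <- paste(study$batch_date, study$plate_id, sep = "\r")
  ex_keys <- paste(exclusions$batch_date, exclusions$plate_id, sep = "\r")
  unknown <- setdiff(ex_keys, keys)
  if (length(unknown)) {
    warning(
      "exclusion(s) reference unknown plate(s): ",
      paste(gsub("\r", " / ", unknown), collapse = "; ")
    )
  }
  drop <- keys %in% ex_keys
  message("apply_exclusions: removed ", sum(drop), " well(s) on ",
    length(setdiff(ex_keys, unknown)), " plate(s)")
  out <- study[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Pool control wells by batch date
#'
#' Selects wells of the requested role and S9 condition and splits them by
#' batch date (each assay date is a batch). Positive controls keep their
#' concentration column so per-concentration QC remains possible.
#'
#' @param study Study table.
#' @param role `"solvent_control"` or `"positive_control"`.
#' @param s9 Logical; the metabolic-activation condition to pool.
#' @return Named list of tibbles, one per batch date (empty list when nothing
#'   matches).
#' @export
pool_controls <- function(study, role = c("solvent_control", "positive_control"), s9) {
  role <- match.arg(role)
  if (nrow(study) == 0) stop("empty study table")
  sel <- study[study$role == role & study$s9 == s9, , drop = FALSE]
  groups <- split(sel, sel$batch_date)
  message(
    "pool_controls: ", nrow(sel), " ", role, " well(s) in ",
    length(groups), " batch(es)"
  )
  groups
}
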