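#' Read a deposited QA measurement workbook
#'
#' Reads the between-/within-scanner measurement workbook deposited with the
#' multicenter study (an XLSX file) — or, equivalently, a directory of CSV
#' files, one per sheet — and normalizes it to a long-format table. Sheets
#' are matched by column names (case- and punctuation-insensitive), with the
#' synonyms: scanner/system/center; sequence/protocol; time point/session;
#' plane/orientation; direction/axis; encoding (role/direction); kind/type;
#' value/measurement/error. A sheet must provide at least a `value` column
#' and either a `direction` or a `kind` column to be accepted; sheets that
#' cannot be interpreted raise a schema error listing everything found.
#'
#' @param path path to an `.xlsx` workbook or a directory of `.csv` sheets.
#' @return data.frame with columns `sheet`, `scanner`, `sequence`,
#'   `time_point`, `plane`, `direction`, `encoding_role`, `kind`, `value`
#'   (missing annotations are `NA`).
#' @export
read_qa_workbook <- function(path) {
  if (!file.exists(path))
    stop("workbook not found: ", path,
         " (the pipeline still runs in simulation mode without it)",
         call. = FALSE)
  sheets <- if (dir.exists(path)) {
    fl <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (!length(fl)) stop("no .csv sheets found in directory ", path,
                          call. = FALSE)
    stats::setNames(lapply(fl, utils::read.csv, check.names = FALSE),
                    sub("\\.csv$", "", basename(fl)))
  } else {
    nm <- readxl::excel_sheets(path)
    stats::setNames(lapply(nm, function(s)
      as.data.frame(readxl::read_excel(path, sheet = s))), nm)
  }

  canon <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  syn <- list(
    scanner = c("scanner", "system", "center", "centre", "site"),
    sequence = c("sequence", "protocol", "pulsesequence"),
    time_point = c("timepoint", "time", "session", "visit"),
    plane = c("plane", "orientation", "imagingplane"),
    direction = c("direction", "axis", "dir"),
    encoding_role = c("encoding", "encodingrole", "encodingdirection",
                      "role"),
    kind = c("kind", "type", "measurementtype"),
    value = c("value", "measurement", "measurementmm", "lengthmm",
              "volumemm3", "volume", "error", "errorpct"))
  norm_sheet <- function(df, sheet) {
    cn <- canon(names(df))
    pick <- function(key) {
      hit <- which(cn %in% syn[[key]])
      if (length(hit)) df[[hit[1]]] else NA
    }
    value <- pick("value")
    direction <- pick("direction")
    kind <- pick("kind")
    if (all(is.na(value)) || (all(is.na(direction)) && all(is.na(kind))))
      return(NULL)
    kind <- if (all(is.na(kind)))
      ifelse(is.na(direction) | direction == "", "volume", "dimension")
      else tolower(as.character(kind))
    data.frame(sheet = sheet,
               scanner = as.character(pick("scanner")),
               sequence = as.character(pick("sequence")),
               time_point = as.character(pick("time_point")),
               plane = tolower(as.character(pick("plane"))),
               direction = tolower(as.character(direction)),
               encoding_role = tolower(as.character(pick("encoding_role"))),
               kind = kind, value = as.numeric(value),
               stringsAsFactors = FALSE)
  }
  out <- Filter(Negate(is.null), Map(norm_sheet, sheets, names(sheets)))
  if (!length(out)) {
    info <- vapply(names(sheets), function(s)
      sprintf("'%s' [%s]", s, paste(names(sheets[[s]]), collapse = ", ")),
      character(1))
    stop("unrecognized workbook layout; sheets found: ",
         paste(info, collapse = "; "), call. = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Published reference statistics for the replication harness
#'
#' Summary statistics printed in the original multicenter study whose
#' deposited workbook [read_qa_workbook()] consumes; used only as the
#' comparison column of the replication report, never as computed output.
#'
#' @return data.frame with `quantity` and `reference` columns.
#' @export
reference_published_results <- function() {
  data.frame(
    quantity = c("worst_scanner_e_x", "worst_scanner_e_y",
                 "worst_scanner_e_z", "worst_scanner_e_v",
                 "within_scanner_e_v_median", "within_scanner_e_v_iqr",
                 "frequency_error_median", "frequency_error_iqr",
                 "phase_error_median", "phase_error_iqr",
                 "encoding_mwu_u"),
    reference = c(4.47, 4.82, 4.47, 18.73, 7.33, 0.43, 0.12, 0.35,
                  -0.63, 0.67, 136),
    stringsAsFactors = FALSE)
}

#' Replicate the deposited-data summary statistics
#'
#' Recomputes, from a normalized measurement table (see
#' [read_qa_workbook()]), the headline statistics of the study: per-scanner
#' per-direction scaling-error medians, the within-scanner volumetric-error
#' median and IQR, and the Mann-Whitney U comparison of scaling errors
#' between frequency- and phase-encoding directions over the longitudinal
#' data. Values may be raw measurements (converted to percent errors against
#' the phantom ground truth) or already-computed percent errors.
#'
#' @param tbl table from [read_qa_workbook()] (or equivalent).
#' @param spec the [phantom_spec()] ground truth (used when
#'   `value_type = "measurement"`).
#' @param value_type `"measurement"` (mm / mm^3) or `"error_pct"`.
#' @return List with `scanner_summary`, `within_volume` (median/IQR),
#'   `encoding_test`, and `comparison` against
#'   [reference_published_results()].
#' @export
replicate_results <- function(tbl, spec = phantom_spec(),
                              value_type = c("measurement", "error_pct")) {
  value_type <- match.arg(value_type)
  stopifnot(all(c("kind", "value") %in% names(tbl)))
  if (value_type == "measurement") {
    an <- analyze_records(tbl, spec,
                          group = if ("scanner" %in% names(tbl) &&
                                      !all(is.na(tbl$scanner)))
                            "scanner" else NULL)
    err <- an$errors
  } else {
    err <- tbl
    err$error_pct <- err$value
  }

  scanner_summary <- if (!all(is.na(err$scanner))) {
    dsub <- err[err$kind == "dimension", ]
    summarize_errors(dsub$error_pct,
                     groups = dsub[, c("scanner", "direction")])
  } else NULL

  within <- err[err$kind == "volume" & !is.na(err$time_point), ]
  within_volume <- if (nrow(within))
    summarize_errors(within$error_pct) else NULL

  dl <- err[err$kind == "dimension" & !is.na(err$time_point) &
              err$encoding_role %in% c("frequency", "phase"), ]
  encoding_test <- if (nrow(dl) &&
                       all(c("frequency", "phase") %in% dl$encoding_role))
    mann_whitney_u(dl$error_pct[dl$encoding_role == "frequency"],
                   dl$error_pct[dl$encoding_role == "phase"]) else NULL

  ref <- reference_published_results()
  comp <- ref
  comp$computed <- NA_real_
  put <- function(q, v) comp$computed[comp$quantity == q] <<- v
  if (!is.null(within_volume)) {
    put("within_scanner_e_v_median", within_volume$median)
    put("within_scanner_e_v_iqr", within_volume$iqr)
  }
  if (nrow(dl)) {
    fs <- summarize_errors(dl$error_pct, groups = dl["encoding_role"])
    put("frequency_error_median",
        fs$median[fs$encoding_role == "frequency"])
    put("frequency_error_iqr", fs$iqr[fs$encoding_role == "frequency"])
    put("phase_error_median", fs$median[fs$encoding_role == "phase"])
    put("phase_error_iqr", fs$iqr[fs$encoding_role == "phase"])
  }
  if (!is.null(encoding_test)) {
    # SPSS prints one orientation; accept the closer one
    u <- c(encoding_test$U_a, encoding_test$U_b)
    put("encoding_mwu_u", u[which.min(abs(u - comp$reference[
      comp$quantity == "encoding_mwu_u"]))])
  }
  comp$delta <- comp$computed - comp$reference
  list(scanner_summary = scanner_summary, within_volume = within_volume,
       encoding_test = encoding_test, comparison = comp)
}
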