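#' Write / read a cohort table
#'
#' The cohort CSV dialect: one row per patient; header
#' `patient_id, center, gender, age_years, tobacco, toxic_exposure, prior_bcg,
#' histology, t_stage, n_stage, regimen, cd3_ct, cd8_ct, cd3_im, cd8_im, pcr,
#' ttr_months, ttr_event, os_months, os_event`; densities in cells/mm^2, times
#' in months, events coded 0/1, `pcr` coded `yes`/`no`; an empty cell means
#' missing (so empty IM density cells flag a specimen without an invasive
#' margin). `read_cohort()` also accepts an `.xlsx` spreadsheet laid out with
#' the same columns (requires the `readxl` package); no analysis result in this
#' package depends on the spreadsheet path.
#'
#' @param cohort A cohort `data.frame` as produced by [generate_cohort()].
#' @param path File path (`.csv`, or `.xlsx` for reading).
#' @return `read_cohort()` returns the validated cohort `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(generate_cohort(cohort_config(n_patients = 5, seed = 3)), f)
#' nrow(read_cohort(f))
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, cohort_columns()$name, drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheets requires the 'readxl' package", call. = FALSE)
    df <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), check.names = FALSE)
  }
  validate_cohort(df)
}

cohort_columns <- function() {
  data.frame(
    name = c("patient_id", "center", "gender", "age_years", "tobacco",
             "toxic_exposure", "prior_bcg", "histology", "t_stage", "n_stage",
             "regimen", "cd3_ct", "cd8_ct", "cd3_im", "cd8_im", "pcr",
             "ttr_months", "ttr_event", "os_months", "os_event"),
    type = c("chr", "chr", "chr", "num", "chr", "chr", "chr", "chr", "chr",
             "chr", "chr", "num", "num", "num", "num", "chr", "num", "int",
             "num", "int"),
    stringsAsFactors = FALSE
  )
}

#' Validate a cohort table
#'
#' Checks the documented schema and the patient-level invariants: densities
#' non-negative, times non-negative, events in \{0, 1\}, `pcr` in
#' \{`yes`, `no`, missing\}, and `ttr_months <= os_months` whenever both are
#' present. Violations raise an error naming the offending row.
#'
#' @param cohort A cohort `data.frame`.
#' @return The cohort, invisibly coerced to canonical column types.
#' @export
validate_cohort <- function(cohort) {
  spec <- cohort_columns()
  missing_cols <- setdiff(spec$name, names(cohort))
  if (length(missing_cols))
    stop("malformed cohort header: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cohort <- cohort[, spec$name, drop = FALSE]
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    if (spec$type[i] %in% c("num", "int")) {
      v <- cohort[[nm]]
      if (is.character(v)) v <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
      if (is.logical(v)) v <- as.numeric(v)  # all-empty column read as logical
      bad <- which(is.na(v) & !is.na(cohort[[nm]]) & cohort[[nm]] != "")
      if (length(bad))
        stop("non-numeric value in '", nm, "' at row ", bad[1], call. = FALSE)
      cohort[[nm]] <- if (spec$type[i] == "int") as.integer(v) else as.numeric(v)
    } else {
      cohort[[nm]] <- as.character(cohort[[nm]])
    }
  }
  check_rows <- function(bad, msg) {
    if (any(bad, na.rm = TRUE))
      stop(msg, " at row ", which(bad)[1], call. = FALSE)
  }
  for (nm in c("cd3_ct", "cd8_ct", "cd3_im", "cd8_im"))
    check_rows(cohort[[nm]] < 0, paste0("negative density in '", nm, "'"))
  for (nm in c("ttr_months", "os_months"))
    check_rows(cohort[[nm]] < 0, paste0("negative time in '", nm, "'"))
  for (nm in c("ttr_event", "os_event"))
    check_rows(!cohort[[nm]] %in% c(0L, 1L), paste0("'", nm, "' must be 0 or 1"))
  check_rows(!is.na(cohort$pcr) & !cohort$pcr %in% c("yes", "no"),
             "'pcr' must be yes/no/empty")
  check_rows(cohort$ttr_months > cohort$os_months + 1e-9,
             "ttr_months exceeds os_months")
  # a specimen either has both IM densities or neither
  check_rows(xor(is.na(cohort$cd3_im), is.na(cohort$cd8_im)),
             "IM densities must be jointly present or jointly missing")
  cohort
}
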