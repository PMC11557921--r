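# Typed patient-table I/O.  The CSV column dictionary spans raw
# physiology, imaging inputs, comorbidity flags, covariates and outcomes;
# an empty cell is an explicit missing value.

#' Patient table column dictionary
#'
#' @return A data frame with one row per column of the patient CSV schema:
#'   `name` and `type` (`"integer"`, `"numeric"`, `"logical"`,
#'   `"character"`).
#' @export
patient_table_columns <- function() {
  cols <- c(
    patient_id = "integer", age = "numeric", sex = "character",
    treatment = "character",
    gcs_min = "integer", hr_min = "numeric", hr_max = "numeric",
    sbp_min = "numeric", sbp_max = "numeric", urea_max = "numeric",
    creatinine_max = "numeric", urine_24h = "numeric",
    ventilated_or_cpap = "logical", pao2_fio2 = "numeric",
    pao2_fio2_unit = "character", wbc_min = "numeric", wbc_max = "numeric",
    platelets_min = "numeric", bilirubin_max = "numeric",
    pt_excess_sec = "numeric",
    stats::setNames(rep("integer", 10), paste0("cistern_", 1:10)),
    stats::setNames(rep("integer", 4), paste0("ventricle_", 1:4)),
    hematoma_a = "numeric", hematoma_b = "numeric", hematoma_c = "numeric",
    loc = "logical", edema = "logical",
    stats::setNames(rep("logical", length(charlson_conditions())),
                    charlson_conditions()),
    mrs = "integer", died_in_hospital = "logical"
  )
  data.frame(name = names(cols), type = unname(cols),
             stringsAsFactors = FALSE)
}

#' Read and validate a patient CSV table
#'
#' The header must contain exactly the dictionary columns (see
#' [patient_table_columns()]); unknown columns are a hard error.  Row
#' validation checks the scoring preconditions (GCS 3-15, grades within
#' range, mRS 0-6, death implies mRS 6, min <= max).  In strict mode an
#' invalid row aborts the read; otherwise invalid rows are dropped with a
#' warning listing their row numbers.
#'
#' @param path Path to a CSV file.
#' @param strict Logical; `TRUE` (default) aborts on the first invalid
#'   row, `FALSE` drops invalid rows with a warning.
#' @return A typed data frame, one row per valid patient.
#' @export
read_patient_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dict <- patient_table_columns()
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  unknown <- setdiff(header, dict$name)
  if (length(unknown) > 0) {
    stop("unknown column(s) in patient table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(dict$name, header)
  if (length(absent) > 0) {
    stop("patient table is missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  classes <- stats::setNames(dict$type, dict$name)[header]
  data <- utils::read.csv(path, colClasses = classes, check.names = FALSE,
                          na.strings = c("", "NA"))
  problems <- .validate_rows(data)
  if (length(problems) > 0) {
    msg <- paste0("row ", names(problems), ": ", unlist(problems))
    if (strict) {
      stop("invalid patient row(s):\n  ", paste(msg, collapse = "\n  "),
           call. = FALSE)
    }
    warning("dropping invalid patient row(s):\n  ",
            paste(msg, collapse = "\n  "), call. = FALSE)
    data <- data[-as.integer(names(problems)), , drop = FALSE]
    rownames(data) <- NULL
  }
  data
}

.validate_rows <- function(data) {
  problems <- list()
  note <- function(rows, what) {
    for (r in rows) problems[[as.character(r)]] <<-
        c(problems[[as.character(r)]], what)
  }
  bad <- which(!is.na(data$gcs_min) & (data$gcs_min < 3 | data$gcs_min > 15))
  note(bad, "gcs_min outside [3, 15]")
  for (g in paste0("cistern_", 1:10)) {
    note(which(!is.na(data[[g]]) & (data[[g]] < 0 | data[[g]] > 3)),
         paste(g, "outside {0..3}"))
  }
  for (g in paste0("ventricle_", 1:4)) {
    note(which(!is.na(data[[g]]) & (data[[g]] < 0 | data[[g]] > 4)),
         paste(g, "outside {0..4}"))
  }
  note(which(!is.na(data$mrs) & (data$mrs < 0 | data$mrs > 6)),
       "mrs outside [0, 6]")
  note(which(!is.na(data$died_in_hospital) & data$died_in_hospital &
             (is.na(data$mrs) | data$mrs != 6)),
       "died_in_hospital without mrs = 6")
  for (pair in list(c("hr_min", "hr_max"), c("sbp_min", "sbp_max"),
                    c("wbc_min", "wbc_max"))) {
    note(which(!is.na(data[[pair[1]]]) & !is.na(data[[pair[2]]]) &
               data[[pair[1]]] > data[[pair[2]]]),
         paste(pair[1], ">", pair[2]))
  }
  problems <- lapply(problems, paste, collapse = "; ")
  problems[order(as.integer(names(problems)))]
}

#' Write a patient or scores table as CSV
#'
#' Plain RFC-4180 CSV, UTF-8, `.` decimal separator, empty cell for
#' missing values; write-then-read round-trips the table.
#'
#' @param data A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_patient_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Published cohort frequency table
#'
#' Frequency counts of EBI grade (1-5), LODS total and mRS (0-6) in the
#' published 324-patient aSAH cohort this package's defaults emulate, as
#' shipped in `inst/extdata/published_cohort_frequencies.csv`.
#'
#' @return A data frame with columns `variable`, `level`, `count`.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "published_cohort_frequencies.csv",
                      package = "lodsebi", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Expand a frequency table into per-patient values
#'
#' @param counts A data frame with columns `level` and `count`.
#' @return Numeric vector repeating each level `count` times.
#' @export
expand_counts <- function(counts) {
  rep(counts$level, counts$count)
}
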