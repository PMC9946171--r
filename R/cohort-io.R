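# Cohort file interchange: RFC-4180 CSV, UTF-8, header row, empty field =
# missing, dates ISO-8601, booleans 0/1. Round-trips are lossless (readr
# writes doubles with shortest round-trip precision).

.cohort_columns <- c(
  "patient_id", "age", "sex", "sbp", "heart_rate", "respiratory_rate",
  "spo2", "temperature", "fio2", "alert", "urea", "leukocytes",
  "icu_admission", "disposition", "died_24h", "presentation_date"
)

# validation ranges for file input (wider than the generator's draw bounds:
# they reject physiologically impossible values, not unusual ones)
.validation_ranges <- list(
  age = c(18, 110), sbp = c(20, 300), heart_rate = c(10, 300),
  respiratory_rate = c(1, 80), spo2 = c(1, 100), temperature = c(25, 45),
  fio2 = c(0.21, 1), urea = c(0.01, 100), leukocytes = c(0.01, 500)
)

#' Write a cohort to CSV
#'
#' One row per ED visit; missing cells are written as empty fields, logical
#' flags as 0/1, dates as ISO-8601. The latent `severity` column, when
#' present, is preserved (it is simulation ground truth, useful for
#' mechanism checks). The same cohort always produces byte-identical files.
#'
#' @param cohort An `ed_cohort` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as_tibble(cohort)
  for (v in c("alert", "icu_admission", "died_24h")) {
    out[[v]] <- as.integer(out[[v]])
  }
  out$presentation_date <- format(out$presentation_date, "%Y-%m-%d")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Parses a file written by [write_cohort()] (or prepared to the same
#' layout). Every row is validated against physiological ranges; malformed
#' rows, unknown columns and out-of-range values raise an error naming the
#' offending row and variable. Empty fields become `NA` (unrecorded).
#'
#' @param path CSV file path.
#' @return An `ed_cohort` tibble.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  extra <- setdiff(names(raw), c(.cohort_columns, "severity"))
  if (length(extra) > 0) {
    stop_ed("unknown column(s) in cohort file: %s", paste(extra, collapse = ", "))
  }
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop_ed("cohort file lacks required column(s): %s",
            paste(missing_cols, collapse = ", "))
  }

  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(x))
    if (length(bad) > 0) {
      stop_ed("row %d: %s = '%s' is not numeric", bad[1], col, raw[[col]][bad[1]])
    }
    x
  }
  parse_bool <- function(col) {
    x <- raw[[col]]
    bad <- which(!is.na(x) & !x %in% c("0", "1"))
    if (length(bad) > 0) {
      stop_ed("row %d: %s = '%s' is not 0/1", bad[1], col, x[bad[1]])
    }
    as.logical(as.integer(x))
  }

  tbl <- tibble(
    patient_id = raw$patient_id,
    age = parse_num("age"),
    sex = raw$sex,
    sbp = parse_num("sbp"),
    heart_rate = parse_num("heart_rate"),
    respiratory_rate = parse_num("respiratory_rate"),
    spo2 = parse_num("spo2"),
    temperature = parse_num("temperature"),
    fio2 = parse_num("fio2"),
    alert = parse_bool("alert"),
    urea = parse_num("urea"),
    leukocytes = parse_num("leukocytes"),
    icu_admission = parse_bool("icu_admission"),
    disposition = raw$disposition,
    died_24h = parse_bool("died_24h"),
    presentation_date = as.Date(raw$presentation_date, format = "%Y-%m-%d")
  )
  if ("severity" %in% names(raw)) tbl$severity <- parse_num("severity")

  bad_date <- which(!is.na(raw$presentation_date) & is.na(tbl$presentation_date))
  if (length(bad_date) > 0) {
    stop_ed("row %d: presentation_date = '%s' is not ISO-8601",
            bad_date[1], raw$presentation_date[bad_date[1]])
  }
  bad_sex <- which(!is.na(tbl$sex) & !tbl$sex %in% c("M", "F"))
  if (length(bad_sex) > 0) {
    stop_ed("row %d: sex = '%s' (expected M or F)", bad_sex[1], tbl$sex[bad_sex[1]])
  }
  bad_disp <- which(!is.na(tbl$disposition) &
                      !tbl$disposition %in% c("admitted", "discharged"))
  if (length(bad_disp) > 0) {
    stop_ed("row %d: disposition = '%s' (expected admitted or discharged)",
            bad_disp[1], tbl$disposition[bad_disp[1]])
  }
  for (v in names(.validation_ranges)) {
    rng <- .validation_ranges[[v]]
    bad <- which(!is.na(tbl[[v]]) & (tbl[[v]] < rng[1] | tbl[[v]] > rng[2]))
    if (length(bad) > 0) {
      stop_ed("row %d: %s = %g outside physiological range [%g, %g]",
              bad[1], v, tbl[[v]][bad[1]], rng[1], rng[2])
    }
  }
  died_discharged <- which(!is.na(tbl$died_24h) & tbl$died_24h &
                             tbl$disposition == "discharged")
  # discharged deaths are allowed only as sensitivity-analysis output, so
  # they are accepted on read; validation rejects only impossible values
  new_ed_cohort(tbl, meta = list(source = path,
                                 discharged_deaths = length(died_discharged)))
}
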