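#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Canonical column order for a grantee cohort. One row per grantee
# (a Section 330 health-center grant recipient, possibly multi-site).
grantee_columns <- function() {
  c(
    "grantee_id", "state",
    "medical_patients",
    "medical_patients_12plus_public", "medical_patients_12plus_private",
    "mh_patients",
    "mh_encounters_licensed", "mh_encounters_psychiatrist",
    "mh_encounters_other_staff",
    "sa_patients", "sa_encounters",
    "fte_licensed_mh", "fte_psychiatrist", "fte_other_mh_staff",
    "fte_substance_abuse"
  )
}

grantee_count_columns <- function() {
  setdiff(grantee_columns(), c("grantee_id", "state",
                               "fte_licensed_mh", "fte_psychiatrist",
                               "fte_other_mh_staff", "fte_substance_abuse"))
}

grantee_fte_columns <- function() {
  c("fte_licensed_mh", "fte_psychiatrist", "fte_other_mh_staff",
    "fte_substance_abuse")
}

grantee_encounter_columns <- function() {
  c("mh_encounters_licensed", "mh_encounters_psychiatrist",
    "mh_encounters_other_staff", "sa_encounters")
}

#' Validate a grantee cohort
#'
#' Checks that a data frame of health-center grantee records satisfies the
#' structural invariants the staffing model relies on: all mandatory columns
#' present, all counts and FTE non-negative, patients aged 12 and over (the
#' two insurance strata combined) not exceeding total medical patients, and
#' no onsite encounters reported by grantees with zero behavioral health FTE.
#'
#' @param grantees A data frame with one row per grantee; see
#'   [generate_grantees()] for the column set.
#' @return The input as a tibble, invisibly classed, or an error naming the
#'   offending row and column.
#' @export
validate_grantees <- function(grantees) {
  if (!is.data.frame(grantees)) {
    stop("`grantees` must be a data frame", call. = FALSE)
  }
  missing <- setdiff(grantee_columns(), names(grantees))
  if (length(missing) > 0) {
    stop("grantee table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grantees <- tibble::as_tibble(grantees)[, grantee_columns()]

  numeric_cols <- setdiff(grantee_columns(), c("grantee_id", "state"))
  for (col in numeric_cols) {
    x <- grantees[[col]]
    if (!is.numeric(x)) {
      stop("column `", col, "` must be numeric", call. = FALSE)
    }
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad) > 0) {
      stop("column `", col, "` has a negative or non-finite value at row ",
           bad[1], call. = FALSE)
    }
  }

  over <- which(grantees$medical_patients_12plus_public +
                  grantees$medical_patients_12plus_private >
                  grantees$medical_patients + 1e-9)
  if (length(over) > 0) {
    stop("12+ insurance strata exceed total medical patients at row ",
         over[1], call. = FALSE)
  }

  fte_total <- rowSums(grantees[grantee_fte_columns()])
  enc_total <- rowSums(grantees[grantee_encounter_columns()])
  bad <- which(fte_total == 0 & enc_total > 0)
  if (length(bad) > 0) {
    stop("grantee at row ", bad[1],
         " reports onsite encounters but zero behavioral health FTE",
         call. = FALSE)
  }
  grantees
}

#' Read a grantee cohort from CSV
#'
#' The file must carry one row per grantee with the exact header documented
#' in [generate_grantees()]; unknown columns are dropped with a warning.
#' Values must be plain numbers (no thousands separators).
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A validated tibble of grantee records.
#' @export
read_grantees <- function(path) {
  if (!file.exists(path)) {
    stop("grantee file not found: ", path, call. = FALSE)
  }
  # parse problems are re-raised below as errors naming row and column, so
  # readr's own advisory warning is muffled
  raw <- withCallingHandlers(
    readr::read_csv(path, col_types = readr::cols(
      grantee_id = readr::col_character(),
      state = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE, show_col_types = FALSE),
    warning = function(w) {
      if (grepl("parsing issues", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("non-numeric or malformed cell at row ", probs$row[1],
         ", column ", probs$col[1], " of ", path, call. = FALSE)
  }
  extra <- setdiff(names(raw), grantee_columns())
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[, setdiff(names(raw), extra)]
  }
  validate_grantees(raw)
}

#' Write a grantee cohort to CSV
#'
#' Round-trips losslessly through [read_grantees()]. No thousands
#' separators are written.
#'
#' @param grantees A grantee cohort (validated on the way out).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grantees <- function(grantees, path) {
  grantees <- validate_grantees(grantees)
  readr::write_csv(grantees, path, progress = FALSE)
  invisible(path)
}
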