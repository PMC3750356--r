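mh_fte_total <- function(cohort) {
  cohort$fte_licensed_mh + cohort$fte_psychiatrist + cohort$fte_other_mh_staff
}

mh_encounters_total <- function(cohort) {
  cohort$mh_encounters_licensed + cohort$mh_encounters_psychiatrist +
    cohort$mh_encounters_other_staff
}

#' Median annual mental health visits per mental health patient
#'
#' For each grantee with onsite mental health staff (positive FTE in any of
#' the three mental health categories) and at least one mental health
#' patient, the annual visits-per-patient ratio is total mental health
#' encounters divided by mental health patients. Returns the median of
#' these per-grantee ratios (average of the two middle order statistics for
#' even counts).
#'
#' @param cohort A grantee cohort.
#' @return Median visits per patient per year.
#' @export
median_visits_per_mh_patient <- function(cohort) {
  cohort <- validate_grantees(cohort)
  eligible <- mh_fte_total(cohort) > 0 & cohort$mh_patients > 0
  if (!any(eligible)) {
    stop("no onsite mental health utilization data: no grantee has both ",
         "positive mental health FTE and patients", call. = FALSE)
  }
  ratios <- mh_encounters_total(cohort)[eligible] /
    cohort$mh_patients[eligible]
  stats::median(ratios)
}

#' Median annual substance abuse visits per substance abuse patient
#'
#' Analogue of [median_visits_per_mh_patient()] for substance abuse:
#' grantees with positive substance abuse FTE and patients.
#'
#' @param cohort A grantee cohort.
#' @return Median visits per patient per year.
#' @export
median_visits_per_sa_patient <- function(cohort) {
  cohort <- validate_grantees(cohort)
  eligible <- cohort$fte_substance_abuse > 0 & cohort$sa_patients > 0
  if (!any(eligible)) {
    stop("no onsite substance abuse utilization data: no grantee has both ",
         "positive substance abuse FTE and patients", call. = FALSE)
  }
  stats::median(cohort$sa_encounters[eligible] / cohort$sa_patients[eligible])
}

#' Pooled visit shares by mental health provider type
#'
#' Sums mental health encounters across all grantees with onsite mental
#' health staff and returns the fraction delivered by licensed mental
#' health providers (psychologists, licensed clinical social workers and
#' other licensed master's-prepared clinicians, pooled), psychiatrists, and
#' other mental health staff. Pooled, not a median of per-grantee shares.
#'
#' @param cohort A grantee cohort.
#' @return Named numeric vector `(licensed, psychiatrist, other_staff)`
#'   summing to 1.
#' @export
visit_shares_by_provider <- function(cohort) {
  cohort <- validate_grantees(cohort)
  eligible <- mh_fte_total(cohort) > 0
  totals <- c(
    licensed = sum(cohort$mh_encounters_licensed[eligible]),
    psychiatrist = sum(cohort$mh_encounters_psychiatrist[eligible]),
    other_staff = sum(cohort$mh_encounters_other_staff[eligible])
  )
  if (sum(totals) <= 0) {
    stop("no pooled mental health encounters among grantees with onsite ",
         "mental health staff", call. = FALSE)
  }
  totals / sum(totals)
}

provider_categories <- function() {
  c("licensed", "psychiatrist", "other_staff", "substance_abuse")
}

category_fields <- function(category) {
  switch(category,
    licensed = list(enc = "mh_encounters_licensed", fte = "fte_licensed_mh"),
    psychiatrist = list(enc = "mh_encounters_psychiatrist",
                        fte = "fte_psychiatrist"),
    other_staff = list(enc = "mh_encounters_other_staff",
                       fte = "fte_other_mh_staff"),
    substance_abuse = list(enc = "sa_encounters", fte = "fte_substance_abuse"),
    stop("unknown provider category `", category, "`; must be one of: ",
         paste(provider_categories(), collapse = ", "), call. = FALSE)
  )
}

#' Median annual visit load per FTE for a provider category
#'
#' For each grantee with positive FTE in the category, the visit load is
#' the category's encounters divided by its FTE; grantees with zero FTE in
#' the category are excluded (not treated as load zero). Returns the median
#' per-grantee load.
#'
#' @param cohort A grantee cohort.
#' @param category One of `"licensed"`, `"psychiatrist"`, `"other_staff"`,
#'   `"substance_abuse"`.
#' @return Median annual visits per 1.0 FTE.
#' @export
median_visit_load <- function(cohort, category) {
  cohort <- validate_grantees(cohort)
  f <- category_fields(category)
  eligible <- cohort[[f$fte]] > 0
  if (!any(eligible)) {
    stop("no grantee has positive FTE in category `", category, "`",
         call. = FALSE)
  }
  stats::median(cohort[[f$enc]][eligible] / cohort[[f$fte]][eligible])
}

#' Construct a utilization-parameter set
#'
#' The nine quantities that convert target patient populations into FTE
#' need: median annual visits per mental health patient, pooled visit
#' shares by provider type, median annual visit loads per FTE for the
#' three mental health categories, and the substance abuse analogues.
#' Shares given in percent (summing to ~100) are auto-normalized with a
#' message.
#'
#' @param median_visits_per_mh_patient Visits/patient/year.
#' @param share_licensed,share_psychiatrist,share_other_staff Visit-share
#'   fractions; must sum to 1 (or 100 if given in percent).
#' @param median_visits_per_licensed_fte,median_visits_per_psychiatrist_fte,median_visits_per_other_staff_fte
#'   Visits/FTE/year for the three mental health categories.
#' @param median_visits_per_sa_patient Visits/patient/year, substance abuse.
#' @param median_visits_per_sa_fte Visits/FTE/year, substance abuse
#'   providers.
#' @return A `bh_utilization` object.
#' @export
utilization_parameters <- function(median_visits_per_mh_patient,
                                   share_licensed,
                                   share_psychiatrist,
                                   share_other_staff,
                                   median_visits_per_licensed_fte,
                                   median_visits_per_psychiatrist_fte,
                                   median_visits_per_other_staff_fte,
                                   median_visits_per_sa_patient,
                                   median_visits_per_sa_fte) {
  shares <- c(share_licensed, share_psychiatrist, share_other_staff)
  if (any(!is.finite(shares)) || any(shares < 0)) {
    stop("visit shares must be finite and non-negative", call. = FALSE)
  }
  s <- sum(shares)
  if (abs(s - 100) < 1) {
    message("visit shares appear to be in percent (sum ", round(s, 3),
            "); normalizing to fractions")
    shares <- shares / s
  } else if (abs(s - 1) > 1e-9) {
    if (abs(s - 1) < 0.01) {
      # printed shares rounded to one decimal percent: renormalize quietly
      shares <- shares / s
    } else {
      stop("visit shares must sum to 1 (got ", s, ")", call. = FALSE)
    }
  }
  medians <- c(median_visits_per_mh_patient,
               median_visits_per_licensed_fte,
               median_visits_per_psychiatrist_fte,
               median_visits_per_other_staff_fte,
               median_visits_per_sa_patient,
               median_visits_per_sa_fte)
  if (any(!is.finite(medians)) || any(medians <= 0)) {
    stop("all median visit rates and visit loads must be positive",
         call. = FALSE)
  }
  structure(list(
    median_visits_per_mh_patient = median_visits_per_mh_patient,
    share_licensed = shares[1],
    share_psychiatrist = shares[2],
    share_other_staff = shares[3],
    median_visits_per_licensed_fte = median_visits_per_licensed_fte,
    median_visits_per_psychiatrist_fte = median_visits_per_psychiatrist_fte,
    median_visits_per_other_staff_fte = median_visits_per_other_staff_fte,
    median_visits_per_sa_patient = median_visits_per_sa_patient,
    median_visits_per_sa_fte = median_visits_per_sa_fte
  ), class = "bh_utilization")
}

#' Estimate utilization parameters from a cohort, or load a literal set
#'
#' With a cohort, composes [median_visits_per_mh_patient()],
#' [visit_shares_by_provider()], [median_visit_load()] and the substance
#' abuse analogues, restricted to grantees with onsite behavioral health
#' staff. With `file`, bypasses estimation and reads the nine parameter
#' values from a YAML/JSON file — used to reproduce published-table
#' arithmetic exactly from printed parameter values.
#'
#' @param cohort A grantee cohort (ignored if `file` is given).
#' @param file Optional path to a parameter file with the nine
#'   [utilization_parameters()] fields.
#' @return A `bh_utilization` object.
#' @export
assemble_parameters <- function(cohort = NULL, file = NULL) {
  if (!is.null(file)) {
    vals <- read_config_file(file)
    need <- c("median_visits_per_mh_patient", "share_licensed",
              "share_psychiatrist", "share_other_staff",
              "median_visits_per_licensed_fte",
              "median_visits_per_psychiatrist_fte",
              "median_visits_per_other_staff_fte",
              "median_visits_per_sa_patient", "median_visits_per_sa_fte")
    missing <- setdiff(need, names(vals))
    if (length(missing) > 0) {
      stop("parameter file missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(do.call(utilization_parameters, vals[need]))
  }
  if (is.null(cohort)) {
    stop("supply either a cohort or a parameter file", call. = FALSE)
  }
  cohort <- validate_grantees(cohort)
  shares <- visit_shares_by_provider(cohort)
  utilization_parameters(
    median_visits_per_mh_patient = median_visits_per_mh_patient(cohort),
    share_licensed = shares[["licensed"]],
    share_psychiatrist = shares[["psychiatrist"]],
    share_other_staff = shares[["other_staff"]],
    median_visits_per_licensed_fte = median_visit_load(cohort, "licensed"),
    median_visits_per_psychiatrist_fte =
      median_visit_load(cohort, "psychiatrist"),
    median_visits_per_other_staff_fte =
      median_visit_load(cohort, "other_staff"),
    median_visits_per_sa_patient = median_visits_per_sa_patient(cohort),
    median_visits_per_sa_fte = median_visit_load(cohort, "substance_abuse")
  )
}

#' Published 2010 utilization parameters
#'
#' The national 2010 UDS-derived utilization medians for health-center
#' grantees with onsite behavioral health staff: 3.7 annual visits per
#' mental health patient; 59.9% / 23.3% / 16.8% of mental health visits to
#' licensed providers, psychiatrists and other staff; median annual visit
#' loads of 889, 2,210 and 648 visits per FTE; 5.8 annual visits per
#' substance abuse patient and 1,012 visits per substance abuse provider
#' FTE.
#'
#' @return A `bh_utilization` object carrying the published values.
#' @export
reference_parameters_2010 <- function() {
  utilization_parameters(
    median_visits_per_mh_patient = 3.7,
    share_licensed = 0.599,
    share_psychiatrist = 0.233,
    share_other_staff = 0.168,
    median_visits_per_licensed_fte = 889,
    median_visits_per_psychiatrist_fte = 2210,
    median_visits_per_other_staff_fte = 648,
    median_visits_per_sa_patient = 5.8,
    median_visits_per_sa_fte = 1012
  )
}

#' @export
print.bh_utilization <- function(x, ...) {
  cat("Annual behavioral health service utilization parameters\n")
  cat(sprintf("  Median visits per mental health patient    %6.1f\n",
              x$median_visits_per_mh_patient))
  cat(sprintf("  Percent of visits to licensed MH providers %6.1f%%\n",
              100 * x$share_licensed))
  cat(sprintf("  Percent of visits to psychiatrists         %6.1f%%\n",
              100 * x$share_psychiatrist))
  cat(sprintf("  Percent of visits to other MH staff        %6.1f%%\n",
              100 * x$share_other_staff))
  cat(sprintf("  Median visits per licensed MH provider FTE %6.0f\n",
              x$median_visits_per_licensed_fte))
  cat(sprintf("  Median visits per psychiatrist FTE         %6.0f\n",
              x$median_visits_per_psychiatrist_fte))
  cat(sprintf("  Median visits per other MH staff FTE       %6.0f\n",
              x$median_visits_per_other_staff_fte))
  cat(sprintf("  Median visits per substance abuse patient  %6.1f\n",
              x$median_visits_per_sa_patient))
  cat(sprintf("  Median visits per substance abuse FTE      %6.0f\n",
              x$median_visits_per_sa_fte))
  invisible(x)
}
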