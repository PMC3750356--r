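#' Target behavioral health patient populations for a grantee
#'
#' Applies insurance-stratified prevalence to a grantee's medical patients
#' aged 12 and over: the expected number of patients with mild or moderate
#' mental illness and the expected number with past-year illicit drug or
#' alcohol abuse. Both are real-valued; no rounding occurs until
#' reporting.
#'
#' @param public_12plus,private_12plus Medical patients aged 12+ in the
#'   public/uninsured and Medicare/private strata (vectorized).
#' @param prevalence A [prevalence_table()].
#' @return A tibble with columns `target_mh_patients` and
#'   `target_sa_patients`.
#' @export
#' @examples
#' target_patients(7600, 2400, default_prevalence())
target_patients <- function(public_12plus, private_12plus, prevalence) {
  stopifnot(inherits(prevalence, "bh_prevalence"))
  tibble::tibble(
    target_mh_patients = public_12plus * prevalence$mi_public +
      private_12plus * prevalence$mi_private,
    target_sa_patients = public_12plus * prevalence$sa_public +
      private_12plus * prevalence$sa_private
  )
}

#' FTE needed to serve target behavioral health populations
#'
#' Converts target patient counts into staffing need: mental health visits
#' needed are target patients times the median annual visits per patient;
#' those visits are split across licensed providers, psychiatrists and
#' other mental health staff by the pooled visit shares; each category's
#' visits are divided by its median annual visit load per FTE. Substance
#' abuse FTE are computed the same way from a single category. Linear and
#' homogeneous in the targets; all arithmetic stays in real numbers.
#'
#' @param target_mh_patients,target_sa_patients Target populations
#'   (vectorized).
#' @param params A [utilization_parameters()] set.
#' @return A tibble with visit and FTE columns: `mh_visits_needed`,
#'   `visits_needed_licensed`, `visits_needed_psychiatrist`,
#'   `visits_needed_other_staff`, `sa_visits_needed`,
#'   `fte_needed_licensed`, `fte_needed_psychiatrist`,
#'   `fte_needed_other_staff`, `fte_needed_sa`.
#' @export
#' @examples
#' fte_needed(5918248, 841182, reference_parameters_2010())
fte_needed <- function(target_mh_patients, target_sa_patients, params) {
  stopifnot(inherits(params, "bh_utilization"))
  loads <- c(params$median_visits_per_licensed_fte,
             params$median_visits_per_psychiatrist_fte,
             params$median_visits_per_other_staff_fte,
             params$median_visits_per_sa_fte)
  if (any(loads <= 0)) {
    stop("all visit loads must be positive to convert visits to FTE",
         call. = FALSE)
  }
  mh_visits <- target_mh_patients * params$median_visits_per_mh_patient
  v_lic <- mh_visits * params$share_licensed
  v_psy <- mh_visits * params$share_psychiatrist
  v_oth <- mh_visits * params$share_other_staff
  sa_visits <- target_sa_patients * params$median_visits_per_sa_patient
  tibble::tibble(
    mh_visits_needed = mh_visits,
    visits_needed_licensed = v_lic,
    visits_needed_psychiatrist = v_psy,
    visits_needed_other_staff = v_oth,
    sa_visits_needed = sa_visits,
    fte_needed_licensed = v_lic / params$median_visits_per_licensed_fte,
    fte_needed_psychiatrist = v_psy / params$median_visits_per_psychiatrist_fte,
    fte_needed_other_staff = v_oth / params$median_visits_per_other_staff_fte,
    fte_needed_sa = sa_visits / params$median_visits_per_sa_fte
  )
}

#' Per-category staffing shortage, floored at zero
#'
#' Shortage is needed FTE minus existing FTE, floored at zero per grantee
#' and category: a grantee staffed beyond its estimated need contributes no
#' negative shortage, so over-served grantees never offset under-served
#' ones.
#'
#' @param needed,existing Numeric vectors of needed and existing FTE.
#' @return `pmax(0, needed - existing)`.
#' @export
shortage <- function(needed, existing) {
  pmax(0, needed - existing)
}

#' Per-grantee behavioral health needs estimates
#'
#' Runs the full needs model for every grantee in a cohort — including
#' grantees with no current onsite behavioral health staff or patients:
#' target populations from prevalence, visit demand, FTE need by provider
#' category, and floored shortages against existing staffing.
#'
#' @param cohort A grantee cohort.
#' @param prevalence A [prevalence_table()]; defaults to
#'   [default_prevalence()].
#' @param params A [utilization_parameters()] set; if `NULL`, estimated
#'   from the cohort with [assemble_parameters()].
#' @return A tibble with one row per grantee: targets, visit demand, FTE
#'   need and `shortage_licensed`, `shortage_psychiatrist`,
#'   `shortage_other_staff`, `shortage_sa`.
#' @export
estimate_needs <- function(cohort, prevalence = default_prevalence(),
                           params = NULL) {
  cohort <- validate_grantees(cohort)
  if (is.null(params)) {
    params <- assemble_parameters(cohort)
  }
  targets <- target_patients(cohort$medical_patients_12plus_public,
                             cohort$medical_patients_12plus_private,
                             prevalence)
  need <- fte_needed(targets$target_mh_patients, targets$target_sa_patients,
                     params)
  dplyr::bind_cols(
    tibble::tibble(grantee_id = cohort$grantee_id),
    targets, need,
    tibble::tibble(
      shortage_licensed = shortage(need$fte_needed_licensed,
                                   cohort$fte_licensed_mh),
      shortage_psychiatrist = shortage(need$fte_needed_psychiatrist,
                                       cohort$fte_psychiatrist),
      shortage_other_staff = shortage(need$fte_needed_other_staff,
                                      cohort$fte_other_mh_staff),
      shortage_sa = shortage(need$fte_needed_sa,
                             cohort$fte_substance_abuse)
    )
  )
}

#' National summary of behavioral health need and shortage
#'
#' Aggregates per-grantee estimates to the program level, mirroring the
#' standard national reporting layout: for each row (mental health
#' patients, substance abuse patients, total behavioral health FTE and the
#' four provider categories) the 2010-style actual, the model result, the
#' number of grantees with a shortage (strictly positive), and the
#' shortage sum with per-grantee flooring. Because of the flooring, the
#' shortage sum exceeds the model-minus-actual difference by exactly the
#' excess delivered by over-served grantees; the summary carries those
#' excess-served identities, plus the count of grantees short in any of
#' the three mental health categories (the "unable to provide onsite
#' mental health services" count).
#'
#' @param estimates Output of [estimate_needs()] for `cohort`.
#' @param cohort The grantee cohort the estimates were computed from.
#' @return A `bh_national_summary`: list with a `summary` tibble (columns
#'   `row`, `actual`, `model`, `n_grantees_with_shortage`, `shortage`),
#'   counts `n_grantees`, `n_short_any_mh`, `n_short_sa`, and the
#'   excess-served patient totals `excess_served_mh`, `excess_served_sa`.
#' @export
aggregate_national <- function(estimates, cohort) {
  cohort <- validate_grantees(cohort)
  if (!setequal(estimates$grantee_id, cohort$grantee_id) ||
      nrow(estimates) != nrow(cohort)) {
    stop("estimates and cohort cover different grantees", call. = FALSE)
  }
  d <- dplyr::inner_join(estimates, cohort, by = "grantee_id")

  pat_short_mh <- shortage(d$target_mh_patients, d$mh_patients)
  pat_short_sa <- shortage(d$target_sa_patients, d$sa_patients)
  short_any_mh <- d$shortage_licensed > 0 | d$shortage_psychiatrist > 0 |
    d$shortage_other_staff > 0

  existing_total <- d$fte_licensed_mh + d$fte_psychiatrist +
    d$fte_other_mh_staff + d$fte_substance_abuse
  needed_total <- d$fte_needed_licensed + d$fte_needed_psychiatrist +
    d$fte_needed_other_staff + d$fte_needed_sa
  shortage_total <- d$shortage_licensed + d$shortage_psychiatrist +
    d$shortage_other_staff + d$shortage_sa

  row <- function(row, actual, model, n_short, short) {
    tibble::tibble(row = row, actual = sum(actual), model = sum(model),
                   n_grantees_with_shortage = n_short,
                   shortage = sum(short))
  }
  summary <- dplyr::bind_rows(
    row("mh_patients", d$mh_patients, d$target_mh_patients,
        sum(pat_short_mh > 0), pat_short_mh),
    row("sa_patients", d$sa_patients, d$target_sa_patients,
        sum(pat_short_sa > 0), pat_short_sa),
    row("bh_fte", existing_total, needed_total, NA_integer_, shortage_total),
    row("fte_licensed", d$fte_licensed_mh, d$fte_needed_licensed,
        sum(d$shortage_licensed > 0), d$shortage_licensed),
    row("fte_psychiatrist", d$fte_psychiatrist, d$fte_needed_psychiatrist,
        sum(d$shortage_psychiatrist > 0), d$shortage_psychiatrist),
    row("fte_other_staff", d$fte_other_mh_staff, d$fte_needed_other_staff,
        sum(d$shortage_other_staff > 0), d$shortage_other_staff),
    row("fte_sa", d$fte_substance_abuse, d$fte_needed_sa,
        sum(d$shortage_sa > 0), d$shortage_sa)
  )
  mh_row <- summary[summary$row == "mh_patients", ]
  sa_row <- summary[summary$row == "sa_patients", ]
  structure(list(
    summary = summary,
    n_grantees = nrow(cohort),
    n_short_any_mh = sum(short_any_mh),
    n_short_sa = sum(d$shortage_sa > 0),
    excess_served_mh = mh_row$shortage - (mh_row$model - mh_row$actual),
    excess_served_sa = sa_row$shortage - (sa_row$model - sa_row$actual)
  ), class = "bh_national_summary")
}

#' @export
print.bh_national_summary <- function(x, ...) {
  cat("National behavioral health staffing summary (",
      x$n_grantees, " grantees)\n", sep = "")
  s <- x$summary
  cat(sprintf("  %-18s %12s %12s %10s %12s\n",
              "", "Actual", "Model", "N short", "Shortage"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %12s %12s %10s %12s\n", s$row[i],
                format(round(s$actual[i]), big.mark = ","),
                format(round(s$model[i]), big.mark = ","),
                ifelse(is.na(s$n_grantees_with_shortage[i]), "-",
                       s$n_grantees_with_shortage[i]),
                format(round(s$shortage[i]), big.mark = ",")))
  }
  cat(sprintf("  grantees short in any MH category: %d (%.0f%%)\n",
              x$n_short_any_mh, 100 * x$n_short_any_mh / x$n_grantees))
  cat(sprintf("  excess patients served by over-served grantees: MH %s, SA %s\n",
              format(round(x$excess_served_mh), big.mark = ","),
              format(round(x$excess_served_sa), big.mark = ",")))
  invisible(x)
}

known_state_codes <- function() {
  c(datasets::state.abb, "DC", "PR", "VI", "GU", "AS", "MP")
}

#' State-level shortage summary
#'
#' Groups per-grantee shortages by state: additional mental health and
#' substance abuse patients needing onsite care, and the FTE shortages by
#' provider category. States with fewer than `min_grantees` grantees are
#' suppressed from the displayed output (to avoid indirect identification
#' of individual grantees) but always included in national totals; set
#' `suppress = FALSE` to keep every state. Unknown state codes are grouped
#' under `"OTHER"` with a warning.
#'
#' @param estimates Output of [estimate_needs()].
#' @param cohort The matching grantee cohort.
#' @param min_grantees Minimum grantees per displayed state (default 3).
#' @param suppress Drop states below `min_grantees`? Default `TRUE`.
#' @return A tibble with one row per displayed state: `state`,
#'   `n_grantees`, `mh_patient_shortage`, `shortage_licensed`,
#'   `shortage_psychiatrist`, `shortage_other_staff`,
#'   `sa_patient_shortage`, `shortage_sa`.
#' @export
aggregate_by_state <- function(estimates, cohort, min_grantees = 3,
                               suppress = TRUE) {
  cohort <- validate_grantees(cohort)
  if (!setequal(estimates$grantee_id, cohort$grantee_id) ||
      nrow(estimates) != nrow(cohort)) {
    stop("estimates and cohort cover different grantees", call. = FALSE)
  }
  d <- dplyr::inner_join(estimates, cohort, by = "grantee_id")
  unknown <- !(d$state %in% known_state_codes())
  if (any(unknown)) {
    warning("unknown state code(s) ",
            paste(unique(d$state[unknown]), collapse = ", "),
            "; grouped under OTHER", call. = FALSE)
    d$state[unknown] <- "OTHER"
  }
  out <- d %>%
    dplyr::mutate(
      mh_patient_shortage = shortage(.data$target_mh_patients,
                                     .data$mh_patients),
      sa_patient_shortage = shortage(.data$target_sa_patients,
                                     .data$sa_patients)
    ) %>%
    dplyr::group_by(.data$state) %>%
    dplyr::summarise(
      n_grantees = dplyr::n(),
      mh_patient_shortage = sum(.data$mh_patient_shortage),
      shortage_licensed = sum(.data$shortage_licensed),
      shortage_psychiatrist = sum(.data$shortage_psychiatrist),
      shortage_other_staff = sum(.data$shortage_other_staff),
      sa_patient_shortage = sum(.data$sa_patient_shortage),
      shortage_sa = sum(.data$shortage_sa),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$state)
  if (suppress) {
    out <- dplyr::filter(out, .data$n_grantees >= min_grantees)
  }
  out
}

#' FTE per 2,500 medical patients
#'
#' The headline staffing ratio: total FTE scaled to a panel of 2,500
#' medical patients.
#'
#' @param fte_total Total FTE.
#' @param medical_patients_total Total medical patients; must be positive.
#' @return A list with the `raw` ratio and `rounded` (one decimal).
#' @export
#' @examples
#' per_2500_ratio(6260, 16777152)
per_2500_ratio <- function(fte_total, medical_patients_total) {
  if (!is.numeric(medical_patients_total) || medical_patients_total <= 0) {
    stop("medical patient total must be positive", call. = FALSE)
  }
  raw <- fte_total / medical_patients_total * 2500
  list(raw = raw, rounded = round(raw, 1))
}
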