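#' Mean public/uninsured patient share across grantees
#'
#' The unweighted (grantee-weighted) mean of each grantee's share of
#' 12-and-over medical patients in the public/uninsured stratum. Grantees
#' with no 12+ patients are excluded. A patient-weighted alternative
#' (program-level pooled share) is available via `weighted = TRUE`.
#'
#' @param cohort A grantee cohort.
#' @param weighted Use patient-weighted pooling instead of the
#'   grantee-weighted mean? Default `FALSE`.
#' @return A rate in `[0, 1]`.
#' @export
mean_public_share <- function(cohort, weighted = FALSE) {
  cohort <- validate_grantees(cohort)
  tot12 <- cohort$medical_patients_12plus_public +
    cohort$medical_patients_12plus_private
  keep <- tot12 > 0
  if (!any(keep)) {
    stop("no grantee has medical patients aged 12 and over", call. = FALSE)
  }
  if (weighted) {
    sum(cohort$medical_patients_12plus_public[keep]) / sum(tot12[keep])
  } else {
    mean(cohort$medical_patients_12plus_public[keep] / tot12[keep])
  }
}

#' Percent increase over a baseline, rounded half-up
#'
#' `(target - baseline) / baseline * 100`, rounded half-up to an integer
#' percent (reporting convention). A non-positive baseline yields `NA`
#' (undefined) rather than an error.
#'
#' @param target,baseline Numeric vectors.
#' @return Integer percents, `NA` where the baseline is not positive.
#' @export
#' @examples
#' percent_increase(5918248, 852984)  # 594
percent_increase <- function(target, baseline) {
  p <- (target - baseline) / baseline * 100
  p[!is.finite(p) | baseline <= 0] <- NA_real_
  # round half-up (not banker's rounding)
  ifelse(is.na(p), NA_real_, floor(p + 0.5))
}

#' Define an expansion scenario
#'
#' A scenario scales the health-center program to a total number of
#' medical patients (default 40 million), splits them into the
#' public/uninsured and Medicare/private strata by a mean public share,
#' applies prevalence to obtain target behavioral health populations, and
#' converts them to FTE need with a utilization-parameter set. The
#' baseline supplies the 2010-style actuals that "additional needed" and
#' percent increases are computed against.
#'
#' By default prevalence is applied to all projected medical patients
#' (blended-rate behavior); set `frac_age_12plus < 1` to first restrict to
#' patients aged 12 and over.
#'
#' @param total_medical_patients Projected program size (default 4e7).
#' @param mean_public_share Public/uninsured share in `[0, 1]`; typically
#'   [mean_public_share()] of a cohort.
#' @param prevalence A [prevalence_table()].
#' @param params A [utilization_parameters()] set.
#' @param baseline A `bh_national_summary` (e.g.
#'   [reference_summary_2010()] or [aggregate_national()] output).
#' @param baseline_medical_patients Baseline medical patient total; taken
#'   from `baseline$medical_patients_total` if present.
#' @param frac_age_12plus Fraction of projected patients aged 12+ to which
#'   prevalence applies (default 1: blended rates on the full total).
#' @return A `bh_scenario` list.
#' @export
expansion_scenario <- function(total_medical_patients = 4e7,
                               mean_public_share = 0.76,
                               prevalence = default_prevalence(),
                               params = reference_parameters_2010(),
                               baseline = reference_summary_2010(),
                               baseline_medical_patients = NULL,
                               frac_age_12plus = 1) {
  if (!is.numeric(total_medical_patients) || length(total_medical_patients) != 1 ||
      !is.finite(total_medical_patients) || total_medical_patients <= 0) {
    stop("`total_medical_patients` must be a single positive number",
         call. = FALSE)
  }
  for (nm in c("mean_public_share", "frac_age_12plus")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
      stop("`", nm, "` must be a rate in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(inherits(prevalence, "bh_prevalence"),
            inherits(params, "bh_utilization"),
            inherits(baseline, "bh_national_summary"))
  if (is.null(baseline_medical_patients)) {
    baseline_medical_patients <- baseline$medical_patients_total
  }
  if (is.null(baseline_medical_patients)) {
    stop("baseline carries no medical patient total; supply ",
         "`baseline_medical_patients`", call. = FALSE)
  }
  structure(list(
    total_medical_patients = total_medical_patients,
    mean_public_share = mean_public_share,
    prevalence = prevalence,
    params = params,
    baseline = baseline,
    baseline_medical_patients = baseline_medical_patients,
    frac_age_12plus = frac_age_12plus
  ), class = "bh_scenario")
}

#' Project behavioral health staffing need under an expansion scenario
#'
#' Splits the scenario's medical patients into the two insurance strata by
#' the mean public share, applies prevalence to obtain target mental
#' health and substance abuse populations, converts them to FTE need by
#' provider category with [fte_needed()], and reports each target next to
#' its baseline with the additional need and integer percent increase.
#'
#' @param scenario An [expansion_scenario()].
#' @return A `bh_projection` tibble with columns `row`, `target`,
#'   `baseline`, `additional`, `pct_increase`; rows `medical_patients`,
#'   `mh_patients`, `sa_patients`, `bh_fte`, `fte_licensed`,
#'   `fte_psychiatrist`, `fte_other_staff`, `fte_sa`.
#' @export
#' @examples
#' proj <- project_expansion(expansion_scenario())
#' proj[proj$row == "bh_fte", ]
project_expansion <- function(scenario) {
  stopifnot(inherits(scenario, "bh_scenario"))
  eligible <- scenario$total_medical_patients * scenario$frac_age_12plus
  pub <- eligible * scenario$mean_public_share
  priv <- eligible - pub
  targets <- target_patients(pub, priv, scenario$prevalence)
  need <- fte_needed(targets$target_mh_patients, targets$target_sa_patients,
                     scenario$params)
  fte_total <- need$fte_needed_licensed + need$fte_needed_psychiatrist +
    need$fte_needed_other_staff + need$fte_needed_sa

  base <- scenario$baseline$summary
  base_actual <- function(row) base$actual[base$row == row]
  out <- tibble::tibble(
    row = c("medical_patients", "mh_patients", "sa_patients", "bh_fte",
            "fte_licensed", "fte_psychiatrist", "fte_other_staff", "fte_sa"),
    target = c(scenario$total_medical_patients,
               targets$target_mh_patients, targets$target_sa_patients,
               fte_total, need$fte_needed_licensed,
               need$fte_needed_psychiatrist, need$fte_needed_other_staff,
               need$fte_needed_sa),
    baseline = c(scenario$baseline_medical_patients,
                 base_actual("mh_patients"), base_actual("sa_patients"),
                 base_actual("bh_fte"), base_actual("fte_licensed"),
                 base_actual("fte_psychiatrist"),
                 base_actual("fte_other_staff"), base_actual("fte_sa"))
  )
  out$additional <- out$target - out$baseline
  out$pct_increase <- percent_increase(out$target, out$baseline)
  class(out) <- c("bh_projection", class(out))
  out
}

#' Reuse a projection's targets as a scenario baseline
#'
#' Wraps a [project_expansion()] result into the summary layout
#' [expansion_scenario()] accepts as a baseline, with the projection's
#' targets as the actuals. Projecting the same scenario against this
#' baseline yields zero additional need in every row (the model's fixed
#' point).
#'
#' @param projection A `bh_projection`.
#' @param n_grantees Grantee count to record (informational).
#' @return A `bh_national_summary`.
#' @export
projection_as_baseline <- function(projection, n_grantees = NA_integer_) {
  stopifnot(inherits(projection, "bh_projection"))
  rows <- setdiff(projection$row, "medical_patients")
  summary <- tibble::tibble(
    row = rows,
    actual = projection$target[match(rows, projection$row)],
    model = projection$target[match(rows, projection$row)],
    n_grantees_with_shortage = NA_integer_,
    shortage = 0
  )
  structure(list(
    summary = summary,
    n_grantees = n_grantees,
    n_short_any_mh = NA_integer_,
    n_short_sa = NA_integer_,
    excess_served_mh = 0,
    excess_served_sa = 0,
    medical_patients_total =
      projection$target[projection$row == "medical_patients"]
  ), class = "bh_national_summary")
}
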