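fmt_big <- function(x) format(round(x), big.mark = ",", scientific = FALSE,
                              trim = TRUE)

write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_params <- function(path) {
  assemble_parameters(file = path)
}

# Table renderers: CSVs carry raw numbers (no separators); the text
# rendering rounds counts/FTE to integers, ratios to one decimal and
# percent increases to integer percents, with thousands separators.
render_utilization_text <- function(params) {
  utils::capture.output(print(params))
}

render_national_text <- function(summary) {
  utils::capture.output(print(summary))
}

render_projection_text <- function(projection) {
  lines <- c("Expansion projection",
             sprintf("  %-18s %14s %14s  %s", "", "Target",
                     "Additional", "(% increase)"))
  for (i in seq_len(nrow(projection))) {
    pct <- projection$pct_increase[i]
    lines <- c(lines, sprintf(
      "  %-18s %14s %14s  (%s)", projection$row[i],
      fmt_big(projection$target[i]), fmt_big(projection$additional[i]),
      ifelse(is.na(pct), "n/a", paste0(pct, "%"))))
  }
  lines
}

national_summary_csv <- function(summary) {
  summary$summary
}

#' Headline numbers for a national analysis
#'
#' The quantities a program planner quotes first: total behavioral health
#' FTE needed, FTE per 2,500 medical patients by category, and the
#' percentage of grantees unable to fully meet onsite mental health or
#' substance abuse need.
#'
#' @param summary A `bh_national_summary` from [aggregate_national()].
#' @param medical_patients_total Total medical patients across the cohort.
#' @return A named list, suitable for JSON serialization.
#' @export
headline_numbers <- function(summary, medical_patients_total) {
  s <- summary$summary
  model <- function(row) s$model[s$row == row]
  list(
    total_bh_fte_needed = model("bh_fte"),
    total_bh_fte_shortage = s$shortage[s$row == "bh_fte"],
    per_2500 = list(
      licensed = per_2500_ratio(model("fte_licensed"),
                                medical_patients_total)$rounded,
      psychiatrist = per_2500_ratio(model("fte_psychiatrist"),
                                    medical_patients_total)$rounded,
      other_staff = per_2500_ratio(model("fte_other_staff"),
                                   medical_patients_total)$rounded,
      substance_abuse = per_2500_ratio(model("fte_sa"),
                                       medical_patients_total)$rounded
    ),
    pct_grantees_short_mh = round(100 * summary$n_short_any_mh /
                                    summary$n_grantees),
    pct_grantees_short_sa = round(100 * summary$n_short_sa /
                                    summary$n_grantees)
  )
}

#' Run the full estimation pipeline
#'
#' simulate (or read) a grantee cohort, estimate utilization parameters,
#' run the per-grantee needs model, aggregate nationally and by state,
#' project the expansion scenario, and write every table plus a headline
#' JSON and a reproducibility manifest to `out_dir`. Deterministic under a
#' fixed config seed: re-running with the same configuration reproduces
#' every numeric output.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [cohort_config()] used when `cohort` is `NULL`.
#' @param cohort Optional pre-built grantee cohort (e.g. from
#'   [read_grantees()]); exactly one of `cohort`/`config` drives the run.
#' @param prevalence A [prevalence_table()].
#' @param params Optional [utilization_parameters()]; estimated from the
#'   cohort when `NULL`.
#' @param scenario_total Projected medical patients for the expansion
#'   scenario.
#' @return Invisibly, a list with the cohort, parameters, estimates,
#'   national and state summaries, projection, and headline numbers.
#' @export
run_pipeline <- function(out_dir,
                         config = cohort_config(),
                         cohort = NULL,
                         prevalence = default_prevalence(),
                         params = NULL,
                         scenario_total = 4e7) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    cohort <- generate_grantees(config)
    seed_used <- config$seed
  } else {
    cohort <- validate_grantees(cohort)
    seed_used <- NA
  }
  write_grantees(cohort, file.path(out_dir, "grantees.csv"))

  if (is.null(params)) {
    params <- assemble_parameters(cohort)
  }
  write_params(params, file.path(out_dir, "utilization.json"))

  estimates <- estimate_needs(cohort, prevalence, params)
  readr::write_csv(estimates, file.path(out_dir, "needs.csv"),
                   progress = FALSE)

  national <- aggregate_national(estimates, cohort)
  readr::write_csv(national_summary_csv(national),
                   file.path(out_dir, "national.csv"), progress = FALSE)
  by_state <- aggregate_by_state(estimates, cohort)
  readr::write_csv(by_state, file.path(out_dir, "state.csv"),
                   progress = FALSE)

  medical_total <- sum(cohort$medical_patients)
  national$medical_patients_total <- medical_total
  scenario <- expansion_scenario(
    total_medical_patients = scenario_total,
    mean_public_share = mean_public_share(cohort),
    prevalence = prevalence, params = params, baseline = national
  )
  projection <- project_expansion(scenario)
  readr::write_csv(projection, file.path(out_dir, "projection.csv"),
                   progress = FALSE)

  headline <- headline_numbers(national, medical_total)
  jsonlite::write_json(headline, file.path(out_dir, "headline.json"),
                       auto_unbox = TRUE, digits = NA)

  writeLines(c(render_utilization_text(params), "",
               render_national_text(national), "",
               render_projection_text(projection)),
             file.path(out_dir, "report.txt"))

  config_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                  digits = NA)
  cfg_file <- tempfile(fileext = ".json")
  writeLines(config_json, cfg_file)
  manifest <- list(
    seed = seed_used,
    n_grantees = nrow(cohort),
    config = jsonlite::fromJSON(config_json),
    config_hash = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("bhworkforce")),
    r_version = as.character(getRversion())
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, params = params, estimates = estimates,
                 national = national, by_state = by_state,
                 projection = projection, headline = headline))
}
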