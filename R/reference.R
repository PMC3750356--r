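#' Published 2010 national summary
#'
#' The published national 2010 figures for the health-center program, in
#' the same layout [aggregate_national()] produces: actual served
#' patients and employed FTE from the 2010 UDS, the needs model's results,
#' the number of grantees with a shortage, and the shortage sums with
#' per-grantee flooring. These are reporting-level (rounded) values; they
#' serve as the baseline for expansion projections and for
#' consistency checks of printed-table arithmetic.
#'
#' 2010 program totals: 16,777,152 medical patients across 1,124 grantees.
#'
#' @return A `bh_national_summary` with an additional
#'   `medical_patients_total` field.
#' @export
reference_summary_2010 <- function() {
  summary <- tibble::tribble(
    ~row,               ~actual,  ~model,    ~n_grantees_with_shortage, ~shortage,
    "mh_patients",      852984,   2512224,   1012L,                     1770027,
    "sa_patients",      98760,    357632,    1002L,                     302613,
    "bh_fte",           5094,     11699,     NA_integer_,               8777,
    "fte_licensed",     2582,     6260,      936L,                      4328,
    "fte_psychiatrist", 394,      982,       998L,                      748,
    "fte_other_staff",  1264,     2407,      997L,                      1916,
    "fte_sa",           854,      2050,      998L,                      1785
  )
  mh <- summary[summary$row == "mh_patients", ]
  sa <- summary[summary$row == "sa_patients", ]
  structure(list(
    summary = summary,
    n_grantees = 1124L,
    n_short_any_mh = 1012L,
    n_short_sa = 1002L,
    excess_served_mh = mh$shortage - (mh$model - mh$actual),
    excess_served_sa = sa$shortage - (sa$model - sa$actual),
    medical_patients_total = 16777152
  ), class = "bh_national_summary")
}
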