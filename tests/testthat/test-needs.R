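test_that("target populations apply stratified prevalence exactly", {
  # single-stratum product
  t1 <- target_patients(10000, 0, prevalence_table(0.20, 0.10, 0.02, 0.01))
  expect_equal(t1$target_mh_patients, 2000)
  # zero prevalence annihilates
  t0 <- target_patients(7600, 2400, prevalence_table(0, 0, 0, 0))
  expect_equal(unlist(t0), c(target_mh_patients = 0, target_sa_patients = 0))
  # mixed strata with the default rates: 7600*0.17 + 2400*0.08 = 1484
  t2 <- target_patients(7600, 2400, default_prevalence())
  expect_equal(t2$target_mh_patients, 1484)
  expect_equal(t2$target_sa_patients, 7600 * 0.024 + 2400 * 0.012)
})

test_that("FTE conversion is linear and reproduces published-scale arithmetic", {
  p <- ref_params()
  need <- fte_needed(5918248, 841182, p)
  expect_equal(round(need$fte_needed_sa), 4821)
  expect_equal(need$fte_needed_licensed, 14748, tolerance = 0.001)
  # zero targets annihilate
  z <- fte_needed(0, 0, p)
  expect_true(all(unlist(z) == 0))
  # homogeneity: doubling targets doubles everything
  twice <- fte_needed(2 * 5918248, 2 * 841182, p)
  expect_equal(unlist(twice), 2 * unlist(need), tolerance = 1e-12)
})

test_that("the three MH visit streams sum back to total MH visits", {
  p <- ref_params()
  for (target in c(1, 1484, 5918248)) {
    need <- fte_needed(target, 0, p)
    expect_equal(need$visits_needed_licensed + need$visits_needed_psychiatrist +
                   need$visits_needed_other_staff,
                 need$mh_visits_needed, tolerance = 1e-6 * need$mh_visits_needed)
  }
})

test_that("shortages floor at zero and never offset across grantees", {
  expect_equal(shortage(10, 12), 0)
  expect_equal(shortage(c(5, 0), c(0, 5)), c(5, 0))
  expect_equal(sum(shortage(c(5, 0), c(0, 5))), 5)
})

test_that("per-grantee estimates match a spreadsheet-style recomputation", {
  co <- dplyr::bind_rows(
    make_grantee("G1", pub12 = 7600, priv12 = 2400),
    make_grantee("G2", pub12 = 1000, priv12 = 9000, fte_licensed = 50),
    make_offsite_grantee("G3"))
  prev <- default_prevalence()
  p <- ref_params()
  est <- estimate_needs(co, prev, p)

  # straight-line recomputation, one grantee at a time
  for (i in seq_len(nrow(co))) {
    mh <- co$medical_patients_12plus_public[i] * 0.17 +
      co$medical_patients_12plus_private[i] * 0.08
    sa <- co$medical_patients_12plus_public[i] * 0.024 +
      co$medical_patients_12plus_private[i] * 0.012
    visits <- mh * 3.7
    expect_equal(est$target_mh_patients[i], mh)
    expect_equal(est$mh_visits_needed[i], visits)
    expect_equal(est$fte_needed_licensed[i], visits * 0.599 / 889)
    expect_equal(est$fte_needed_psychiatrist[i], visits * 0.233 / 2210)
    expect_equal(est$fte_needed_other_staff[i], visits * 0.168 / 648)
    expect_equal(est$fte_needed_sa[i], sa * 5.8 / 1012)
    expect_equal(est$shortage_licensed[i],
                 max(0, visits * 0.599 / 889 - co$fte_licensed_mh[i]))
  }
  # the over-staffed grantee (50 licensed FTE) has zero licensed shortage
  expect_equal(est$shortage_licensed[2], 0)
  # offsite grantees still get need estimated
  expect_gt(est$fte_needed_licensed[3], 0)
})

test_that("needs scale linearly with 12+ patient counts", {
  co <- random_cohort(40, seed = 44)
  prev <- default_prevalence()
  p <- ref_params()
  est1 <- estimate_needs(co, prev, p)
  co2 <- dplyr::mutate(
    co,
    medical_patients = medical_patients * 2,
    medical_patients_12plus_public = medical_patients_12plus_public * 2,
    medical_patients_12plus_private = medical_patients_12plus_private * 2)
  est2 <- estimate_needs(co2, prev, p)
  for (col in c("target_mh_patients", "target_sa_patients",
                "mh_visits_needed", "fte_needed_licensed", "fte_needed_sa")) {
    expect_equal(est2[[col]], 2 * est1[[col]], tolerance = 1e-12)
  }
})

test_that("national aggregation floors dominate the aggregate difference", {
  for (seed in c(6, 60)) {
    co <- random_cohort(30, seed)
    est <- estimate_needs(co, default_prevalence(), ref_params())
    nat <- aggregate_national(est, co)
    s <- nat$summary
    for (i in seq_len(nrow(s))) {
      expect_gte(s$shortage[i] + 1e-9, max(0, s$model[i] - s$actual[i]))
    }
    # brute-force oracle: recompute category shortages grantee by grantee
    d <- dplyr::inner_join(est, co, by = "grantee_id")
    expect_equal(s$shortage[s$row == "fte_licensed"],
                 sum(pmax(0, d$fte_needed_licensed - d$fte_licensed_mh)))
    expect_equal(s$shortage[s$row == "fte_sa"],
                 sum(pmax(0, d$fte_needed_sa - d$fte_substance_abuse)))
    # excess-served identity
    mh <- s[s$row == "mh_patients", ]
    expect_equal(nat$excess_served_mh, mh$shortage - (mh$model - mh$actual))
    expect_gte(nat$excess_served_mh, -1e-9)
  }
})

test_that("the shortage identity recovers excess patients served from totals", {
  ref <- reference_summary_2010()
  expect_equal(ref$excess_served_mh, 110787)
  expect_equal(ref$excess_served_sa, 43741)
})

test_that("every-grantee-covered cohorts report zero shortage", {
  co <- dplyr::bind_rows(
    make_grantee("G1", fte_licensed = 100, fte_psychiatrist = 100,
                 fte_other = 100, fte_sa = 100,
                 mh_patients = 5000, sa_patients = 1000),
    make_grantee("G2", fte_licensed = 100, fte_psychiatrist = 100,
                 fte_other = 100, fte_sa = 100,
                 mh_patients = 5000, sa_patients = 1000))
  est <- estimate_needs(co, default_prevalence(), ref_params())
  nat <- aggregate_national(est, co)
  fte_rows <- nat$summary[nat$summary$row %in%
                            c("fte_licensed", "fte_psychiatrist",
                              "fte_other_staff", "fte_sa"), ]
  expect_true(all(fte_rows$shortage == 0))
  expect_true(all(fte_rows$n_grantees_with_shortage == 0))
  expect_equal(nat$n_short_any_mh, 0L)
})

test_that("mismatched estimate and cohort ids are rejected", {
  co <- random_cohort(5, seed = 1)
  est <- estimate_needs(co, default_prevalence(), ref_params())
  expect_error(aggregate_national(est[-1, ], co), "different grantees")
})

test_that("state aggregation suppresses small states but conserves totals", {
  co <- dplyr::bind_rows(
    make_grantee("G1", state = "CO"), make_grantee("G2", state = "CO"),
    make_grantee("G3", state = "CO"), make_grantee("G4", state = "WY"),
    make_grantee("G5", state = "WY"))
  est <- estimate_needs(co, default_prevalence(), ref_params())
  shown <- aggregate_by_state(est, co)
  expect_identical(shown$state, "CO")
  all_states <- aggregate_by_state(est, co, suppress = FALSE)
  expect_setequal(all_states$state, c("CO", "WY"))
  nat <- aggregate_national(est, co)
  expect_equal(sum(all_states$shortage_licensed),
               nat$summary$shortage[nat$summary$row == "fte_licensed"])
  expect_equal(sum(all_states$mh_patient_shortage),
               nat$summary$shortage[nat$summary$row == "mh_patients"])
})

test_that("a single-state cohort reproduces the national totals", {
  co <- random_cohort(12, seed = 9)
  co$state <- "NM"
  est <- estimate_needs(co, default_prevalence(), ref_params())
  row <- aggregate_by_state(est, co)
  nat <- aggregate_national(est, co)
  expect_identical(nrow(row), 1L)
  expect_equal(row$shortage_sa,
               nat$summary$shortage[nat$summary$row == "fte_sa"])
})

test_that("unknown state codes are grouped under OTHER with a warning", {
  co <- dplyr::bind_rows(make_grantee("G1", state = "ZZ"),
                         make_grantee("G2", state = "CO"))
  est <- estimate_needs(co, default_prevalence(), ref_params())
  expect_warning(out <- aggregate_by_state(est, co, suppress = FALSE), "ZZ")
  expect_true("OTHER" %in% out$state)
})

test_that("the per-2,500 staffing ratio matches the published headline", {
  r <- per_2500_ratio(6260, 16777152)
  expect_equal(r$raw, 6260 / 16777152 * 2500)
  expect_equal(r$rounded, 0.9)
  expect_equal(per_2500_ratio(2050, 16777152)$rounded, 0.3)
  expect_equal(per_2500_ratio(0, 100)$rounded, 0)
  expect_error(per_2500_ratio(10, 0), "positive")
})
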