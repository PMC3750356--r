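test_that("visits-per-patient median follows the sort-based convention", {
  # odd count: middle order statistic
  expect_equal(median_visits_per_mh_patient(
    cohort_with_mh_ratios(c(2.0, 3.7, 10.0))), 3.7)
  # even count: average of the two middle order statistics
  expect_equal(median_visits_per_mh_patient(
    cohort_with_mh_ratios(c(1, 2, 4, 8))), 3.0)
})

test_that("grantees without onsite MH staff or patients are excluded from the ratio", {
  co <- dplyr::bind_rows(
    cohort_with_mh_ratios(c(2.0, 3.7, 10.0)),
    make_offsite_grantee("G9"),
    # SA-only grantee: has BH staff but no MH staff, so excluded from the
    # MH visits-per-patient statistic
    make_grantee("G10", mh_patients = 100, enc_licensed = 0,
                 enc_psychiatrist = 0, enc_other = 0,
                 fte_licensed = 0, fte_psychiatrist = 0, fte_other = 0,
                 fte_sa = 1, sa_patients = 50, sa_encounters = 300)
  )
  expect_equal(median_visits_per_mh_patient(co), 3.7)
  expect_error(median_visits_per_mh_patient(
    dplyr::bind_rows(make_offsite_grantee("G1"))), "no onsite")
})

test_that("visit shares are pooled across grantees, not averaged", {
  one <- make_grantee("G1", enc_licensed = 599, enc_psychiatrist = 233,
                      enc_other = 168)
  expect_equal(unname(visit_shares_by_provider(one)),
               c(0.599, 0.233, 0.168))
  two <- dplyr::bind_rows(
    make_grantee("G1", enc_licensed = 100, enc_psychiatrist = 0,
                 enc_other = 0),
    make_grantee("G2", enc_licensed = 0, enc_psychiatrist = 100,
                 enc_other = 0))
  expect_equal(unname(visit_shares_by_provider(two)), c(0.5, 0.5, 0))
})

test_that("visit shares sum to one and are scale invariant", {
  co <- random_cohort(120, seed = 31)
  s <- visit_shares_by_provider(co)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  scaled <- co
  for (col in c("mh_encounters_licensed", "mh_encounters_psychiatrist",
                "mh_encounters_other_staff")) {
    scaled[[col]] <- scaled[[col]] * 7
  }
  expect_equal(visit_shares_by_provider(scaled), s, tolerance = 1e-12)
})

test_that("visit loads are per-grantee medians excluding zero-FTE grantees", {
  one <- make_grantee("G1", enc_psychiatrist = 2210, fte_psychiatrist = 1.0)
  expect_equal(median_visit_load(one, "psychiatrist"), 2210)

  co <- dplyr::bind_rows(
    make_grantee("G1", enc_other = 500, fte_other = 1),
    make_grantee("G2", enc_other = 648, fte_other = 1),
    make_grantee("G3", enc_other = 900, fte_other = 1),
    # zero FTE in the category: excluded, not counted as load 0
    make_grantee("G4", enc_other = 0, fte_other = 0))
  expect_equal(median_visit_load(co, "other_staff"), 648)
  expect_error(median_visit_load(co, "typo"), "unknown provider category")
  no_sa <- make_grantee("G1", fte_sa = 0, sa_encounters = 0)
  expect_error(median_visit_load(no_sa, "substance_abuse"), "substance_abuse")
})

test_that("medians are invariant to permutation and cohort duplication", {
  co <- random_cohort(51, seed = 13)
  perm <- co[sample(nrow(co)), ]
  doubled <- dplyr::bind_rows(co, dplyr::mutate(
    co, grantee_id = paste0(grantee_id, "b")))
  for (f in list(median_visits_per_mh_patient, median_visits_per_sa_patient,
                 function(x) median_visit_load(x, "licensed"))) {
    expect_equal(f(perm), f(co))
    expect_equal(f(doubled), f(co))
  }
})

test_that("medians match the brute-force oracle on small cohorts", {
  for (seed in 1:4) {
    co <- random_cohort(10, seed)
    elig <- (co$fte_licensed_mh + co$fte_psychiatrist +
               co$fte_other_mh_staff) > 0 & co$mh_patients > 0
    if (any(elig)) {
      ratios <- (co$mh_encounters_licensed + co$mh_encounters_psychiatrist +
                   co$mh_encounters_other_staff)[elig] / co$mh_patients[elig]
      expect_identical(median_visits_per_mh_patient(co),
                       median_oracle(ratios))
    }
    elig_l <- co$fte_licensed_mh > 0
    if (any(elig_l)) {
      expect_identical(
        median_visit_load(co, "licensed"),
        median_oracle(co$mh_encounters_licensed[elig_l] /
                        co$fte_licensed_mh[elig_l]))
    }
  }
})

test_that("a literal parameter file is echoed exactly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    median_visits_per_mh_patient = 3.7,
    share_licensed = 0.599, share_psychiatrist = 0.233,
    share_other_staff = 0.168,
    median_visits_per_licensed_fte = 889,
    median_visits_per_psychiatrist_fte = 2210,
    median_visits_per_other_staff_fte = 648,
    median_visits_per_sa_patient = 5.8,
    median_visits_per_sa_fte = 1012
  ), path)
  p <- assemble_parameters(file = path)
  expect_equal(p, ref_params(), tolerance = 1e-12)
  readr::write_lines(
    "median_visits_per_mh_patient: 3.7", path)
  expect_error(assemble_parameters(file = path), "missing field")
})

test_that("shares given in percent are normalized to fractions", {
  expect_message(
    p <- utilization_parameters(3.7, 59.9, 23.3, 16.8, 889, 2210, 648,
                                5.8, 1012),
    "percent")
  expect_equal(p$share_licensed + p$share_psychiatrist + p$share_other_staff,
               1, tolerance = 1e-12)
  expect_equal(p$share_licensed, 0.599, tolerance = 1e-9)
})

test_that("a single fully-specified grantee yields its own ratios", {
  one <- make_grantee("G1", mh_patients = 500, enc_licensed = 1200,
                      enc_psychiatrist = 400, enc_other = 250,
                      sa_patients = 100, sa_encounters = 580,
                      fte_licensed = 1.5, fte_psychiatrist = 0.2,
                      fte_other = 0.4, fte_sa = 0.6)
  p <- assemble_parameters(one)
  expect_equal(p$median_visits_per_mh_patient, 1850 / 500)
  expect_equal(p$share_licensed, 1200 / 1850)
  expect_equal(p$median_visits_per_licensed_fte, 1200 / 1.5)
  expect_equal(p$median_visits_per_psychiatrist_fte, 400 / 0.2)
  expect_equal(p$median_visits_per_sa_patient, 5.8)
  expect_equal(p$median_visits_per_sa_fte, 580 / 0.6)
})
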