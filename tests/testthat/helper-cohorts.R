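# Hand-built grantee records for exact, spreadsheet-checkable cases.
make_grantee <- function(id = "G1", state = "CO",
                         medical = 10000, pub12 = 7600, priv12 = 2400,
                         mh_patients = 500,
                         enc_licensed = 1200, enc_psychiatrist = 400,
                         enc_other = 250,
                         sa_patients = 100, sa_encounters = 580,
                         fte_licensed = 1.5, fte_psychiatrist = 0.2,
                         fte_other = 0.4, fte_sa = 0.6) {
  tibble::tibble(
    grantee_id = id, state = state,
    medical_patients = medical,
    medical_patients_12plus_public = pub12,
    medical_patients_12plus_private = priv12,
    mh_patients = mh_patients,
    mh_encounters_licensed = enc_licensed,
    mh_encounters_psychiatrist = enc_psychiatrist,
    mh_encounters_other_staff = enc_other,
    sa_patients = sa_patients,
    sa_encounters = sa_encounters,
    fte_licensed_mh = fte_licensed,
    fte_psychiatrist = fte_psychiatrist,
    fte_other_mh_staff = fte_other,
    fte_substance_abuse = fte_sa
  )
}

# A grantee with no onsite behavioral health services at all.
make_offsite_grantee <- function(id = "G0", state = "CO",
                                 medical = 5000, pub12 = 3800, priv12 = 450) {
  make_grantee(id = id, state = state, medical = medical,
               pub12 = pub12, priv12 = priv12,
               mh_patients = 0, enc_licensed = 0, enc_psychiatrist = 0,
               enc_other = 0, sa_patients = 0, sa_encounters = 0,
               fte_licensed = 0, fte_psychiatrist = 0, fte_other = 0,
               fte_sa = 0)
}

# A cohort whose per-grantee MH visit ratios are exactly `ratios`.
cohort_with_mh_ratios <- function(ratios) {
  dplyr::bind_rows(lapply(seq_along(ratios), function(i) {
    make_grantee(id = paste0("G", i), mh_patients = 100,
                 enc_licensed = 100 * ratios[i], enc_psychiatrist = 0,
                 enc_other = 0)
  }))
}

# Small randomized cohorts for property-style tests.
random_cohort <- function(n, seed) {
  generate_grantees(cohort_config(n_grantees = n, seed = seed))
}

# Brute-force median oracle: sort, take middle (average middle pair if even).
median_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

ref_params <- function() reference_parameters_2010()
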