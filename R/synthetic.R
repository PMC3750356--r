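#' Configuration for the synthetic grantee-cohort generator
#'
#' Describes a UDS-style national cohort of health-center grantees: how many
#' grantees, how large they are, their insurance mix, what fraction staff
#' behavioral health onsite, and the utilization targets (median visit rates
#' and visit loads) the generated cohort should recover. Defaults emulate
#' the 2010 health-center program: 1,124 grantees, right-skewed grantee
#' sizes, ~76% of patients public/uninsured, ~74% of grantees with onsite
#' behavioral health staff, and the published 2010 utilization medians.
#'
#' @param n_grantees Number of grantees to simulate.
#' @param seed Integer seed; identical config gives byte-identical cohorts.
#' @param frac_with_onsite_bh Expected fraction of grantees with onsite
#'   behavioral health staff.
#' @param mean_medical_patients Mean medical patients per grantee.
#' @param patient_size_dispersion Log-scale SD of the log-normal grantee
#'   size distribution.
#' @param public_share_mean,public_share_concentration Mean and
#'   concentration of the Beta distribution of each grantee's
#'   public/uninsured patient share.
#' @param target_median_visits_per_mh_patient Target median annual mental
#'   health visits per mental health patient.
#' @param target_visit_shares Length-3 vector (licensed, psychiatrist,
#'   other staff) of pooled visit shares; must sum to 1.
#' @param target_median_visit_loads Length-3 vector of target median annual
#'   visits per FTE for the three mental health provider categories.
#' @param target_median_visits_per_sa_patient Target median annual substance
#'   abuse visits per substance abuse patient.
#' @param target_median_sa_visit_load Target median annual visits per
#'   substance abuse provider FTE.
#' @param frac_age_12plus Fraction of medical patients aged 12 and over.
#' @param mh_patient_share_mean,sa_patient_share_mean Mean fraction of a
#'   grantee's medical patients seen for mental health / substance abuse
#'   (onsite grantees only).
#' @param ratio_dispersion Log-scale SD of per-grantee visits-per-patient
#'   ratios.
#' @param load_dispersion Log-scale SD of per-grantee visit loads.
#' @param share_concentration Dirichlet concentration for per-grantee visit
#'   shares around `target_visit_shares`.
#' @return A validated `bh_cohort_config` list.
#' @export
cohort_config <- function(n_grantees = 1124,
                          seed = 20100L,
                          frac_with_onsite_bh = 0.74,
                          mean_medical_patients = 14900,
                          patient_size_dispersion = 1.1,
                          public_share_mean = 0.76,
                          public_share_concentration = 25,
                          target_median_visits_per_mh_patient = 3.7,
                          target_visit_shares = c(licensed = 0.599,
                                                  psychiatrist = 0.233,
                                                  other_staff = 0.168),
                          target_median_visit_loads = c(licensed = 889,
                                                        psychiatrist = 2210,
                                                        other_staff = 648),
                          target_median_visits_per_sa_patient = 5.8,
                          target_median_sa_visit_load = 1012,
                          frac_age_12plus = 0.85,
                          mh_patient_share_mean = 0.07,
                          sa_patient_share_mean = 0.012,
                          ratio_dispersion = 0.5,
                          load_dispersion = 0.6,
                          share_concentration = 200) {
  cfg <- list(
    n_grantees = n_grantees, seed = seed,
    frac_with_onsite_bh = frac_with_onsite_bh,
    mean_medical_patients = mean_medical_patients,
    patient_size_dispersion = patient_size_dispersion,
    public_share_mean = public_share_mean,
    public_share_concentration = public_share_concentration,
    target_median_visits_per_mh_patient = target_median_visits_per_mh_patient,
    target_visit_shares = target_visit_shares,
    target_median_visit_loads = target_median_visit_loads,
    target_median_visits_per_sa_patient = target_median_visits_per_sa_patient,
    target_median_sa_visit_load = target_median_sa_visit_load,
    frac_age_12plus = frac_age_12plus,
    mh_patient_share_mean = mh_patient_share_mean,
    sa_patient_share_mean = sa_patient_share_mean,
    ratio_dispersion = ratio_dispersion,
    load_dispersion = load_dispersion,
    share_concentration = share_concentration
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  check_pos_scalar <- function(x, nm, allow_zero = FALSE) {
    ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
      (x > 0 || (allow_zero && x >= 0))
    if (!ok) stop("invalid `", nm, "`: must be a finite positive number",
                  call. = FALSE)
  }
  check_rate <- function(x, nm) {
    ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
    if (!ok) stop("invalid `", nm, "`: must be a rate in [0, 1]",
                  call. = FALSE)
  }
  if (!is.numeric(cfg$n_grantees) || length(cfg$n_grantees) != 1 ||
      !is.finite(cfg$n_grantees) || cfg$n_grantees < 1 ||
      cfg$n_grantees != round(cfg$n_grantees)) {
    stop("invalid `n_grantees`: must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed)) {
    stop("invalid `seed`: must be a single integer", call. = FALSE)
  }
  check_rate(cfg$frac_with_onsite_bh, "frac_with_onsite_bh")
  check_rate(cfg$public_share_mean, "public_share_mean")
  check_rate(cfg$frac_age_12plus, "frac_age_12plus")
  check_rate(cfg$mh_patient_share_mean, "mh_patient_share_mean")
  check_rate(cfg$sa_patient_share_mean, "sa_patient_share_mean")
  check_pos_scalar(cfg$mean_medical_patients, "mean_medical_patients")
  check_pos_scalar(cfg$patient_size_dispersion, "patient_size_dispersion")
  check_pos_scalar(cfg$public_share_concentration, "public_share_concentration")
  check_pos_scalar(cfg$target_median_visits_per_mh_patient,
                   "target_median_visits_per_mh_patient")
  check_pos_scalar(cfg$target_median_visits_per_sa_patient,
                   "target_median_visits_per_sa_patient")
  check_pos_scalar(cfg$target_median_sa_visit_load,
                   "target_median_sa_visit_load")
  check_pos_scalar(cfg$ratio_dispersion, "ratio_dispersion")
  check_pos_scalar(cfg$load_dispersion, "load_dispersion")
  check_pos_scalar(cfg$share_concentration, "share_concentration")
  shares <- cfg$target_visit_shares
  if (!is.numeric(shares) || length(shares) != 3 || any(!is.finite(shares)) ||
      any(shares < 0) || abs(sum(shares) - 1) > 1e-9) {
    stop("invalid `target_visit_shares`: three non-negative values summing ",
         "to 1", call. = FALSE)
  }
  loads <- cfg$target_median_visit_loads
  if (!is.numeric(loads) || length(loads) != 3 || any(!is.finite(loads)) ||
      any(loads <= 0)) {
    stop("invalid `target_median_visit_loads`: three positive values",
         call. = FALSE)
  }
  structure(cfg, class = "bh_cohort_config")
}

# Log-normal draws whose empirical median equals `target` exactly: the
# standard normal draws are recentred on their sample median before
# exponentiating, i.e. the log-scale location parameter is set from the
# sample itself. Keeps the right skew while making the median a controlled
# calibration quantity rather than a noisy one.
rlnorm_median <- function(n, target, sdlog) {
  z <- stats::rnorm(n)
  target * exp(sdlog * (z - stats::median(z)))
}

rbeta_mean <- function(n, mean, concentration) {
  stats::rbeta(n, shape1 = mean * concentration,
               shape2 = (1 - mean) * concentration)
}

# Dirichlet via independent gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Generate a synthetic UDS-style grantee cohort
#'
#' Simulates a national cohort of health-center grantees with the
#' statistical structure the staffing model assumes: log-normal
#' (right-skewed) grantee sizes and utilization ratios, Beta-distributed
#' public/uninsured insurance shares, and a configurable fraction of
#' grantees with onsite behavioral health staff. Per-grantee encounter
#' counts are derived as patients times a per-grantee visit ratio, and FTE
#' as encounters divided by a per-grantee visit load, so the cohort's
#' median utilization statistics recover the configured targets.
#'
#' Grantees without onsite staff still carry medical patients and an
#' insurance mix: they enter needs estimation but contribute nothing to
#' utilization statistics.
#'
#' @param config A [cohort_config()].
#' @return A validated tibble with one row per grantee and columns
#'   `grantee_id`, `state`, `medical_patients`,
#'   `medical_patients_12plus_public`, `medical_patients_12plus_private`,
#'   `mh_patients`, `mh_encounters_licensed`, `mh_encounters_psychiatrist`,
#'   `mh_encounters_other_staff`, `sa_patients`, `sa_encounters`,
#'   `fte_licensed_mh`, `fte_psychiatrist`, `fte_other_mh_staff`,
#'   `fte_substance_abuse`.
#' @export
#' @examples
#' cohort <- generate_grantees(cohort_config(n_grantees = 50, seed = 1))
#' nrow(cohort)
generate_grantees <- function(config = cohort_config()) {
  cfg <- validate_cohort_config(config)
  n <- cfg$n_grantees
  withr::with_seed(cfg$seed, {
    # grantee sizes: log-normal with the configured arithmetic mean
    sdlog <- cfg$patient_size_dispersion
    meanlog <- log(cfg$mean_medical_patients) - sdlog^2 / 2
    medical <- pmax(100, round(stats::rlnorm(n, meanlog, sdlog)))

    share_pub <- rbeta_mean(n, cfg$public_share_mean,
                            cfg$public_share_concentration)
    n12 <- round(medical * cfg$frac_age_12plus)
    pub12 <- round(n12 * share_pub)
    priv12 <- n12 - pub12

    states <- sample(c(datasets::state.abb, "DC", "PR"), n, replace = TRUE)
    onsite <- stats::rbinom(n, 1, cfg$frac_with_onsite_bh) == 1

    mh_patients <- integer(n)
    sa_patients <- integer(n)
    enc <- matrix(0, n, 3,
                  dimnames = list(NULL, c("licensed", "psychiatrist",
                                          "other_staff")))
    sa_enc <- numeric(n)
    fte <- matrix(0, n, 3, dimnames = dimnames(enc))
    sa_fte <- numeric(n)

    m <- sum(onsite)
    if (m > 0) {
      mh_patients[onsite] <- pmax(1, round(
        medical[onsite] * rbeta_mean(m, cfg$mh_patient_share_mean, 50)))
      sa_patients[onsite] <- pmax(1, round(
        medical[onsite] * rbeta_mean(m, cfg$sa_patient_share_mean, 50)))

      r_mh <- rlnorm_median(m, cfg$target_median_visits_per_mh_patient,
                            cfg$ratio_dispersion)
      r_sa <- rlnorm_median(m, cfg$target_median_visits_per_sa_patient,
                            cfg$ratio_dispersion)
      total_mh_enc <- pmax(1, round(mh_patients[onsite] * r_mh))
      sa_enc[onsite] <- pmax(1, round(sa_patients[onsite] * r_sa))

      shares <- rdirichlet(m, cfg$target_visit_shares *
                                cfg$share_concentration)
      e_lic <- round(total_mh_enc * shares[, 1])
      e_psy <- round(total_mh_enc * shares[, 2])
      e_oth <- pmax(0, total_mh_enc - e_lic - e_psy)
      enc[onsite, ] <- cbind(e_lic, e_psy, e_oth)

      # FTE = encounters / per-grantee visit load; a category with zero
      # encounters carries zero FTE and is excluded from load medians
      for (j in 1:3) {
        load <- rlnorm_median(m, cfg$target_median_visit_loads[j],
                              cfg$load_dispersion)
        fte[onsite, j] <- ifelse(enc[onsite, j] > 0,
                                 enc[onsite, j] / load, 0)
      }
      sa_load <- rlnorm_median(m, cfg$target_median_sa_visit_load,
                               cfg$load_dispersion)
      sa_fte[onsite] <- ifelse(sa_enc[onsite] > 0,
                               sa_enc[onsite] / sa_load, 0)
    }

    cohort <- tibble::tibble(
      grantee_id = sprintf("G%05d", seq_len(n)),
      state = states,
      medical_patients = as.numeric(medical),
      medical_patients_12plus_public = as.numeric(pub12),
      medical_patients_12plus_private = as.numeric(priv12),
      mh_patients = as.numeric(mh_patients),
      mh_encounters_licensed = as.numeric(enc[, "licensed"]),
      mh_encounters_psychiatrist = as.numeric(enc[, "psychiatrist"]),
      mh_encounters_other_staff = as.numeric(enc[, "other_staff"]),
      sa_patients = as.numeric(sa_patients),
      sa_encounters = as.numeric(sa_enc),
      fte_licensed_mh = fte[, "licensed"],
      fte_psychiatrist = fte[, "psychiatrist"],
      fte_other_mh_staff = fte[, "other_staff"],
      fte_substance_abuse = sa_fte
    )
    validate_grantees(cohort)
  })
}
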