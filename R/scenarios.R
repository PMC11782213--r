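#' Canonical simulation scenarios
#'
#' Pre-specified [cohort_config()]s used by the test-bench analyses:
#'
#' * `null_cohort_config()` — DS and control groups identical in law: all
#'   trajectory amplitudes 0, all mediation paths 0, equal sex composition,
#'   no missingness. Any downstream signal is a false positive, so p-values
#'   should be uniform and divergence detection near the alpha level.
#' * `abrupt_onset_config()` — an amyloid trajectory with a threshold-like
#'   lift-off (rate 3/yr, amplitude 90 Centiloid, noise SD 8, midpoint at
#'   EYO 10). Because the transition from floor to rise spans only ~2
#'   years, the sustained-exceedance divergence age is nearly insensitive
#'   to sample size, which is what makes a large-n oracle run a valid
#'   ground truth for the desk-scale estimator.
#' * `mediation_recovery_config(pm)` — strong, well-conditioned mediation
#'   triangle with a known true proportion mediated (`0.4`: a = 0.5,
#'   b = 0.4, c' = 0.3; `0.15`: a = 0.5, b = 0.3, c' = 0.85), no
#'   missingness, for parameter-recovery checks.
#'
#' @param n_ds,n_controls Group sizes.
#' @param seed RNG seed.
#' @name scenarios
NULL

no_missing <- c(centiloid = 0, tau_suvr = 0, gfap = 0, ptau217 = 0)

#' @rdname scenarios
#' @export
null_cohort_config <- function(n_ds = 100, n_controls = 100, seed = 1L) {
  flat <- function(floor, noise)
    trajectory_params(floor = floor, amplitude = 0, midpoint_eyo = 10,
                      rate = 0.45, noise_sd = noise)
  null_med <- function(m_sd, o_sd)
    mediation_structure(a = 0, b = 0, c_prime = 0,
                        mediator_noise_sd = m_sd, outcome_noise_sd = o_sd)
  cohort_config(
    n_ds = n_ds, n_controls = n_controls,
    trajectories = list(centiloid = flat(5, 12), gfap = flat(110, 40),
                        ptau217 = flat(0.25, 0.10), tau_suvr = flat(1.12, 0.15)),
    mediation = list(tau_suvr = null_med(40, 0.15),
                     ptau217 = null_med(40, 0.10)),
    sex_prob = c(ds = 0.5, control = 0.5),
    age_mean = c(ds = 44, control = 44), age_sd = c(ds = 10, control = 10),
    missingness = no_missing, seed = seed)
}

#' @rdname scenarios
#' @export
abrupt_onset_config <- function(n_ds = 348, n_controls = 42, seed = 1L) {
  cfg <- cohort_config(n_ds = n_ds, n_controls = n_controls, seed = seed)
  cfg$trajectories$centiloid <- trajectory_params(
    floor = 5, amplitude = 90, midpoint_eyo = 10, rate = 3, noise_sd = 8)
  cfg$missingness <- no_missing
  cfg
}

#' @rdname scenarios
#' @param proportion_mediated Target true proportion mediated, 0.4 or 0.15
#'   (other values are built with a = 0.5, b chosen freely and c' solving
#'   for the target).
#' @export
mediation_recovery_config <- function(proportion_mediated = 0.4,
                                      n_ds = 500, n_controls = 42,
                                      seed = 1L) {
  a <- 0.5
  b <- if (isTRUE(all.equal(proportion_mediated, 0.15))) 0.3 else 0.4
  acme <- a * b
  c_prime <- acme / proportion_mediated - acme
  med <- function(o_sd)
    mediation_structure(a = a, b = b, c_prime = c_prime,
                        mediator_noise_sd = 10, outcome_noise_sd = o_sd)
  cohort_config(
    n_ds = n_ds, n_controls = n_controls,
    trajectories = list(
      centiloid = trajectory_params(floor = 0, amplitude = 80,
                                    midpoint_eyo = 10, rate = 0.45,
                                    noise_sd = 10),
      gfap = trajectory_params(floor = 100, amplitude = 0, midpoint_eyo = 10,
                               rate = 0.45, noise_sd = 10),
      ptau217 = trajectory_params(floor = 50, amplitude = 0, midpoint_eyo = 10,
                                  rate = 0.45, noise_sd = 10),
      tau_suvr = trajectory_params(floor = 50, amplitude = 0, midpoint_eyo = 10,
                                   rate = 0.45, noise_sd = 10)),
    mediation = list(tau_suvr = med(10), ptau217 = med(10)),
    missingness = no_missing, seed = seed)
}
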