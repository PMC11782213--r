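#' Sigmoidal trajectory parameters for one biomarker
#'
#' Describes the mean trajectory of a biomarker in the Down syndrome (DS)
#' group as a function of estimated years to symptom onset (EYO). The mean
#' follows a four-parameter logistic that rises from `floor` toward
#' `floor + amplitude` as EYO counts down toward clinical onset at 0.
#' Control-group trajectories are age-flat at `floor`.
#'
#' @param floor Pre-pathology mean, in the biomarker's measurement units.
#' @param amplitude Asymptotic rise above the floor (same units); `0` gives a
#'   flat trajectory.
#' @param midpoint_eyo EYO (years) at which half the rise has occurred.
#' @param rate Sigmoid steepness, per year; larger values give a more abrupt
#'   transition.
#' @param noise_sd Additive Gaussian measurement noise SD (same units).
#'   For biomarkers generated through the mediation structure this field is
#'   kept for completeness but the mediation-model noise SD is what the
#'   generator uses (one noise source per biomarker).
#' @return A list of class `"trajectory_params"`.
#' @seealso [sigmoid_mean()], [cohort_config()]
#' @export
trajectory_params <- function(floor, amplitude, midpoint_eyo, rate, noise_sd) {
  p <- list(floor = floor, amplitude = amplitude, midpoint_eyo = midpoint_eyo,
            rate = rate, noise_sd = noise_sd)
  for (f in names(p)) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]))
      stop("trajectory_params: field '", f, "' must be a finite numeric scalar")
  }
  if (p$amplitude < 0) stop("trajectory_params: field 'amplitude' must be >= 0")
  if (p$rate <= 0) stop("trajectory_params: field 'rate' must be > 0")
  if (p$noise_sd <= 0) stop("trajectory_params: field 'noise_sd' must be > 0")
  class(p) <- "trajectory_params"
  p
}

#' Linear mediation structure: amyloid -> GFAP -> outcome
#'
#' Encodes the causal triangle used to generate DS biomarkers: the treatment
#' (amyloid Centiloid) affects the mediator (plasma GFAP) through path `a`,
#' the mediator affects the outcome through path `b`, and a direct path
#' `c_prime` links treatment to outcome. The true proportion mediated is
#' `a*b / (c_prime + a*b)`.
#'
#' @param a Mediator units per treatment unit (pg/mL GFAP per Centiloid).
#' @param b Outcome units per mediator unit.
#' @param c_prime Direct outcome units per treatment unit.
#' @param mediator_noise_sd,outcome_noise_sd Residual Gaussian SDs (> 0).
#' @param covariate_effects Optional list with numeric vectors `mediator` and
#'   `outcome`, each with entries `sex_male`, `apoe4`, `latency` giving
#'   additive covariate coefficients; defaults to all zero.
#' @return A list of class `"mediation_structure"`.
#' @seealso [true_proportion_mediated()], [cohort_config()]
#' @export
mediation_structure <- function(a, b, c_prime,
                                mediator_noise_sd, outcome_noise_sd,
                                covariate_effects = NULL) {
  zero <- c(sex_male = 0, apoe4 = 0, latency = 0)
  if (is.null(covariate_effects))
    covariate_effects <- list(mediator = zero, outcome = zero)
  for (part in c("mediator", "outcome")) {
    ce <- covariate_effects[[part]]
    if (is.null(ce)) { covariate_effects[[part]] <- zero; next }
    if (!all(names(zero) %in% names(ce)))
      stop("mediation_structure: field 'covariate_effects$", part,
           "' must name sex_male, apoe4 and latency")
    covariate_effects[[part]] <- ce[names(zero)]
  }
  m <- list(a = a, b = b, c_prime = c_prime,
            mediator_noise_sd = mediator_noise_sd,
            outcome_noise_sd = outcome_noise_sd,
            covariate_effects = covariate_effects)
  for (f in c("a", "b", "c_prime", "mediator_noise_sd", "outcome_noise_sd")) {
    if (!is.numeric(m[[f]]) || length(m[[f]]) != 1L || !is.finite(m[[f]]))
      stop("mediation_structure: field '", f, "' must be a finite numeric scalar")
  }
  if (m$mediator_noise_sd <= 0)
    stop("mediation_structure: field 'mediator_noise_sd' must be > 0")
  if (m$outcome_noise_sd <= 0)
    stop("mediation_structure: field 'outcome_noise_sd' must be > 0")
  class(m) <- "mediation_structure"
  m
}

#' True proportion mediated implied by a mediation structure
#'
#' Ground truth for parameter-recovery tests: the indirect share
#' `a*b / (c_prime + a*b)` of the total treatment effect.
#'
#' @param structure A [mediation_structure()].
#' @return The proportion mediated (may fall outside `[0, 1]` when paths have
#'   opposing signs).
#' @export
true_proportion_mediated <- function(structure) {
  stopifnot(inherits(structure, "mediation_structure"))
  te <- structure$c_prime + structure$a * structure$b
  if (abs(te) < .Machine$double.eps^0.5)
    stop("true_proportion_mediated: total effect c_prime + a*b is zero; ",
         "proportion mediated is undefined")
  structure$a * structure$b / te
}

#' Full synthetic-cohort configuration
#'
#' Bundles everything [generate_cohort()] needs. Defaults reproduce the study
#' conditions the pipeline is designed around: 348 DS participants and 42
#' sibling controls aged 25-65, average age of symptom onset (AAO) 52.5
#' years, sex imbalance between groups (78.6% vs 45.1% female), 23.4% APOE
#' e4 carriers, measurement latency uniform on 0-540 days, and per-modality
#' missingness matching the observed availability of amyloid PET, tau PET
#' and plasma assays (39.4%, 54.6%, 13.2%, 13.2% missing).
#'
#' The default mediation structures place the true proportion of the
#' amyloid effect carried by GFAP at 15.3% for the tau-PET outcome and
#' 42.1% for the plasma pTau-217 outcome.
#'
#' @param n_ds,n_controls Group sizes (> 0).
#' @param age_range Numeric length-2 truncation range for age, years.
#' @param age_mean,age_sd Named numeric (`ds`, `control`): moments of the
#'   truncated-normal age distribution per group; defaults are the observed
#'   group means and SDs (44.93 \[9.7\] DS, 43.57 \[12.5\] controls).
#' @param aao Average age of clinical symptom onset, years; EYO = aao - age.
#' @param trajectories Named list of [trajectory_params()] for `centiloid`,
#'   `gfap`, `ptau217`, `tau_suvr`.
#' @param mediation Named list of [mediation_structure()] for outcomes
#'   `tau_suvr` and `ptau217`. GFAP is a single shared mediator, so both
#'   structures must agree on `a` and `mediator_noise_sd`.
#' @param sex_prob Named numeric, probability of female sex per group
#'   (`ds`, `control`).
#' @param apoe4_prob APOE e4 carrier probability (both groups).
#' @param latency_days_range Integer length-2 range for inter-measurement
#'   latency, days.
#' @param missingness Named fractions in `[0,1]` per modality column
#'   (`centiloid`, `tau_suvr`, `gfap`, `ptau217`).
#' @param seed Integer RNG seed recorded in the ground-truth sidecar.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_ds = 348, n_controls = 42,
                          age_range = c(25, 65),
                          age_mean = c(ds = 44.93, control = 43.57),
                          age_sd = c(ds = 9.7, control = 12.5),
                          aao = 52.5,
                          trajectories = default_trajectories(),
                          mediation = default_mediation(),
                          sex_prob = c(ds = 0.451, control = 0.786),
                          apoe4_prob = 0.234,
                          latency_days_range = c(0L, 540L),
                          missingness = c(centiloid = 0.394, tau_suvr = 0.546,
                                          gfap = 0.132, ptau217 = 0.132),
                          seed = 101L) {
  cfg <- list(n_ds = n_ds, n_controls = n_controls, age_range = age_range,
              age_mean = age_mean, age_sd = age_sd,
              aao = aao, trajectories = trajectories, mediation = mediation,
              sex_prob = sex_prob, apoe4_prob = apoe4_prob,
              latency_days_range = latency_days_range,
              missingness = missingness, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

#' @rdname cohort_config
#' @export
default_trajectories <- function() {
  list(
    centiloid = trajectory_params(floor = 5,   amplitude = 80, midpoint_eyo = 2,
                                  rate = 0.45, noise_sd = 12),
    gfap      = trajectory_params(floor = 110, amplitude = 0,  midpoint_eyo = 2,
                                  rate = 0.45, noise_sd = 40),
    ptau217   = trajectory_params(floor = 0.25, amplitude = 0, midpoint_eyo = 2,
                                  rate = 0.45, noise_sd = 0.10),
    tau_suvr  = trajectory_params(floor = 1.06, amplitude = 0, midpoint_eyo = 2,
                                  rate = 0.45, noise_sd = 0.10)
  )
}

#' @rdname cohort_config
#' @export
default_mediation <- function() {
  list(
    # a*b/(c'+a*b) = 0.153: GFAP carries 15.3% of the amyloid -> tau-PET effect
    tau_suvr = mediation_structure(a = 2.0, b = 0.000306, c_prime = 0.003388,
                                   mediator_noise_sd = 40, outcome_noise_sd = 0.10),
    # a*b/(c'+a*b) = 0.421 for the amyloid -> plasma pTau-217 effect
    ptau217 = mediation_structure(a = 2.0, b = 0.001263, c_prime = 0.003474,
                                  mediator_noise_sd = 40, outcome_noise_sd = 0.10)
  )
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) if (!ok) stop("cohort_config: field '", field, "' ", msg)
  chk(is.numeric(cfg$n_ds) && cfg$n_ds >= 1, "n_ds", "must be a positive count")
  chk(is.numeric(cfg$n_controls) && cfg$n_controls >= 1, "n_controls",
      "must be a positive count")
  chk(is.numeric(cfg$age_range) && length(cfg$age_range) == 2 &&
        cfg$age_range[1] > 0 && diff(cfg$age_range) > 0, "age_range",
      "must be an increasing positive range")
  for (f in c("age_mean", "age_sd"))
    chk(all(c("ds", "control") %in% names(cfg[[f]])) &&
          all(is.finite(cfg[[f]])) && all(cfg[[f]] > 0), f,
        "must give positive values for 'ds' and 'control'")
  chk(is.numeric(cfg$aao) && cfg$aao > 0, "aao", "must be > 0")
  for (bm in c("centiloid", "gfap", "ptau217", "tau_suvr"))
    chk(inherits(cfg$trajectories[[bm]], "trajectory_params"),
        paste0("trajectories$", bm), "must be trajectory_params")
  for (out in c("tau_suvr", "ptau217"))
    chk(inherits(cfg$mediation[[out]], "mediation_structure"),
        paste0("mediation$", out), "must be a mediation_structure")
  chk(isTRUE(all.equal(cfg$mediation$tau_suvr$a, cfg$mediation$ptau217$a)) &&
        isTRUE(all.equal(cfg$mediation$tau_suvr$mediator_noise_sd,
                         cfg$mediation$ptau217$mediator_noise_sd)),
      "mediation", paste("must share one mediator model: 'a' and",
                         "'mediator_noise_sd' must agree across outcomes",
                         "(GFAP is generated once)"))
  chk(all(c("ds", "control") %in% names(cfg$sex_prob)) &&
        all(cfg$sex_prob >= 0 & cfg$sex_prob <= 1), "sex_prob",
      "must give probabilities in [0,1] for 'ds' and 'control'")
  chk(is.numeric(cfg$apoe4_prob) && cfg$apoe4_prob >= 0 && cfg$apoe4_prob <= 1,
      "apoe4_prob", "must be a probability in [0,1]")
  chk(is.numeric(cfg$latency_days_range) && length(cfg$latency_days_range) == 2 &&
        cfg$latency_days_range[1] >= 0 &&
        cfg$latency_days_range[2] >= cfg$latency_days_range[1],
      "latency_days_range", "must be a non-negative non-decreasing range")
  mods <- c("centiloid", "tau_suvr", "gfap", "ptau217")
  chk(all(mods %in% names(cfg$missingness)) &&
        all(cfg$missingness >= 0 & cfg$missingness <= 1), "missingness",
      "must give fractions in [0,1] for centiloid, tau_suvr, gfap, ptau217")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed", "must be a finite integer")
  invisible(TRUE)
}
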