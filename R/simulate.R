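#' Sigmoidal DS mean trajectory as a function of EYO
#'
#' Mean biomarker level at a given estimated-years-to-onset, under the
#' convention EYO = AAO - age: EYO counts *down* toward clinical onset at 0,
#' so the curve rises as EYO decreases.
#'
#' @param eyo Estimated years to symptom onset (vectorised).
#' @param params A [trajectory_params()] object.
#' @return `floor + amplitude / (1 + exp(-rate * (midpoint_eyo - eyo)))`.
#' @export
sigmoid_mean <- function(eyo, params) {
  stopifnot(inherits(params, "trajectory_params"))
  params$floor + params$amplitude /
    (1 + exp(-params$rate * (params$midpoint_eyo - eyo)))
}

#' Generate a synthetic DS / sibling-control cohort
#'
#' Draws one cross-sectional cohort under the configured causal structure.
#' Controls draw every biomarker age-flat from its floor plus covariate
#' effects and noise. DS participants draw amyloid (Centiloid) from the
#' sigmoidal EYO trajectory, then plasma GFAP from the mediator model
#' (amyloid + covariates), then tau-PET SUVR and plasma pTau-217 from the
#' outcome models (amyloid + GFAP + covariates). Concentrations (GFAP,
#' pTau-217) and SUVR are truncated at 0. Per-modality missingness is then
#' applied completely at random. The same config and seed give
#' byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `cohort` (data frame of participant records,
#'   missing values as `NA`) and `truth` (ground-truth sidecar: full
#'   parameter set, seed, and true proportion mediated per outcome).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n_ds <- as.integer(config$n_ds); n_ct <- as.integer(config$n_controls)
  n <- n_ds + n_ct
  group <- c(rep("DS", n_ds), rep("control", n_ct))
  id <- sprintf("%s%03d", ifelse(group == "DS", "DS", "C"),
                c(seq_len(n_ds), seq_len(n_ct)))
  mu <- ifelse(group == "DS", config$age_mean[["ds"]], config$age_mean[["control"]])
  sd <- ifelse(group == "DS", config$age_sd[["ds"]], config$age_sd[["control"]])
  # truncated normal by inverse-CDF, keeps one uniform draw per participant
  plo <- stats::pnorm(config$age_range[1], mu, sd)
  phi <- stats::pnorm(config$age_range[2], mu, sd)
  age <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sd)
  p_female <- ifelse(group == "DS", config$sex_prob[["ds"]],
                     config$sex_prob[["control"]])
  sex <- ifelse(stats::runif(n) < p_female, "female", "male")
  apoe4 <- ifelse(stats::runif(n) < config$apoe4_prob, "carrier", "non-carrier")
  latency_days <- sample(seq(config$latency_days_range[1],
                             config$latency_days_range[2]), n, replace = TRUE)
  eyo <- config$aao - age

  tr <- config$trajectories
  med_tau <- config$mediation$tau_suvr
  med_ptau <- config$mediation$ptau217

  # covariate design shared by mediator and outcome models
  Z <- cbind(sex_male = as.numeric(sex == "male"),
             apoe4 = as.numeric(apoe4 == "carrier"),
             latency = latency_days)
  cov_term <- function(coefs) drop(Z %*% coefs)

  is_ds <- group == "DS"
  # amyloid: sigmoidal in EYO for DS, flat at floor for controls
  amy_mean <- ifelse(is_ds, sigmoid_mean(eyo, tr$centiloid), tr$centiloid$floor)
  centiloid <- amy_mean + stats::rnorm(n, 0, tr$centiloid$noise_sd)
  amy_centred <- centiloid - tr$centiloid$floor

  # mediator (GFAP), shared across outcomes; DS-only amyloid dependence
  a <- med_tau$a
  gfap <- tr$gfap$floor + ifelse(is_ds, a * amy_centred, 0) +
    cov_term(med_tau$covariate_effects$mediator) +
    stats::rnorm(n, 0, med_tau$mediator_noise_sd)
  gfap <- pmax(gfap, 0)
  gfap_centred <- gfap - tr$gfap$floor

  outcome_draw <- function(floorv, med) {
    y <- floorv +
      ifelse(is_ds, med$c_prime * amy_centred + med$b * gfap_centred, 0) +
      cov_term(med$covariate_effects$outcome) +
      stats::rnorm(n, 0, med$outcome_noise_sd)
    pmax(y, 0)
  }
  tau_suvr <- outcome_draw(tr$tau_suvr$floor, med_tau)
  ptau217 <- outcome_draw(tr$ptau217$floor, med_ptau)

  cohort <- data.frame(
    participant_id = id, group = group,
    age = age, sex = sex, apoe4 = apoe4,
    centiloid = centiloid, tau_suvr = tau_suvr,
    gfap = gfap, ptau217 = ptau217,
    latency_days = as.integer(latency_days),
    stringsAsFactors = FALSE
  )
  cohort <- apply_missingness(cohort, config$missingness,
                              seed = NULL)  # inherits the seeded stream

  truth <- list(
    seed = config$seed,
    n_ds = n_ds, n_controls = n_ct,
    aao = config$aao, age_range = config$age_range,
    age_mean = as.list(config$age_mean), age_sd = as.list(config$age_sd),
    trajectories = lapply(config$trajectories, unclass),
    mediation = lapply(config$mediation, unclass),
    sex_prob = as.list(config$sex_prob),
    apoe4_prob = config$apoe4_prob,
    latency_days_range = config$latency_days_range,
    missingness = as.list(config$missingness),
    true_proportion_mediated = list(
      tau_suvr = tryCatch(true_proportion_mediated(med_tau),
                          error = function(e) NA_real_),
      ptau217 = tryCatch(true_proportion_mediated(med_ptau),
                         error = function(e) NA_real_)
    )
  )
  list(cohort = cohort, truth = truth)
}

#' Mark biomarker values missing completely at random
#'
#' Each modality column is set to `NA` independently per participant at the
#' configured rate. Rows are never removed.
#'
#' @param table Cohort data frame.
#' @param fractions Named missingness fractions in `[0,1]`; names must be
#'   columns of `table`.
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream (used internally by [generate_cohort()]).
#' @return The table with missing cells as `NA`.
#' @export
apply_missingness <- function(table, fractions, seed = NULL) {
  if (any(fractions < 0 | fractions > 1))
    stop("apply_missingness: fractions must lie in [0,1]")
  bad <- setdiff(names(fractions), names(table))
  if (length(bad))
    stop("apply_missingness: no such column: ", paste(bad, collapse = ", "))
  run <- function() {
    for (col in names(fractions)) {
      f <- fractions[[col]]
      if (f > 0)
        table[[col]][stats::runif(nrow(table)) < f] <- NA
    }
    table
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write / read a cohort as CSV plus a JSON ground-truth sidecar
#'
#' The CSV has one row per participant with the fixed header
#' `participant_id, group, age, sex, apoe4, centiloid, tau_suvr, gfap,
#' ptau217, latency_days`; missing cells are empty.
#'
#' @param x Result of [generate_cohort()].
#' @param csv_path Output CSV path.
#' @param sidecar_path Optional JSON path for the ground-truth sidecar.
#' @return `csv_path`, invisibly.
#' @export
write_cohort <- function(x, csv_path, sidecar_path = NULL) {
  utils::write.csv(x$cohort, csv_path, row.names = FALSE, na = "")
  if (!is.null(sidecar_path))
    jsonlite::write_json(x$truth, sidecar_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(csv_path)
}

#' @rdname write_cohort
#' @param path CSV path to read.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  required <- c("participant_id", "group", "age", "sex", "apoe4",
                "centiloid", "tau_suvr", "gfap", "ptau217", "latency_days")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("read_cohort: missing columns: ", paste(missing_cols, collapse = ", "))
  df
}
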