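#' Estimated years to symptom onset
#'
#' EYO is the average age of clinical symptom onset (AAO) minus the
#' participant's age, so it is positive before expected onset, zero at it,
#' and negative afterwards. Note the sign convention: EYO *decreases* with
#' age (some staging papers use the opposite sign).
#'
#' @param age Age in years (> 0, vectorised).
#' @param aao Average age of onset, default 52.5 years.
#' @return `aao - age`.
#' @export
compute_eyo <- function(age, aao = 52.5) {
  if (any(!is.na(age) & age <= 0)) stop("compute_eyo: age must be > 0")
  aao - age
}

#' Classify amyloid/tau (A/T) pathology status
#'
#' Amyloid positivity is Centiloid strictly greater than `centiloid_threshold`
#' and tau positivity is summary SUVR strictly greater than `tau_threshold`;
#' values exactly at a threshold are negative. Missing values yield status
#' `"unknown"`. Sibling controls keep the combined label `"control"`
#' regardless of their biomarker values; DS participants with both statuses
#' known get one of `"A-/T-"`, `"A+/T-"`, `"A+/T+"`, `"A-/T+"`, otherwise
#' `"unknown"`.
#'
#' @param centiloid,tau_suvr Numeric vectors, `NA` allowed.
#' @param group Character vector, `"DS"` or `"control"`.
#' @param centiloid_threshold,tau_threshold Positivity cutoffs (defaults 18
#'   Centiloid and 1.3 SUVR).
#' @return Data frame with columns `amyloid`, `tau`
#'   (`negative`/`positive`/`unknown`) and `combined_label`.
#' @export
classify_at_status <- function(centiloid, tau_suvr, group,
                               centiloid_threshold = 18, tau_threshold = 1.3) {
  n <- max(length(centiloid), length(tau_suvr), length(group))
  centiloid <- rep_len(centiloid, n)
  tau_suvr <- rep_len(tau_suvr, n)
  group <- rep_len(group, n)
  status <- function(x, thr)
    ifelse(is.na(x), "unknown", ifelse(x > thr, "positive", "negative"))
  amyloid <- status(centiloid, centiloid_threshold)
  tau <- status(tau_suvr, tau_threshold)
  lab <- paste0("A", ifelse(amyloid == "positive", "+", "-"),
                "/T", ifelse(tau == "positive", "+", "-"))
  lab[amyloid == "unknown" | tau == "unknown"] <- "unknown"
  lab[group == "control"] <- "control"
  data.frame(amyloid = amyloid, tau = tau, combined_label = lab,
             stringsAsFactors = FALSE)
}

#' Tau-PET summary SUVR over a Braak I/III/IV region set
#'
#' Unweighted arithmetic mean of regional SUVRs over the configured region
#' set. The set is configurable because the composite is defined by the
#' Braak stages it reflects, not a fixed atlas parcellation.
#'
#' @param regional_suvrs Named numeric vector of region SUVRs.
#' @param region_set Character vector of region names to average; defaults to
#'   a representative Braak I/III/IV set.
#' @return Mean SUVR over `region_set`.
#' @export
tau_summary_suvr <- function(regional_suvrs,
                             region_set = c("entorhinal", "parahippocampal",
                                            "fusiform", "amygdala",
                                            "inferior_temporal",
                                            "middle_temporal")) {
  missing_regions <- setdiff(region_set, names(regional_suvrs))
  if (length(missing_regions))
    stop("tau_summary_suvr: missing region(s): ",
         paste(missing_regions, collapse = ", "))
  mean(as.numeric(regional_suvrs[region_set]))
}

#' Build a per-analysis table with exclusions and complete-case filtering
#'
#' Joins A/T status and EYO onto the cohort, excludes DS participants with
#' the discordant A-/T+ profile, and keeps complete cases on
#' `required_variables`. Every dropped row is logged with its reason, and the
#' reported N is the number of remaining rows. Filtering is per-analysis: a
#' participant can enter the group comparisons but not the mediation.
#'
#' @param cohort Cohort data frame (schema of [generate_cohort()]).
#' @param required_variables Character vector of columns that must be
#'   observed; rows missing any are dropped (empty vector keeps all rows).
#' @param exclude_discordant Drop DS A-/T+ participants (default TRUE).
#' @param centiloid_threshold,tau_threshold,aao Passed to
#'   [classify_at_status()] and [compute_eyo()].
#' @return A list of class `"analysis_table"` with elements `table` (rows
#'   retained, plus `eyo`, `amyloid`, `tau`, `combined_label`), `exclusions`
#'   (data frame `participant_id`, `reason`) and `n`.
#' @export
build_analysis_table <- function(cohort, required_variables = character(),
                                 exclude_discordant = TRUE,
                                 centiloid_threshold = 18, tau_threshold = 1.3,
                                 aao = 52.5) {
  required_cols <- c("participant_id", "group", "age")
  missing_cols <- setdiff(c(required_cols, required_variables), names(cohort))
  if (length(missing_cols))
    stop("build_analysis_table: cohort lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- cohort
  tab$eyo <- compute_eyo(tab$age, aao)
  st <- classify_at_status(tab$centiloid, tab$tau_suvr, tab$group,
                           centiloid_threshold, tau_threshold)
  tab <- cbind(tab, st)

  exclusions <- data.frame(participant_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  if (exclude_discordant) {
    disc <- tab$group == "DS" & tab$combined_label == "A-/T+"
    if (any(disc)) {
      exclusions <- rbind(exclusions, data.frame(
        participant_id = tab$participant_id[disc],
        reason = "discordant A-/T+ profile", stringsAsFactors = FALSE))
      tab <- tab[!disc, , drop = FALSE]
    }
  }
  if (length(required_variables)) {
    complete <- stats::complete.cases(tab[, required_variables, drop = FALSE])
    if (any(!complete)) {
      exclusions <- rbind(exclusions, data.frame(
        participant_id = tab$participant_id[!complete],
        reason = "incomplete on required variables", stringsAsFactors = FALSE))
      tab <- tab[complete, , drop = FALSE]
    }
  }
  if (nrow(tab) == 0)
    stop("build_analysis_table: no rows remain after exclusions")
  rownames(tab) <- NULL
  structure(list(table = tab, exclusions = exclusions, n = nrow(tab)),
            class = "analysis_table")
}

#' @export
print.analysis_table <- function(x, ...) {
  cat("analysis_table:", x$n, "rows retained,",
      nrow(x$exclusions), "excluded\n")
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  invisible(x)
}
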