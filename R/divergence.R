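#' Bootstrap estimate of the age at which a DS biomarker diverges from controls
#'
#' Penalized cubic-regression-spline curves are fitted to the biomarker
#' against age separately for the DS and control groups; participants are
#' then resampled with replacement *within group* `n_bootstrap` times, both
#' curves refitted (knots fixed at the original quantiles), and the DS minus
#' control difference recorded on a fine age grid.
#'
#' Divergence is operationalized as sustained exceedance: the point estimate
#' is the smallest grid age at which the pointwise bootstrap percentile
#' interval (level `1 - alpha`) of the difference lies strictly above 0 there
#' and at every older grid age. Each replicate also records its own
#' divergence age — the first grid age where its difference curve exceeds
#' `z[1-alpha/2]` model-based standard errors above 0, sustained to the end
#' of the grid — which calibrates false detection to roughly the alpha level
#' under the null. The CI is the percentile interval of those per-replicate
#' ages, and when fewer than half the replicates detect a divergence the
#' estimate is reported as none (`NA`) with the detection fraction.
#'
#' @param cohort Cohort data frame (or [build_analysis_table()] result) with
#'   `group`, `age` and the biomarker column.
#' @param biomarker Column name to analyse.
#' @param axis `"age"` (default) or `"eyo"`; fitting is done on age and the
#'   EYO report applies `eyo = aao - age`.
#' @param n_bootstrap Bootstrap replicates (default 10000).
#' @param alpha Two-sided level for intervals and detection (default 0.05).
#' @param grid_step Age-grid resolution in years (default 0.1).
#' @param grid_trim Tail fraction of each group's age distribution excluded
#'   from the evaluation grid (default 0.025 per side). Spline fits are
#'   boundary-unstable where data are sparse, and the sustained-exceedance
#'   rule reads the difference band all the way to the oldest grid age, so
#'   the grid is restricted to ages both groups support.
#' @param k Spline basis dimension per group (default 10).
#' @param control_fit `"spline"` fits the control curve with the same model;
#'   `"flat"` summarizes controls by their mean (age-flat reference).
#' @param adjust If TRUE, residualize the biomarker on sex, APOE e4 and
#'   latency (pooled linear fit) before curve fitting.
#' @param aao Average age of onset used for the EYO relabeling.
#' @param seed Integer seed; two biomarkers analysed from the same cohort
#'   with the same seed share resampling indices (paired replicates).
#' @return An object of class `"divergence_result"`; see Details.
#' @export
estimate_divergence_age <- function(cohort, biomarker, axis = c("age", "eyo"),
                                    n_bootstrap = 10000, alpha = 0.05,
                                    grid_step = 0.1, grid_trim = 0.025, k = 10,
                                    control_fit = c("spline", "flat"),
                                    adjust = FALSE, aao = 52.5, seed = 1L) {
  axis <- match.arg(axis)
  control_fit <- match.arg(control_fit)
  tab <- if (inherits(cohort, "analysis_table")) cohort$table else cohort
  if (!biomarker %in% names(tab))
    stop("estimate_divergence_age: no column '", biomarker, "'")
  y_all <- tab[[biomarker]]
  if (adjust) y_all <- adjust_for_covariates(y_all, tab)

  take <- function(g) {
    sel <- tab$group == g & !is.na(y_all) & !is.na(tab$age)
    list(x = tab$age[sel], y = y_all[sel])
  }
  ds <- take("DS"); ct <- take("control")
  if (length(unique(ds$x)) < k)
    stop("estimate_divergence_age: DS group has too few distinct ages for k = ", k)
  if (control_fit == "spline" && length(unique(ct$x)) < k)
    stop("estimate_divergence_age: control group has too few distinct ages ",
         "for k = ", k, "; consider control_fit = \"flat\"")
  # per-group support bounds: the k-th extreme observed age, with k at
  # least 5 so the curve is never read where only a couple of participants
  # anchor it (small control groups otherwise destabilise the band edge)
  support <- function(xs) {
    xs <- sort(xs)
    k <- min(max(5, ceiling(grid_trim * length(xs))), floor(length(xs) / 2))
    c(xs[k], xs[length(xs) - k + 1])
  }
  s_ds <- support(ds$x); s_ct <- support(ct$x)
  lo <- max(s_ds[1], s_ct[1]); hi <- min(s_ds[2], s_ct[2])
  if (hi <= lo) stop("estimate_divergence_age: group age ranges do not overlap")
  grid <- seq(lo, hi, by = grid_step)
  G <- length(grid)
  z <- stats::qnorm(1 - alpha / 2)

  basis_ds <- make_cr_basis(ds$x, k)
  Bg_ds <- cr_basis_at(basis_ds, grid)
  if (control_fit == "spline") {
    basis_ct <- make_cr_basis(ct$x, k)
    Bg_ct <- cr_basis_at(basis_ct, grid)
  }

  group_curve <- function(X, y, S, Bg) {
    f <- pspline_solve(X, y, S, lambda = "gcv")
    M <- Bg %*% f$A
    list(mean = drop(Bg %*% f$coefficients),
         var = pmax(f$sigma2, 0) * pmax(rowSums((M %*% f$XtX) * M), 0))
  }
  flat_curve <- function(y) {
    list(mean = rep(mean(y), G), var = rep(stats::var(y) / length(y), G))
  }

  idx <- withr::with_seed(seed, list(
    ds = matrix(sample.int(length(ds$y), length(ds$y) * n_bootstrap,
                           replace = TRUE), ncol = n_bootstrap),
    ct = matrix(sample.int(length(ct$y), length(ct$y) * n_bootstrap,
                           replace = TRUE), ncol = n_bootstrap)
  ))

  diffs <- matrix(NA_real_, G, n_bootstrap)
  rep_age <- rep(NA_real_, n_bootstrap)
  failed <- 0L
  for (b in seq_len(n_bootstrap)) {
    res <- tryCatch({
      i <- idx$ds[, b]; j <- idx$ct[, b]
      cds <- group_curve(basis_ds$X[i, , drop = FALSE], ds$y[i],
                         basis_ds$S, Bg_ds)
      cct <- if (control_fit == "spline")
        group_curve(basis_ct$X[j, , drop = FALSE], ct$y[j], basis_ct$S, Bg_ct)
      else flat_curve(ct$y[j])
      d <- cds$mean - cct$mean
      se <- sqrt(cds$var + cct$var)
      list(d = d, age = sustained_onset(d - z * se > 0, grid))
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    diffs[, b] <- res$d
    rep_age[b] <- res$age
  }
  ok <- colSums(is.na(diffs)) < G
  if (!any(ok)) stop("estimate_divergence_age: all bootstrap replicates failed")

  lower_band <- apply(diffs[, ok, drop = FALSE], 1, stats::quantile,
                      probs = alpha / 2)
  ensemble_age <- sustained_onset(lower_band > 0, grid)
  detection_fraction <- mean(!is.na(rep_age[ok]))
  detected_ages <- rep_age[ok & !is.na(rep_age)]
  ci_age <- if (length(detected_ages) >= 2)
    stats::quantile(detected_ages, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  else c(NA_real_, NA_real_)
  div_age <- if (detection_fraction >= 0.5 && !is.na(ensemble_age))
    ensemble_age else NA_real_
  # point estimate (ensemble band rule) and CI (per-replicate ages) are
  # different functionals; widen the CI when needed so it brackets the point
  if (!is.na(div_age) && all(is.finite(ci_age))) {
    ci_age[1] <- min(ci_age[1], div_age)
    ci_age[2] <- max(ci_age[2], div_age)
  }

  to_axis <- function(a) if (axis == "eyo") aao - a else a
  ci <- sort(to_axis(ci_age), na.last = TRUE)
  structure(list(
    biomarker = biomarker, axis = axis, aao = aao,
    divergence_age = to_axis(div_age),
    divergence_age_years = div_age,
    bootstrap_ages = to_axis(detected_ages),
    replicate_ages_years = rep_age,
    ci_low = ci[1], ci_high = ci[2],
    n_bootstrap = n_bootstrap, n_failed = failed,
    detection_fraction = detection_fraction,
    grid = to_axis(grid), grid_years = grid,
    difference_lower_band = lower_band,
    alpha = alpha, seed = seed, control_fit = control_fit,
    paired_key = list(seed = seed, n_ds = length(ds$y), n_ct = length(ct$y),
                      n_bootstrap = n_bootstrap)
  ), class = "divergence_result")
}

# First grid point from which `flag` stays TRUE through the end of the grid;
# NA when the final point is FALSE.
sustained_onset <- function(flag, grid) {
  if (!length(flag) || is.na(flag[length(flag)]) || !flag[length(flag)])
    return(NA_real_)
  last_false <- suppressWarnings(max(which(!flag)))
  if (!is.finite(last_false)) grid[1] else grid[last_false + 1L]
}

adjust_for_covariates <- function(y, tab) {
  covs <- intersect(c("sex", "apoe4", "latency_days"), names(tab))
  if (!length(covs)) return(y)
  d <- tab[, covs, drop = FALSE]
  d$y <- y
  fit <- stats::lm(y ~ ., data = d, na.action = stats::na.exclude)
  mean(y, na.rm = TRUE) + stats::residuals(fit)
}

#' @export
print.divergence_result <- function(x, ...) {
  cat("divergence_result:", x$biomarker, "on", x$axis, "axis\n")
  if (is.na(x$divergence_age)) {
    cat("  no divergence detected (detection fraction ",
        round(x$detection_fraction, 3), ")\n", sep = "")
  } else {
    cat(sprintf("  divergence at %.1f (%.0f%% CI %.1f-%.1f), detection %.1f%%\n",
                x$divergence_age, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
                100 * x$detection_fraction))
  }
  invisible(x)
}

#' Compare divergence timing between two biomarkers
#'
#' Uses the per-replicate divergence ages. When both results come from the
#' same cohort and seed the replicates are paired (same participant
#' resamples); the two-sided p-value is `2 * min(P(diff <= 0), P(diff >= 0))`
#' over replicates where both biomarkers detected a divergence, floored at
#' `1 / n_bootstrap`. Replicates lacking a detection for either biomarker
#' are dropped and their fraction reported.
#'
#' @param result_a,result_b [estimate_divergence_age()] results with equal
#'   `n_bootstrap`.
#' @return List with `biomarkers`, `paired`, `timing_differences` (years,
#'   a minus b), `median_difference`, `p_value`, `dropped_fraction`.
#' @export
compare_divergence_timing <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "divergence_result"),
            inherits(result_b, "divergence_result"))
  if (result_a$n_bootstrap != result_b$n_bootstrap)
    stop("compare_divergence_timing: results use different n_bootstrap")
  if (result_a$detection_fraction < 0.5 && result_b$detection_fraction < 0.5)
    stop("compare_divergence_timing: both biomarkers undetected in more ",
         "than half the replicates")
  paired <- identical(result_a$paired_key$seed, result_b$paired_key$seed) &&
    identical(result_a$paired_key$n_ds, result_b$paired_key$n_ds) &&
    identical(result_a$paired_key$n_ct, result_b$paired_key$n_ct)
  da <- result_a$replicate_ages_years
  db <- result_b$replicate_ages_years
  both <- !is.na(da) & !is.na(db)
  if (!any(both))
    stop("compare_divergence_timing: no replicate detected both biomarkers")
  d <- da[both] - db[both]
  B <- result_a$n_bootstrap
  p <- max(2 * min(mean(d <= 0), mean(d >= 0)), 1 / B)
  list(biomarkers = c(result_a$biomarker, result_b$biomarker),
       paired = paired,
       timing_differences = d,
       median_difference = stats::median(d),
       p_value = min(1, p),
       dropped_fraction = 1 - mean(both))
}
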