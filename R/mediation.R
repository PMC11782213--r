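#' Closed-form ordinary least squares
#'
#' Thin wrapper over the QR least-squares solver ([stats::lm.fit()]) that
#' errors on rank deficiency naming the collinear columns and returns the
#' quantities the mediation estimator needs.
#'
#' @param design Numeric matrix or data frame of predictors (an intercept
#'   column is added unless one is present).
#' @param response Numeric response vector.
#' @return List with `coefficients`, `residual_variance` (on `n - p` df),
#'   `coefficient_covariance`, `fitted`, `residuals`.
#' @export
fit_ols <- function(design, response) {
  X <- as.matrix(design)
  if (!"(Intercept)" %in% colnames(X))
    X <- cbind("(Intercept)" = 1, X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("fit_ols: need more observations than predictors")
  fit <- stats::lm.fit(X, response)
  if (fit$rank < p) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    stop("fit_ols: design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - p)
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  list(coefficients = fit$coefficients, residual_variance = s2,
       coefficient_covariance = s2 * XtX_inv,
       fitted = fit$fitted.values, residuals = fit$residuals)
}

#' Specify a mediation analysis
#'
#' @param treatment,mediator,outcome Column names (must be distinct);
#'   defaults follow the amyloid -> GFAP -> outcome triangle.
#' @param covariates Character vector of adjustment columns (possibly
#'   empty). `"sex"` and `"apoe4"` enter as binary indicators,
#'   `"latency_days"` as continuous.
#' @param n_bootstrap,seed,ci_level Bootstrap controls.
#' @return List of class `"mediation_spec"`.
#' @export
mediation_spec <- function(treatment = "centiloid", mediator = "gfap",
                           outcome = "tau_suvr",
                           covariates = c("latency_days", "sex", "apoe4"),
                           n_bootstrap = 5000, seed = 1L, ci_level = 0.95) {
  if (anyDuplicated(c(treatment, mediator, outcome)))
    stop("mediation_spec: treatment, mediator and outcome must be distinct")
  structure(list(treatment = treatment, mediator = mediator,
                 outcome = outcome, covariates = covariates,
                 n_bootstrap = n_bootstrap, seed = as.integer(seed),
                 ci_level = ci_level),
            class = "mediation_spec")
}

# numeric model columns: binary indicators for sex / apoe4, identity else
mediation_design <- function(spec, table) {
  need <- c(spec$treatment, spec$mediator, spec$outcome, spec$covariates)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("estimate_mediation: table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- table[stats::complete.cases(table[, need, drop = FALSE]), ,
               drop = FALSE]
  as_num <- function(col) {
    v <- tab[[col]]
    if (col == "sex") as.numeric(v == "male")
    else if (col == "apoe4") as.numeric(v == "carrier")
    else as.numeric(v)
  }
  Z <- if (length(spec$covariates))
    do.call(cbind, stats::setNames(lapply(spec$covariates, as_num),
                                   spec$covariates))
  else NULL
  list(t = as_num(spec$treatment), m = as_num(spec$mediator),
       y = as_num(spec$outcome), Z = Z, n = nrow(tab))
}

#' Point estimate of the mediated effect (product of coefficients)
#'
#' Linear-model mediation: the mediator model `M ~ T + Z` gives path `a`,
#' the outcome model `Y ~ T + M + Z` gives paths `b` and `c'`. The average
#' causal mediation effect (ACME) is `a * b`, the average direct effect
#' (ADE) is `c'`, and their sum equals the treatment coefficient of
#' `Y ~ T + Z` exactly (an algebraic identity of least squares). This equals
#' the counterfactual ACME under linearity, no treatment-mediator
#' interaction, and the usual no-unmeasured-confounding assumptions.
#'
#' @param spec A [mediation_spec()].
#' @param table Data frame; complete cases on the spec variables are used.
#' @param min_n Minimum analysis size (default 30).
#' @return List with `acme`, `ade`, `total_effect`, `proportion_mediated`
#'   (raw; also `proportion_mediated_truncated` clipped to `[0,1]`),
#'   `paths` (a, b, c_prime), `analysis_n`, `stability_flag` (near-zero
#'   total effect).
#' @export
estimate_mediation <- function(spec, table, min_n = 30) {
  d <- mediation_design(spec, table)
  if (d$n < min_n)
    stop("estimate_mediation: only ", d$n, " complete cases (minimum ", min_n, ")")
  est <- mediation_paths(d)
  est$analysis_n <- d$n
  est
}

mediation_paths <- function(d, tol = 1e-8) {
  Xm <- cbind(treatment = d$t, d$Z)
  Xy <- cbind(treatment = d$t, mediator = d$m, d$Z)
  a <- fit_ols(Xm, d$m)$coefficients[["treatment"]]
  fy <- fit_ols(Xy, d$y)$coefficients
  b <- fy[["mediator"]]; c_prime <- fy[["treatment"]]
  acme <- a * b
  te <- c_prime + acme
  stable <- abs(te) > tol * max(1, abs(acme))
  list(acme = acme, ade = c_prime, total_effect = te,
       proportion_mediated = if (stable) acme / te else NA_real_,
       proportion_mediated_truncated = if (stable)
         min(max(acme / te, 0), 1) else NA_real_,
       paths = c(a = a, b = b, c_prime = c_prime),
       stability_flag = !stable)
}

#' Bootstrap mediation analysis with CIs and p-values
#'
#' Nonparametric case-resampling bootstrap of [estimate_mediation()]:
#' percentile CIs for ACME, ADE, total effect and proportion mediated, and
#' two-sided p-values `2 * min(P(est <= 0), P(est >= 0))` floored at
#' `1 / n_bootstrap`. Proportion-mediated replicates with a near-zero total
#' effect are dropped; when more than 1% are dropped the `stability_flag`
#' is set.
#'
#' @inheritParams estimate_mediation
#' @param te_tolerance Total-effect magnitude below which a replicate's
#'   proportion mediated is considered unstable, relative to the point
#'   estimate's total effect (default 1% of it).
#' @return The [estimate_mediation()] list augmented with `ci` (matrix,
#'   one row per quantity), `p_values`, `n_bootstrap`, `seed`,
#'   `dropped_pm_fraction`.
#' @export
bootstrap_mediation <- function(spec, table, min_n = 30, te_tolerance = NULL) {
  d <- mediation_design(spec, table)
  if (d$n < min_n)
    stop("bootstrap_mediation: only ", d$n, " complete cases (minimum ", min_n, ")")
  point <- mediation_paths(d)
  point$analysis_n <- d$n
  if (is.null(te_tolerance)) te_tolerance <- 0.01 * abs(point$total_effect)

  B <- spec$n_bootstrap
  draws <- withr::with_seed(spec$seed, {
    out <- matrix(NA_real_, B, 4,
                  dimnames = list(NULL, c("acme", "ade", "total_effect",
                                          "proportion_mediated")))
    for (i in seq_len(B)) {
      idx <- sample.int(d$n, d$n, replace = TRUE)
      db <- list(t = d$t[idx], m = d$m[idx], y = d$y[idx],
                 Z = if (is.null(d$Z)) NULL else d$Z[idx, , drop = FALSE],
                 n = d$n)
      r <- tryCatch(mediation_paths(db), error = function(e) NULL)
      if (is.null(r)) next
      pm <- if (abs(r$total_effect) > te_tolerance)
        r$acme / r$total_effect else NA_real_
      out[i, ] <- c(r$acme, r$ade, r$total_effect, pm)
    }
    out
  })

  alpha <- 1 - spec$ci_level
  ci <- t(apply(draws, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
                na.rm = TRUE))
  colnames(ci) <- c("low", "high")
  boot_p <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    min(1, max(2 * min(mean(v <= 0), mean(v >= 0)), 1 / B))
  }
  dropped <- mean(is.na(draws[, "proportion_mediated"]))
  point$ci <- ci
  point$p_values <- apply(draws, 2, boot_p)
  point$n_bootstrap <- B
  point$seed <- spec$seed
  point$dropped_pm_fraction <- dropped
  point$stability_flag <- point$stability_flag || dropped > 0.01
  point$bootstrap_draws <- draws
  class(point) <- "mediation_result"
  point
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation_result (n = %d, %d bootstrap replicates)\n",
              x$analysis_n, x$n_bootstrap))
  q <- c("acme", "ade", "total_effect", "proportion_mediated")
  for (nm in q)
    cat(sprintf("  %-20s %9.4g  [%.4g, %.4g]  p = %.3g\n", nm, x[[nm]],
                x$ci[nm, "low"], x$ci[nm, "high"], x$p_values[[nm]]))
  if (x$stability_flag) cat("  (unstable: near-zero total effect)\n")
  invisible(x)
}
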