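#' Fit a penalized cubic regression spline
#'
#' Minimizes `||y - B beta||^2 + lambda * beta' P beta`, where `B` is the
#' cubic-regression-spline basis with knots at empirical quantiles of `x`
#' (built with [mgcv::smoothCon()]) and `P` the second-derivative penalty.
#' The penalty nullspace contains constant and linear functions, so the
#' effective degrees of freedom (trace of the smoother matrix) run from 2
#' (`lambda -> Inf`, an ordinary least-squares line) up to `k`
#' (`lambda = 0`, an unpenalized regression spline). `lambda = "gcv"`
#' selects the smoothing parameter by generalized cross-validation,
#' `n * RSS / (n - edf)^2`, over a logarithmic grid scaled to the problem.
#'
#' @param x Numeric predictor (years); needs at least `k` distinct values.
#' @param y Numeric response, same length.
#' @param k Basis dimension (default 10, minimum 4).
#' @param lambda Non-negative smoothing parameter, or `"gcv"`.
#' @param lambda_grid Optional explicit GCV search grid.
#' @return An object of class `"pspline_fit"`: basis and penalty, selected
#'   `lambda`, `coefficients`, `edf`, `sigma2` (residual variance on
#'   `n - edf` df), `fitted`, `gcv`, and the data range for extrapolation
#'   flagging.
#' @export
fit_penalized_spline <- function(x, y, k = 10, lambda = "gcv",
                                 lambda_grid = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (k < 4) stop("fit_penalized_spline: k must be >= 4")
  if (k > n) stop("fit_penalized_spline: k exceeds the number of observations")
  if (length(unique(x)) < k)
    stop("fit_penalized_spline: need at least k distinct x values")
  basis <- make_cr_basis(x, k)
  fit <- pspline_solve(basis$X, y, basis$S, lambda, lambda_grid)
  structure(c(fit, list(basis = basis, x_range = range(x), n = n, y = y)),
            class = "pspline_fit")
}

# Cubic-regression-spline basis with knots at quantiles of x.
make_cr_basis <- function(x, k) {
  sm <- mgcv::smoothCon(mgcv::s(x, k = k, bs = "cr"),
                        data = data.frame(x = x), knots = NULL,
                        absorb.cons = FALSE)[[1]]
  list(sm = sm, X = sm$X, S = sm$S[[1]], k = k)
}

cr_basis_at <- function(basis, xnew) {
  mgcv::PredictMat(basis$sm, data.frame(x = xnew))
}

# Penalized normal-equations solve plus GCV grid search. Shared by the
# user-facing fit and the bootstrap fast path (which indexes precomputed
# basis rows instead of rebuilding the basis).
pspline_solve <- function(X, y, S, lambda = "gcv", lambda_grid = NULL) {
  n <- length(y)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  one_fit <- function(lam) {
    A <- tryCatch(solve(XtX + lam * S),
                  error = function(e)
                    stop("fit_penalized_spline: penalized system is rank ",
                         "deficient (too few distinct x values?)",
                         call. = FALSE))
    beta <- drop(A %*% Xty)
    edf <- sum(diag(A %*% XtX))
    rss <- max(yty - 2 * sum(beta * Xty) + drop(crossprod(beta, XtX %*% beta)),
               0)
    list(A = A, beta = beta, edf = edf, rss = rss,
         gcv = if (n > edf) n * rss / (n - edf)^2 else Inf)
  }
  if (identical(lambda, "gcv")) {
    if (is.null(lambda_grid)) {
      scale <- sum(diag(XtX)) / max(sum(diag(S)), .Machine$double.eps)
      lambda_grid <- scale * 10^seq(-8, 8, length.out = 41)
    }
    fits <- lapply(lambda_grid, one_fit)
    best <- which.min(vapply(fits, `[[`, numeric(1), "gcv"))
    fit <- fits[[best]]
    lam <- lambda_grid[best]
  } else {
    if (!is.numeric(lambda) || lambda < 0)
      stop("fit_penalized_spline: lambda must be non-negative or \"gcv\"")
    fit <- one_fit(lambda)
    lam <- lambda
  }
  sigma2 <- if (n - fit$edf > 0) fit$rss / (n - fit$edf) else NA_real_
  list(coefficients = fit$beta, lambda = lam, edf = fit$edf,
       sigma2 = sigma2, gcv = fit$gcv, A = fit$A, XtX = XtX,
       fitted = drop(X %*% fit$beta))
}

#' Predict a fitted spline curve with pointwise standard errors
#'
#' Model-based frequentist pointwise SEs from the smoother covariance
#' `sigma^2 * A X'X A` with `A = (X'X + lambda P)^-1`. Grid points outside
#' the observed `x` range are flagged as extrapolation.
#'
#' @param fit A [fit_penalized_spline()] result.
#' @param grid Numeric vector of evaluation points.
#' @return Data frame with `x`, `fit`, `se`, `extrapolated`.
#' @export
predict_curve <- function(fit, grid) {
  stopifnot(inherits(fit, "pspline_fit"))
  B <- cr_basis_at(fit$basis, grid)
  pred <- drop(B %*% fit$coefficients)
  M <- B %*% fit$A
  v <- rowSums((M %*% fit$XtX) * M)
  se <- sqrt(pmax(fit$sigma2, 0) * pmax(v, 0))
  data.frame(x = grid, fit = pred, se = se,
             extrapolated = grid < fit$x_range[1] | grid > fit$x_range[2])
}
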