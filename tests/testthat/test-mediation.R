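test_that("fit_ols reproduces exact fits and matches a normal-equations oracle", {
  x <- 1:10
  f <- fit_ols(cbind(x = x), 2 * x + 1)
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-10)

  set.seed(9)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rnorm(50)
  expect_equal(unname(fit_ols(X, y)$coefficients), unname(ne_ols(X, y)),
               tolerance = 1e-8)

  Xc <- cbind(a = rnorm(20), b = 1:20, c = 2 * (1:20))
  expect_error(fit_ols(Xc, rnorm(20)), "collinear.*c")
  expect_error(fit_ols(matrix(rnorm(4), 2, 2), rnorm(2)), "more observations")
})

test_that("a 12-row hand table gives the oracle paths and an exact identity", {
  tab <- data.frame(
    t = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    m = c(2, 5, 5, 9, 11, 12, 16, 15, 19, 22, 21, 25),
    y = c(3, 6, 8, 11, 15, 14, 20, 21, 24, 28, 27, 32),
    z = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1))
  spec <- mediation_spec(treatment = "t", mediator = "m", outcome = "y",
                         covariates = "z")
  est <- estimate_mediation(spec, tab, min_n = 10)
  a_or <- ne_ols(tab[, c("t", "z")], tab$m)[["t"]]
  fy <- ne_ols(tab[, c("t", "m", "z")], tab$y)
  expect_equal(est$paths[["a"]], a_or, tolerance = 1e-10)
  expect_equal(est$paths[["b"]], fy[["m"]], tolerance = 1e-10)
  expect_equal(est$ade, fy[["t"]], tolerance = 1e-10)
  expect_equal(est$acme, a_or * fy[["m"]], tolerance = 1e-10)
  # algebraic identity: ACME + ADE equals the total-effect regression slope
  te_or <- ne_ols(tab[, c("t", "z")], tab$y)[["t"]]
  expect_equal(est$acme + est$ade - est$total_effect, 0, tolerance = 1e-12)
  expect_equal(est$total_effect, te_or, tolerance = 1e-10)
  expect_equal(est$analysis_n, 12)
})

test_that("the ACME + ADE = total effect identity holds on random designs", {
  set.seed(10)
  for (i in 1:20) {
    n <- 60
    tab <- data.frame(t = rnorm(n), z1 = rnorm(n), z2 = rbinom(n, 1, 0.4))
    tab$m <- 0.5 * tab$t + 0.3 * tab$z1 + rnorm(n)
    tab$y <- 0.4 * tab$m + 0.3 * tab$t - 0.2 * tab$z2 + rnorm(n)
    est <- estimate_mediation(
      mediation_spec(treatment = "t", mediator = "m", outcome = "y",
                     covariates = c("z1", "z2")), tab)
    expect_lt(abs(est$acme + est$ade - est$total_effect), 1e-10)
  }
})

test_that("null (b = 0) and full (c' = 0) mediation limits are recovered", {
  set.seed(11)
  n <- 2000
  tab <- data.frame(t = rnorm(n))
  tab$m <- 0.8 * tab$t + rnorm(n)
  tab$y_null <- 0.5 * tab$t + rnorm(n)          # b = 0
  tab$y_full <- 0.6 * tab$m + rnorm(n)          # c' = 0
  s_null <- mediation_spec(treatment = "t", mediator = "m",
                           outcome = "y_null", covariates = character(),
                           n_bootstrap = 400, seed = 2L)
  m_null <- bootstrap_mediation(s_null, tab)
  expect_lt(abs(m_null$proportion_mediated), 0.05)
  expect_true(m_null$ci["acme", "low"] <= 0 & 0 <= m_null$ci["acme", "high"])
  s_full <- mediation_spec(treatment = "t", mediator = "m",
                           outcome = "y_full", covariates = character(),
                           n_bootstrap = 400, seed = 2L)
  m_full <- bootstrap_mediation(s_full, tab)
  expect_lt(abs(m_full$proportion_mediated - 1), 0.05)
})

test_that("rescaling the mediator leaves every effect unchanged", {
  sim <- generate_cohort(mediation_recovery_config(0.4, seed = 6L))
  ds <- sim$cohort[sim$cohort$group == "DS", ]
  spec <- mediation_spec(outcome = "tau_suvr", n_bootstrap = 200, seed = 3L)
  m1 <- bootstrap_mediation(spec, ds)
  ds2 <- ds; ds2$gfap <- ds2$gfap * 10
  m2 <- bootstrap_mediation(spec, ds2)
  for (q in c("acme", "ade", "total_effect", "proportion_mediated"))
    expect_equal(m1[[q]], m2[[q]], tolerance = 1e-8)
  expect_equal(m1$ci, m2$ci, tolerance = 1e-6)
  expect_equal(m2$paths[["a"]], 10 * m1$paths[["a"]], tolerance = 1e-8)
})

test_that("bootstrap mediation is deterministic given the seed", {
  sim <- generate_cohort(mediation_recovery_config(0.4, seed = 7L))
  ds <- sim$cohort[sim$cohort$group == "DS", ]
  spec <- mediation_spec(outcome = "tau_suvr", n_bootstrap = 150, seed = 12L)
  m1 <- bootstrap_mediation(spec, ds)
  m2 <- bootstrap_mediation(spec, ds)
  expect_identical(m1$ci, m2$ci)
  expect_identical(m1$p_values, m2$p_values)
})

test_that("proportion mediated is recovered across the configured effect grid", {
  for (pm in c(0.15, 0.4, 0.8)) {
    ests <- vapply(1:4, function(s) {
      cfg <- if (pm %in% c(0.15, 0.4)) mediation_recovery_config(pm, seed = s)
      else {
        cfg <- mediation_recovery_config(0.4, seed = s)
        # rebuild for pm = 0.8: a = 0.5, b = 0.4 -> c' = ab/pm - ab
        cfg$mediation$tau_suvr$c_prime <- 0.2 / 0.8 - 0.2
        cfg$mediation$ptau217$c_prime <- 0.2 / 0.8 - 0.2
        cfg
      }
      sim <- generate_cohort(cfg)
      ds <- sim$cohort[sim$cohort$group == "DS", ]
      estimate_mediation(mediation_spec(outcome = "tau_suvr"),
                         ds)$proportion_mediated
    }, numeric(1))
    expect_lt(abs(mean(ests) - pm), 0.05)
  }
})

test_that("near-zero total effects trip the stability flag", {
  set.seed(13)
  n <- 150
  tab <- data.frame(t = rnorm(n))
  tab$m <- 0.5 * tab$t + rnorm(n)
  tab$y <- 0.25 * tab$m - 0.125 * tab$t + rnorm(n)  # total effect ~ 0
  m <- bootstrap_mediation(
    mediation_spec(treatment = "t", mediator = "m", outcome = "y",
                   covariates = character(), n_bootstrap = 200, seed = 5L),
    tab, te_tolerance = 0.05)
  expect_true(m$stability_flag)
  expect_gt(m$dropped_pm_fraction, 0.01)
})

test_that("covariate choice changes estimates only through the covariate path", {
  # echo of the robustness claim: with APOE effects absent from the
  # generator, dropping the APOE covariate leaves conclusions intact
  sim <- generate_cohort(mediation_recovery_config(0.4, seed = 15L))
  ds <- sim$cohort[sim$cohort$group == "DS", ]
  with_apoe <- estimate_mediation(mediation_spec(outcome = "tau_suvr"), ds)
  without <- estimate_mediation(
    mediation_spec(outcome = "tau_suvr",
                   covariates = c("latency_days", "sex")), ds)
  expect_lt(abs(with_apoe$proportion_mediated - without$proportion_mediated),
            0.02)
})
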