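# Small cohorts used across tests; sizes chosen so the whole suite stays fast.
tiny_cohort <- function(seed = 1L, n_ds = 120, n_controls = 60) {
  generate_cohort(cohort_config(n_ds = n_ds, n_controls = n_controls,
                                seed = seed))
}

# independent normal-equations OLS oracle (pseudo-inverse, no lm machinery)
ne_ols <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  drop(solve(t(X) %*% X, t(X) %*% y))
}
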