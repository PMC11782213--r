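test_that("exact Wilcoxon enumeration matches hand counts and stats oracle", {
  # complete separation: 2 of the 20 equally likely rank assignments are as
  # extreme, so the doubled one-sided p is 0.1
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$p_value, 0.1)
  expect_equal(r$statistic, 6)

  # identical samples: perfectly symmetric, p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 5, 9), c(2, 5, 9), mode = "exact")$p_value, 1)

  # agreement with the independent exact distribution in stats (tie-free)
  set.seed(11)
  for (i in 1:10) {
    x <- sample(100, 6); y <- sample(200, 7) + 0.5
    ours <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(1:15, 1:15, mode = "exact"), "<= 20")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("degenerate all-tied data is flagged with p = 1", {
  r <- wilcoxon_rank_sum(rep(3, 5), rep(3, 4), mode = "exact")
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  kr <- kruskal_wallis(list(rep(1, 5), rep(1, 6)))
  expect_true(kr$degenerate)
  expect_equal(kr$p_value, 1)
})

test_that("normal approximation stays close to the exact p for small samples", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(sample(8:10, 1))
    y <- rnorm(sample(8:10, 1), mean = runif(1, 0, 2))
    pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    pn <- wilcoxon_rank_sum(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("a one-SD shift at n = 200 is overwhelmingly significant", {
  set.seed(3)
  x <- rnorm(200); y <- rnorm(200, 1)
  expect_lt(wilcoxon_rank_sum(x, y)$p_value, 1e-6)
})

test_that("Hodges-Lehmann estimate is the median pairwise difference", {
  expect_equal(hodges_lehmann_shift(c(1, 2, 3), c(3, 4, 5))$estimate, -2)
  x <- c(4.2, 7.5, 1.1, 9)
  expect_equal(hodges_lehmann_shift(x, x + 2.5)$estimate, -2.5)
  # equivariance: adding c to x shifts the estimate by exactly c
  set.seed(8)
  a <- rnorm(15); b <- rnorm(12)
  h0 <- hodges_lehmann_shift(a, b)
  h1 <- hodges_lehmann_shift(a + 1.7, b)
  expect_equal(h1$estimate, h0$estimate + 1.7)
  expect_equal(h1$ci_low, h0$ci_low + 1.7)
})

test_that("inversion CI matches the order-statistic oracle and stats", {
  set.seed(5)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  h <- hodges_lehmann_shift(x, y, ci_level = 0.95)
  # oracle: walk the ordered pairwise differences at the exact Mann-Whitney
  # critical value
  d <- sort(as.vector(outer(x, y, "-")))
  k <- max(stats::qwilcox(0.025, 10, 12), 1)
  expect_equal(h$ci_low, d[k])
  expect_equal(h$ci_high, d[10 * 12 - k + 1])
  ref <- stats::wilcox.test(x, y, conf.int = TRUE, exact = TRUE)
  expect_equal(as.numeric(ref$conf.int), c(h$ci_low, h$ci_high),
               tolerance = 1e-8)
  expect_true(h$ci_low <= h$estimate && h$estimate <= h$ci_high)
  # bootstrap method is seeded and reproducible
  b1 <- hodges_lehmann_shift(x, y, method = "bootstrap", seed = 4L)
  b2 <- hodges_lehmann_shift(x, y, method = "bootstrap", seed = 4L)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$estimate && b1$estimate <= b1$ci_high)
})

test_that("Kruskal-Wallis equals the hand-ranked formula and the Wilcoxon limit", {
  # ranks 1..9 in three groups: H = 12/(9*10) * sum(R_g^2/3) - 3*10 = 7.2
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  # two-group case agrees with the tie-corrected normal Wilcoxon
  set.seed(12)
  x <- rnorm(40); y <- rnorm(35, 0.4)
  expect_lt(abs(kruskal_wallis(list(x, y))$p_value -
                  wilcoxon_rank_sum(x, y, mode = "normal")$p_value), 0.01)
  expect_error(kruskal_wallis(list(1:3)), "groups")
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  pvals <- vapply(1:150, function(s) {
    set.seed(s + 4000)
    kruskal_wallis(list(rnorm(30), rnorm(30), rnorm(30)))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, family_size = 3), 0.03)
  expect_equal(bonferroni_adjust(c(0.5, 0.9)), c(1, 1))
  p <- runif(10)
  expect_true(all(bonferroni_adjust(p, 6) >= p))
  expect_error(bonferroni_adjust(c(0.2, 1.3)), "\\[0,1\\]")
})

test_that("2x2 chi-square matches the expected-count formula", {
  even <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  # sex-by-group counts: 33/9 female/male controls, 157/191 in DS
  tab <- matrix(c(33, 9, 157, 191), 2, 2)
  hand <- {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  got <- chi_square_2x2(tab)
  expect_equal(got$statistic, hand, tolerance = 1e-12)
  expect_lt(got$p_value, 0.001)
  # doubling every cell doubles the uncorrected statistic
  expect_equal(chi_square_2x2(2 * tab)$statistic, 2 * hand, tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("pathology-group comparison reports every testable pair once", {
  sim <- tiny_cohort(seed = 14L, n_ds = 300, n_controls = 42)
  at <- build_analysis_table(sim$cohort)
  cc <- compare_by_pathology_group(at, "gfap")
  groups <- c("control", "A-/T-", "A+/T-", "A+/T+")
  counts <- vapply(groups, function(g)
    sum(at$table$combined_label == g & !is.na(at$table$gfap)), integer(1))
  testable <- sum(utils::combn(counts, 2, function(p) all(p >= 2)))
  expect_equal(nrow(cc$pairwise), testable)
  expect_equal(cc$family_size, 6)
  expect_true(all(cc$pairwise$adjusted_p >= cc$pairwise$raw_p))
  expect_true(all(cc$pairwise$hl_ci_low <= cc$pairwise$hl_shift &
                    cc$pairwise$hl_shift <= cc$pairwise$hl_ci_high))
})

test_that("pairs with fewer than two observations are skipped and logged", {
  co <- data.frame(
    participant_id = paste0("P", 1:30),
    group = c(rep("control", 10), rep("DS", 20)),
    age = 40, sex = "female", apoe4 = "non-carrier",
    centiloid = c(rep(5, 10), rep(c(5, 30), 10)),
    tau_suvr = 1.1, gfap = rnorm(30, 100), ptau217 = 0.2, latency_days = 0L)
  at <- build_analysis_table(co)
  cc <- compare_by_pathology_group(at, "gfap")
  expect_true(any(grepl("A\\+/T\\+", cc$skipped)))
  expect_equal(nrow(cc$pairwise) + length(cc$skipped), 6)
})

test_that("demographic summary reproduces within-group percentages", {
  co <- data.frame(
    participant_id = paste0("P", 1:10),
    group = rep(c("control", "DS"), each = 5),
    age = 40, sex = c("female", "female", "male", "male", "male",
                      rep("female", 4), "male"),
    apoe4 = c(rep("carrier", 2), rep("non-carrier", 8)),
    centiloid = c(NA, 1:9), tau_suvr = 1, gfap = 1, ptau217 = 1,
    latency_days = 0L)
  dem <- suppressWarnings(summarize_demographics(co))  # small-count chi-square
  s <- dem$summary
  expect_equal(s$pct[s$variable == "sex" & s$group == "control"], 40)
  expect_equal(s$pct[s$variable == "sex" & s$group == "DS"], 80)
  expect_equal(s$n[s$variable == "available" & s$level == "centiloid" &
                     s$group == "control"], 4)
  expect_true(all(c("chi-square", "kruskal-wallis") %in% dem$tests$test))
})
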