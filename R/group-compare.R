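#' Two-sample Wilcoxon rank-sum test
#'
#' `mode = "exact"` enumerates all rank assignments of the pooled sample
#' (feasible for `n_a + n_b <= 20`; ties are handled by average ranks) and
#' reports the doubled one-sided tail probability. `mode = "normal"` uses
#' the tie-corrected normal approximation with continuity correction via
#' [stats::wilcox.test()]. Two-sided throughout.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"exact"` or `"normal"`.
#' @return A list with `statistic` (rank sum of `x`), `p_value`, `mode` and
#'   `degenerate` (TRUE when every pooled value is tied, in which case
#'   `p_value` is 1).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("wilcoxon_rank_sum: both samples must be non-empty")
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  r <- rank(pooled)
  W <- sum(r[seq_len(m)])
  if (length(unique(pooled)) == 1L)
    return(list(statistic = W, p_value = 1, mode = mode, degenerate = TRUE))
  if (mode == "exact") {
    if (m + n > 20)
      stop("wilcoxon_rank_sum: exact enumeration limited to n_a + n_b <= 20")
    idx <- utils::combn(m + n, m)
    sums <- colSums(matrix(r[idx], nrow = m))
    # guard against floating ties in average ranks
    eps <- 1e-8
    p <- 2 * min(mean(sums <= W + eps), mean(sums >= W - eps))
    p <- min(1, p)
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  list(statistic = W, p_value = p, mode = mode, degenerate = FALSE)
}

#' Hodges-Lehmann location-shift estimate with confidence interval
#'
#' Point estimate is the median of all `n_a * n_b` pairwise differences
#' `x_i - y_j`, the standard companion to the Wilcoxon rank-sum test.
#' `method = "inversion"` inverts the rank-sum test: the CI endpoints are
#' order statistics of the pairwise differences at the Mann-Whitney critical
#' values (normal-approximation critical values beyond the exact range).
#' `method = "bootstrap"` gives a seeded percentile interval over
#' participant resamples, useful when heavy ties make inversion
#' conservative.
#'
#' @param x,y Non-empty numeric samples.
#' @param ci_level Confidence level (default 0.95).
#' @param method `"inversion"` or `"bootstrap"`.
#' @param n_bootstrap,seed Bootstrap controls (bootstrap method only).
#' @return List with `estimate`, `ci_low`, `ci_high`, `ci_level`, `method`.
#' @export
hodges_lehmann_shift <- function(x, y, ci_level = 0.95,
                                 method = c("inversion", "bootstrap"),
                                 n_bootstrap = 2000, seed = 1L) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("hodges_lehmann_shift: both samples must be non-empty")
  m <- length(x); n <- length(y)
  diffs <- sort(as.vector(outer(x, y, "-")))
  est <- stats::median(diffs)
  alpha <- 1 - ci_level
  if (method == "inversion") {
    # endpoints D_(k) and D_(mn - k + 1), k the smallest Mann-Whitney
    # quantile with null CDF >= alpha/2 (guarantees >= nominal coverage)
    if (m * n <= 1e6 && m <= 1000 && n <= 1000) {
      k <- stats::qwilcox(alpha / 2, m, n)
    } else {
      mu <- m * n / 2
      sigma <- sqrt(m * n * (m + n + 1) / 12)
      k <- floor(stats::qnorm(alpha / 2, mu, sigma))
    }
    k <- min(max(k, 1), floor((m * n + 1) / 2))
    lo <- diffs[k]
    hi <- diffs[m * n - k + 1]
  } else {
    qs <- withr::with_seed(seed, {
      boot <- replicate(n_bootstrap, {
        xb <- sample(x, m, replace = TRUE)
        yb <- sample(y, n, replace = TRUE)
        stats::median(as.vector(outer(xb, yb, "-")))
      })
      stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    })
    lo <- qs[1]; hi <- qs[2]
  }
  list(estimate = est, ci_low = lo, ci_high = hi,
       ci_level = ci_level, method = method)
}

#' Kruskal-Wallis omnibus rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k-1 degrees of
#' freedom (via [stats::kruskal.test()]). When every observation across all
#' groups is identical the data carry no rank information; the result is
#' flagged degenerate with `p_value = 1`.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with `statistic`, `df`, `p_value`, `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(!lengths(groups)))
    stop("kruskal_wallis: need >= 2 non-empty groups")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                degenerate = TRUE))
  kt <- stats::kruskal.test(pooled,
                            factor(rep(seq_along(groups), lengths(groups))))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, degenerate = FALSE)
}

#' Bonferroni multiple-comparison adjustment
#'
#' Each p-value is multiplied by the family size and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param family_size Number of comparisons in the family (default
#'   `length(p_values)`).
#' @return Adjusted p-values, order-preserving.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("bonferroni_adjust: p-values must lie in [0,1]")
  pmin(1, p_values * family_size)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' @param table 2x2 matrix of non-negative integer counts with no zero
#'   margin.
#' @param correction Apply the Yates continuity correction (default FALSE).
#' @return List with `statistic`, `df`, `p_value`, `correction`.
#' @export
chi_square_2x2 <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop("chi_square_2x2: need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("chi_square_2x2: counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi_square_2x2: zero margin")
  ct <- stats::chisq.test(table, correct = correction)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, correction = correction)
}

#' Compare a plasma biomarker across A/T pathology groups
#'
#' Omnibus Kruskal-Wallis across the groups present (canonically control,
#' A-/T-, A+/T-, A+/T+; discordant A-/T+ rows are removed upstream by
#' [build_analysis_table()]), followed by all pairwise Wilcoxon rank-sum
#' tests with Bonferroni correction over the full pairwise family, each
#' with a Hodges-Lehmann shift estimate and CI. Pairs where either group
#' has fewer than 2 observed values are skipped and logged.
#'
#' @param analysis_table An [build_analysis_table()] result (or its
#'   `$table`).
#' @param biomarker Column name to compare (e.g. `"gfap"`).
#' @param ci_level CI level for the shift estimates.
#' @param groups Group labels, in display order, to include.
#' @return List with `omnibus` ([kruskal_wallis()] result), `pairwise`
#'   (data frame: one row per tested pair with counts, rank-sum statistic,
#'   raw and Bonferroni-adjusted p, HL shift and CI), `family_size`, and
#'   `skipped` (labels of pairs not tested).
#' @export
compare_by_pathology_group <- function(analysis_table, biomarker,
                                       ci_level = 0.95,
                                       groups = c("control", "A-/T-",
                                                  "A+/T-", "A+/T+")) {
  tab <- if (inherits(analysis_table, "analysis_table"))
    analysis_table$table else analysis_table
  if (!biomarker %in% names(tab))
    stop("compare_by_pathology_group: no column '", biomarker, "'")
  samples <- lapply(groups, function(g) {
    v <- tab[[biomarker]][tab$combined_label == g]
    v[!is.na(v)]
  })
  names(samples) <- groups
  present <- lengths(samples) >= 2
  omnibus <- kruskal_wallis(samples[present])

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  family_size <- length(pairs)
  rows <- list(); skipped <- character()
  for (pr in pairs) {
    xa <- samples[[pr[1]]]; xb <- samples[[pr[2]]]
    if (length(xa) < 2 || length(xb) < 2) {
      skipped <- c(skipped, paste(pr, collapse = " vs "))
      next
    }
    wt <- wilcoxon_rank_sum(xa, xb, mode = "normal")
    hl <- hodges_lehmann_shift(xa, xb, ci_level = ci_level)
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = pr[1], group_b = pr[2],
      n_a = length(xa), n_b = length(xb),
      rank_sum_statistic = wt$statistic,
      raw_p = wt$p_value, adjusted_p = NA_real_,
      hl_shift = hl$estimate, hl_ci_low = hl$ci_low,
      hl_ci_high = hl$ci_high, ci_level = ci_level,
      stringsAsFactors = FALSE)
  }
  pairwise <- do.call(rbind, rows)
  if (!is.null(pairwise))
    pairwise$adjusted_p <- bonferroni_adjust(pairwise$raw_p, family_size)
  list(omnibus = omnibus, pairwise = pairwise,
       family_size = family_size, skipped = skipped)
}

#' Demographic summary by group
#'
#' Counts and within-group percentages for sex, APOE e4 carriage and
#' per-modality biomarker availability, plus between-group tests: Pearson
#' chi-square (corrected and uncorrected) for the categorical variables and
#' Kruskal-Wallis for age.
#'
#' @param cohort Cohort data frame.
#' @return List with `summary` (data frame: `variable`, `level`, `group`,
#'   `n`, `pct`) and `tests` (data frame of test results).
#' @export
summarize_demographics <- function(cohort) {
  grp <- cohort$group
  group_n <- table(grp)
  rows <- list()
  add <- function(variable, level, flag) {
    for (g in names(group_n)) {
      n <- sum(flag & grp == g, na.rm = TRUE)
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, level = level, group = g, n = n,
        pct = 100 * n / as.integer(group_n[[g]]), stringsAsFactors = FALSE)
    }
  }
  add("sex", "female", cohort$sex == "female")
  add("apoe4", "carrier", cohort$apoe4 == "carrier")
  for (col in intersect(c("centiloid", "tau_suvr", "gfap", "ptau217"),
                        names(cohort)))
    add("available", col, !is.na(cohort[[col]]))
  summary <- do.call(rbind, rows)

  tests <- list()
  cat_test <- function(variable, flag) {
    tb <- table(factor(flag, c(FALSE, TRUE)), grp)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) return()
    for (corr in c(FALSE, TRUE)) {
      ct <- chi_square_2x2(tb, correction = corr)
      tests[[length(tests) + 1L]] <<- data.frame(
        variable = variable,
        test = if (corr) "chi-square (Yates)" else "chi-square",
        statistic = ct$statistic, p_value = ct$p_value,
        stringsAsFactors = FALSE)
    }
  }
  cat_test("sex", cohort$sex == "female")
  cat_test("apoe4", cohort$apoe4 == "carrier")
  if (length(unique(grp)) >= 2) {
    kw <- kruskal_wallis(split(cohort$age, grp))
    tests[[length(tests) + 1L]] <- data.frame(
      variable = "age", test = "kruskal-wallis",
      statistic = kw$statistic, p_value = kw$p_value,
      stringsAsFactors = FALSE)
  }
  list(summary = summary, tests = do.call(rbind, tests))
}
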