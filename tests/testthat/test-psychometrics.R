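test_that("Cronbach's alpha hits its closed-form landmarks", {
  # J identical copies of a varying item: perfect internal consistency
  col <- c(1, 2, 4, 5)
  expect_equal(cronbach_alpha(cbind(col, col, col)), 1)
  # two items with zero sample covariance: alpha = 0
  m0 <- cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(cronbach_alpha(m0), 0)
  # hand-computed fixture (covariance-matrix arithmetic done independently)
  m <- rbind(c(1, 2, 3), c(2, 4, 4), c(3, 3, 5), c(4, 5, 5))
  expect_equal(cronbach_alpha(m), 0.9160305343511449, tolerance = 1e-12)
})

test_that("alpha agrees with the covariance-matrix oracle on random matrices", {
  set.seed(42)
  for (rep in 1:25) {
    m <- random_matrix(sample(4:12, 1), sample(2:8, 1))
    if (stats::var(rowSums(m)) == 0) next
    expect_equal(cronbach_alpha(m), alpha_cov_oracle(m), tolerance = 1e-12)
  }
})

test_that("alpha rejects degenerate input", {
  expect_error(cronbach_alpha(matrix(1:4, ncol = 1)), "2 items")
  expect_error(cronbach_alpha(matrix(1:4, nrow = 1)), "2 respondents")
  const <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_error(cronbach_alpha(const), "variance is zero")
})

test_that("reliability stats satisfy the SEM identity", {
  set.seed(7)
  m <- trait_matrix(30, 6)
  st <- estimate_reliability(m)
  expect_gt(st$alpha, 0)
  expect_equal(st$sem, st$sd_score * sqrt(1 - st$alpha))
  expect_equal(st$mean_score, mean(rowSums(m)))
  expect_equal(st$sd_score, stats::sd(rowSums(m)))
  expect_equal(st$n_respondents, 30L)
  # alpha = 1: zero measurement error
  col <- c(1, 2, 4, 5)
  expect_equal(estimate_reliability(cbind(col, col))$sem, 0)
  # alpha = 0: SEM equals the score SD
  m0 <- cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))
  st0 <- estimate_reliability(m0)
  expect_equal(st0$sem, st0$sd_score)
})

test_that("SEM is monotone decreasing in alpha for fixed score SD", {
  alphas <- seq(0, 1, by = 0.1)
  sems <- vapply(alphas, function(a) make_stats(a, 20, 4)$sem, numeric(1))
  expect_true(all(diff(sems) < 0))
  expect_equal(make_stats(0.75, 20, 4)$sem, 2)  # 4 * sqrt(0.25)
})

test_that("negative alpha is reported but clamped for the SEM", {
  # anti-consistent items: near-reflected columns (totals not constant)
  m <- cbind(c(1, 5, 2, 4), c(5, 1, 4, 3))
  expect_lt(cronbach_alpha(m), 0)
  expect_warning(st <- estimate_reliability(m), "negative")
  expect_true(st$alpha_clamped)
  expect_equal(st$sem, st$sd_score)   # clamp: sqrt(1 - 0)
})

test_that("the true-score estimate shrinks the observed score to the mean", {
  expect_equal(ets_true_score(30, make_stats(0.8, 25, 4)), 29)
  expect_equal(ets_true_score(30, make_stats(1, 25, 4)), 30)   # no shrinkage
  expect_equal(ets_true_score(30, make_stats(0, 25, 4)), 25)   # full shrinkage
  # monotone in X and between X and the mean for alpha in [0, 1]
  st <- make_stats(0.6, 25, 4)
  xs <- seq(5, 45, by = 5)
  vs <- ets_true_score(xs, st)
  expect_true(all(diff(vs) > 0))
  expect_true(all(vs >= pmin(xs, 25) & vs <= pmax(xs, 25)))
})

test_that("ETS intervals match the printed arithmetic under paper rounding", {
  st <- make_stats(0.8, 25, 2 / sqrt(1 - 0.8))  # sem = 2
  expect_equal(st$sem, 2)
  ci <- ets_interval(30, st, 0.95, paper_rounding = TRUE)
  expect_equal(ci$center, 29)
  expect_equal(c(ci$lower, ci$upper), c(29 - 1.96 * 2, 29 + 1.96 * 2))
  expect_equal(c(ci$lower, ci$upper), c(25.08, 32.92))
  # exact quantile mode differs in the 3rd decimal
  ci2 <- ets_interval(30, st, 0.95)
  expect_equal(ci2$upper, 29 + stats::qnorm(0.975) * 2)
  expect_false(identical(ci$upper, ci2$upper))
})

test_that("ETS interval width is constant across respondents", {
  set.seed(13)
  st <- make_stats(0.85, 70, 9)
  widths <- vapply(sample(40:100, 20), function(x) {
    ci <- ets_interval(x, st, 0.95)
    ci$upper - ci$lower
  }, numeric(1))
  expect_equal(max(widths) - min(widths), 0)
  expect_equal(widths[1], 2 * stats::qnorm(0.975) * st$sem)
})

test_that("zero SEM collapses the ETS interval to a point", {
  ci <- ets_interval(12, make_stats(1, 10, 3))
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$lower, 12)
})

test_that("one-sided ETS intervals put the other bound at the scale limit", {
  sp <- scale_spec(8, 1, 5)
  st <- make_stats(0.8, 25, 2 / sqrt(0.2))
  up <- ets_interval(30, st, 0.95, "upper_only", sp, paper_rounding = TRUE)
  expect_equal(up$lower, 8)            # J * scale_min
  expect_equal(up$upper, 29 + 1.64 * st$sem)
  lo <- ets_interval(30, st, 0.95, "lower_only", sp, paper_rounding = TRUE)
  expect_equal(lo$upper, 40)           # J * scale_max
  expect_equal(lo$lower, 29 - 1.64 * st$sem)
  expect_error(ets_interval(30, st, 0.95, "upper_only"), "spec")
})

test_that("ETS bounds are not clipped and out-of-range limits are flagged", {
  sp <- scale_spec(4, 1, 5)   # scores in [4, 20]
  st <- make_stats(0.5, 18, 6)
  ci <- ets_interval(20, st, 0.95, spec = sp)
  expect_gt(ci$upper, 20)     # exceeds the maximum possible score
  expect_true(ci$out_of_range)
  ci_in <- ets_interval(12, make_stats(0.99, 12, 2), spec = sp)
  expect_false(ci_in$out_of_range)
})

test_that("invalid confidence levels are rejected", {
  st <- make_stats(0.8, 25, 4)
  expect_error(ets_interval(30, st, level = 0), "level")
  expect_error(ets_interval(30, st, level = 1), "level")
})
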