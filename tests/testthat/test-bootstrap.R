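test_that("constant response vectors are recognised as degenerate", {
  expect_true(is_degenerate(c(3, 3, 3, 3)))
  expect_false(is_degenerate(c(3, 3, 3, 4)))
  v <- rep(2, 24); v[17] <- 3
  expect_false(is_degenerate(v))
})

test_that("bootstrapping a degenerate vector raises a typed error", {
  err <- tryCatch(bsi(rep(3, 8), seed = 1), condition = identity)
  expect_s3_class(err, "itemboot_degenerate")
  expect_match(conditionMessage(err), "same response")
  err2 <- tryCatch(bsi_interval(rep(5, 8), seed = 1, id = "p07"),
                   condition = identity)
  expect_match(conditionMessage(err2), "p07")
})

test_that("the bootstrap distribution is reproducible and well-formed", {
  v <- c(1, 2, 2, 3, 4, 5, 3, 2)
  d1 <- bsi(v, B = 500, seed = 99)
  d2 <- bsi(v, B = 500, seed = 99)
  expect_identical(d1$scores, d2$scores)
  expect_length(d1$scores, 500)
  expect_false(is.unsorted(d1$scores))
  expect_equal(d1$observed, sum(v))
  d3 <- bsi(v, B = 500, seed = 100)
  expect_false(identical(d1$scores, d3$scores))
  expect_identical(bsi_interval(v, B = 500, seed = 99),
                   bsi_interval(v, B = 500, seed = 99))
})

test_that("resampled scores respect the attainable score bounds", {
  set.seed(31)
  for (rep in 1:30) {
    J <- sample(3:24, 1)
    v <- random_rv(J)
    d <- bsi(v, B = 200, seed = sample.int(1e6, 1))
    expect_gte(min(d$scores), J * min(v))
    expect_lte(max(d$scores), J * max(v))
  }
})

test_that("resampling moments match the empirical-distribution theory", {
  # resampled score = sum of J iid draws from the empirical distribution,
  # so mean = J * mean(v) and variance = J * var_pop(v)
  v <- c(1, 2, 3)
  J <- 3
  mu <- J * mean(v)
  var_pop <- mean((v - mean(v))^2)
  sigma2 <- J * var_pop
  d <- bsi(v, B = 20000, seed = 8)
  se_mean <- sqrt(sigma2 / d$B)
  expect_lt(abs(mean(d$scores) - mu), 4 * se_mean)
  expect_lt(abs(stats::var(d$scores) - sigma2), 4 * sigma2 * sqrt(2 / d$B))
})

test_that("percentile intervals read the stated empirical percentiles", {
  v <- c(1, 2, 2, 4, 5, 3)
  d <- bsi(v, B = 3000, seed = 5)
  ci <- percentile_interval(d, 0.95)
  expect_equal(ci$lower, unname(stats::quantile(d$scores, 0.025, type = 7)))
  expect_equal(ci$upper, unname(stats::quantile(d$scores, 0.975, type = 7)))
  expect_equal(ci$method, "BSI_percentile")
  expect_equal(ci$center, sum(v))
  # one-sided: single stated percentile, other bound at the scale limit
  sp <- scale_spec(6, 1, 5)
  up <- percentile_interval(d, 0.95, "upper_only", sp)
  expect_equal(up$upper, unname(stats::quantile(d$scores, 0.95, type = 7)))
  expect_equal(up$lower, 6)
  lo <- percentile_interval(d, 0.95, "lower_only", sp)
  expect_equal(lo$lower, unname(stats::quantile(d$scores, 0.05, type = 7)))
  expect_equal(lo$upper, 30)
})

test_that("a constant bootstrap distribution gives a zero-width interval", {
  d <- make_dist(rep(12, 1000), values = c(2, 2, 4, 4))
  ci <- percentile_interval(d, 0.95)
  expect_equal(ci$lower, 12)
  expect_equal(ci$upper, 12)
})

test_that("percentile bounds match the exact enumeration oracle for small J", {
  for (v in list(c(1, 2, 3), c(1, 1, 4, 5))) {
    exact <- enumerate_resample_scores(v)   # J^J equally likely outcomes
    lo_exact <- unname(stats::quantile(exact, 0.025, type = 7))
    hi_exact <- unname(stats::quantile(exact, 0.975, type = 7))
    d <- bsi(v, B = 20000, seed = 17)
    ci <- percentile_interval(d, 0.95)
    expect_lt(abs(ci$lower - lo_exact), 1)
    expect_lt(abs(ci$upper - hi_exact), 1)
  }
})

test_that("BCa reduces to the percentile interval when z0 = 0 and a = 0", {
  # symmetric scores around the observed total, half strictly below;
  # symmetric response values make the jackknife skewness vanish
  v <- c(1, 2, 2, 3)        # observed 8
  scores <- rep(c(6, 7, 9, 10), 250)
  d <- make_dist(scores, values = v, observed = 8)
  bca <- bca_interval(d, 0.95)
  pct <- percentile_interval(d, 0.95)
  p <- attr(bca, "bca")
  expect_equal(p$z0, 0)
  expect_equal(p$a, 0)
  expect_equal(bca$lower, pct$lower)
  expect_equal(bca$upper, pct$upper)
})

test_that("the bias correction counts strictly below, so ties do not inflate z0", {
  v <- c(1, 2, 2, 3)
  # 300 below, 400 equal to the observed score, 300 above
  scores <- c(rep(6, 300), rep(8, 400), rep(10, 300))
  d <- make_dist(scores, values = v, observed = 8)
  p <- attr(bca_interval(d, 0.95), "bca")
  expect_equal(p$z0, stats::qnorm(300 / 1000))
})

test_that("an undefined bias correction falls back to the percentile interval", {
  v <- c(1, 2, 2, 3)
  scores <- rep(8, 1000) + sample(0:2, 1000, replace = TRUE)  # none below 8
  d <- make_dist(scores, values = v, observed = 8)
  expect_warning(ci <- bca_interval(d, 0.95), "percentile")
  pct <- percentile_interval(d, 0.95)
  expect_equal(ci$lower, pct$lower)
  expect_equal(ci$upper, pct$upper)
  expect_equal(ci$method, "BSI_bca")
})

test_that("zero jackknife variance sets the acceleration to zero", {
  d <- make_dist(c(rep(7, 500), rep(9, 500)), values = c(2, 2, 2, 2),
                 observed = 8)
  expect_warning(ci <- bca_interval(d, 0.95), "jackknife")
  expect_equal(attr(ci, "bca")$a, 0)
})

test_that("BCa bounds match an independent reference implementation", {
  # reference computed once with an independent numpy/scipy BCa
  # implementation on the identical frozen bootstrap distribution
  d <- bsi(c(1, 1, 2, 3, 5), B = 2000, seed = 20240117)
  ci <- bca_interval(d, 0.95)
  p <- attr(ci, "bca")
  expect_equal(p$z0, -0.0576844251, tolerance = 1e-8)
  expect_equal(p$a, 0.0544255885, tolerance = 1e-8)
  expect_equal(p$adjusted, c(0.0303486484, 0.9805048246), tolerance = 1e-8)
  expect_equal(ci$lower, 6, tolerance = 1e-8)
  expect_equal(ci$upper, 19, tolerance = 1e-8)
})

test_that("heterogeneous responses give wider intervals at equal total score", {
  # same observed score 24 on 8 items; spread-out responses vs packed ones
  hetero <- c(1, 1, 2, 3, 4, 4, 5, 4)
  homo <- c(3, 3, 3, 3, 3, 3, 3, 3 + 0)  # adjust one item to avoid degeneracy
  homo[8] <- 2; homo[1] <- 4
  expect_equal(sum(hetero), sum(homo))
  widths <- vapply(1:21, function(s) {
    wh <- function(v) {
      ci <- bsi_interval(v, B = 1000, seed = s, method = "percentile")
      ci$upper - ci$lower
    }
    wh(hetero) - wh(homo)
  }, numeric(1))
  expect_gte(stats::median(widths), 0)
  expect_gt(mean(widths), 0)
})

test_that("interval width is non-decreasing in the confidence level", {
  d <- bsi(c(1, 2, 3, 4, 5, 2, 3, 4), B = 4000, seed = 3)
  widths <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(lv) {
    ci <- percentile_interval(d, lv)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("bsi_interval validates its inputs", {
  v <- c(1, 2, 3, 4)
  expect_error(bsi(v, B = 0, seed = 1), "positive")
  expect_error(bsi(v), "seed")
  d <- bsi(v, B = 100, seed = 1)
  expect_error(percentile_interval(d, 1.5), "level")
  expect_error(bca_interval(d, -1), "level")
})
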