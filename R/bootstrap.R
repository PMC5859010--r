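#' Is a response vector degenerate?
#'
#' A respondent who gives the identical response to every item has a
#' bootstrap score distribution that is a constant, so no interval can be
#' formed from it. Such respondents are excluded from change-rate
#' denominators at the pipeline level.
#'
#' @param values a response vector.
#' @return `TRUE` iff all responses are identical.
#' @export
is_degenerate <- function(values) {
  length(unique(values)) == 1L
}

degeneracy_error <- function(id = NULL) {
  who <- if (is.null(id)) "respondent" else sprintf("respondent '%s'", id)
  stop(structure(
    class = c("itemboot_degenerate", "error", "condition"),
    list(message = sprintf(
      "%s gave the same response to every item; the bootstrap distribution is constant and no interval exists",
      who), call = NULL)))
}

#' Bootstrap distribution of the total score (BSI)
#'
#' Resamples an individual's own item responses: each repetition draws J
#' values with replacement from the respondent's empirical response
#' distribution and sums them. The B resulting scores estimate the
#' distribution of total scores this person would produce over repeated
#' administrations of similar tests. Every resampled score necessarily
#' lies within the possible score range \eqn{[J\,\mathrm{min}(x),
#' J\,\mathrm{max}(x)]}.
#'
#' @param values the respondent's J item responses (not all identical).
#' @param B number of bootstrap repetitions (default 3000).
#' @param seed integer seed; required, so every distribution is reproducible.
#' @param id optional respondent identifier used in error messages.
#' @return An object of class `"bsi_dist"`: sorted `scores` (length B),
#'   `observed` total score, `B`, `J`, `values`, `seed`.
#' @examples
#' d <- bsi(c(2, 3, 3, 4, 5, 2, 1, 4), B = 1000, seed = 7)
#' d
#' @export
bsi <- function(values, B = 3000, seed, id = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!is.numeric(B) || length(B) != 1L || B < 1)
    stop("`B` must be a positive integer", call. = FALSE)
  if (is_degenerate(values)) degeneracy_error(id)
  B <- as.integer(B)
  J <- length(values)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  draws <- sample(values, J * B, replace = TRUE)
  scores <- sort(colSums(matrix(draws, nrow = J, ncol = B)))
  structure(
    list(scores = scores, observed = sum(values), B = B, J = J,
         values = values, seed = as.integer(seed)),
    class = "bsi_dist"
  )
}

#' @export
print.bsi_dist <- function(x, ...) {
  cat(sprintf("Item-bootstrap distribution: B = %d, J = %d, observed score = %g\n",
              x$B, x$J, x$observed))
  cat(sprintf("  resampled scores in [%g, %g], mean %.2f, sd %.2f\n",
              min(x$scores), max(x$scores), mean(x$scores),
              stats::sd(x$scores)))
  invisible(x)
}

#' @export
plot.bsi_dist <- function(x, ...) {
  graphics::hist(x$scores, breaks = "FD",
                 main = "Bootstrap distribution of the total score",
                 xlab = "Resampled total score", ...)
  graphics::abline(v = x$observed, lwd = 2)
  invisible(x)
}

# Empirical quantile of the bootstrap scores; type 7 (linear interpolation
# between order statistics), the convention stated in the docs.
boot_quantile <- function(scores, p) {
  unname(stats::quantile(scores, p, type = 7, names = FALSE))
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must be a probability strictly between 0 and 1", call. = FALSE)
}

one_sided_limits <- function(dist, spec) {
  if (!is.null(spec)) score_range(spec)
  else c(dist$J * min(dist$values), dist$J * max(dist$values))
}

#' Percentile bootstrap interval
#'
#' The plain percentile interval: for a two-sided level the empirical
#' percentiles at (1 - level)/2 and (1 + level)/2 of the bootstrap scores
#' (2.5 and 97.5 for 95%); for one-sided use, the single stated percentile
#' (95th or 5th for a one-sided 95% interval), with the other bound set to
#' the scale limit.
#'
#' @param dist a [bsi()] distribution.
#' @param level confidence level in (0, 1).
#' @param sidedness `"two_sided"`, `"lower_only"` or `"upper_only"`.
#' @param spec optional [scale_spec()]; supplies the scale-limit bound for
#'   one-sided intervals (the attainable range of the respondent's own
#'   responses is used if absent).
#' @return A `"conf_int"` with `method = "BSI_percentile"`.
#' @export
percentile_interval <- function(dist, level = 0.95,
                                sidedness = c("two_sided", "lower_only",
                                              "upper_only"),
                                spec = NULL) {
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(dist, "bsi_dist"))
  check_level(level)
  rng <- one_sided_limits(dist, spec)
  bounds <- switch(sidedness,
    two_sided  = boot_quantile(dist$scores, c((1 - level) / 2, (1 + level) / 2)),
    lower_only = c(boot_quantile(dist$scores, 1 - level), rng[2L]),
    upper_only = c(rng[1L], boot_quantile(dist$scores, level)))
  new_conf_int(bounds[1L], bounds[2L], level, sidedness, "BSI_percentile",
               dist$observed, out_of_range = FALSE)
}

# BCa ingredients. z0 counts resampled scores strictly below the observed
# score (ties between integer scores are common; the strict-count convention
# follows the standard BCa formulation). Acceleration comes from a
# leave-one-item-out jackknife of the mean-rescaled total,
# theta_(i) = J/(J-1) * (X - x_i), so replicates live on the score scale.
bca_params <- function(dist) {
  B <- dist$B
  n_below <- sum(dist$scores < dist$observed)
  z0 <- stats::qnorm(n_below / B)
  jack <- (dist$J / (dist$J - 1)) * (dist$observed - dist$values)
  d <- mean(jack) - jack
  denom <- sum(d^2)
  if (denom == 0) {
    warning("zero jackknife variance; acceleration set to 0", call. = FALSE)
    a <- 0
  } else {
    a <- sum(d^3) / (6 * denom^1.5)
  }
  list(z0 = z0, a = a)
}

#' BCa bootstrap interval
#'
#' The bias-corrected and accelerated interval of Efron and Tibshirani:
#' the percentile levels are adjusted by a bias correction
#' \eqn{z_0 = \Phi^{-1}(\#\{\theta^* < \hat\theta\}/B)} and an acceleration
#' \eqn{a} from a leave-one-item-out jackknife, then the empirical
#' percentiles of the bootstrap scores are read at the adjusted levels
#' \eqn{\alpha_k = \Phi\!\big(z_0 + (z_0+z_k)/(1 - a(z_0+z_k))\big)}.
#'
#' If the bias correction is undefined (no resampled score on one side of
#' the observed score, so \eqn{z_0 = \pm\infty}) the function falls back to
#' the plain percentile interval with a warning.
#'
#' @inheritParams percentile_interval
#' @return A `"conf_int"` with `method = "BSI_bca"` and attribute `"bca"`
#'   carrying z0, a and the adjusted percentile levels.
#' @export
bca_interval <- function(dist, level = 0.95,
                         sidedness = c("two_sided", "lower_only",
                                       "upper_only"),
                         spec = NULL) {
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(dist, "bsi_dist"))
  check_level(level)
  par <- bca_params(dist)
  if (!is.finite(par$z0)) {
    warning("bias correction undefined (all bootstrap scores on one side of the observed score); falling back to the percentile interval",
            call. = FALSE)
    ci <- percentile_interval(dist, level, sidedness, spec)
    ci$method <- "BSI_bca"
    return(ci)
  }
  adjust <- function(z) stats::pnorm(par$z0 + (par$z0 + z) /
                                       (1 - par$a * (par$z0 + z)))
  rng <- one_sided_limits(dist, spec)
  if (sidedness == "two_sided") {
    zk <- stats::qnorm(c((1 - level) / 2, (1 + level) / 2))
    ak <- adjust(zk)
    bounds <- boot_quantile(dist$scores, ak)
  } else if (sidedness == "lower_only") {
    ak <- adjust(stats::qnorm(1 - level))
    bounds <- c(boot_quantile(dist$scores, ak), rng[2L])
  } else {
    ak <- adjust(stats::qnorm(level))
    bounds <- c(rng[1L], boot_quantile(dist$scores, ak))
  }
  ci <- new_conf_int(bounds[1L], bounds[2L], level, sidedness, "BSI_bca",
                     dist$observed, out_of_range = FALSE)
  attr(ci, "bca") <- c(par, list(adjusted = ak))
  ci
}

#' Item-bootstrap confidence interval for one respondent
#'
#' Convenience composition of the full BSI procedure: degeneracy check,
#' bootstrap distribution of the total score, then the chosen interval
#' (BCa by default, plain percentile on request).
#'
#' @param values the respondent's J item responses.
#' @param level confidence level in (0, 1).
#' @param sidedness `"two_sided"`, `"lower_only"` or `"upper_only"`.
#' @param B number of bootstrap repetitions.
#' @param method `"bca"` or `"percentile"`.
#' @param seed integer seed (required).
#' @param spec optional [scale_spec()] for the one-sided scale-limit bound.
#' @param id optional respondent identifier for error messages.
#' @return A `"conf_int"`, with the observed total score as center.
#' @examples
#' bsi_interval(c(2, 3, 3, 4, 5, 2, 1, 4), seed = 7)
#' @export
bsi_interval <- function(values, level = 0.95,
                         sidedness = c("two_sided", "lower_only",
                                       "upper_only"),
                         B = 3000, method = c("bca", "percentile"), seed,
                         spec = NULL, id = NULL) {
  sidedness <- match.arg(sidedness)
  method <- match.arg(method)
  dist <- bsi(values, B = B, seed = seed, id = id)
  if (method == "bca") bca_interval(dist, level, sidedness, spec)
  else percentile_interval(dist, level, sidedness, spec)
}
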