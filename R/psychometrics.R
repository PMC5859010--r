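#' Cronbach's alpha
#'
#' Internal-consistency reliability of a test from a respondents x items
#' response matrix:
#' \deqn{\alpha = \frac{J}{J-1}\left(1 - \frac{\sum_j s^2_j}{s^2_X}\right)}
#' where \eqn{s^2_j} are the item variances and \eqn{s^2_X} the variance of
#' the total score, all with the n-1 denominator. Alpha can be negative for
#' badly behaved data; it never exceeds 1.
#'
#' @param mat numeric respondents x items matrix (>= 2 respondents, >= 2
#'   items, nonzero total-score variance).
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L)
    stop("Cronbach's alpha needs at least 2 items", call. = FALSE)
  if (nrow(mat) < 2L)
    stop("Cronbach's alpha needs at least 2 respondents", call. = FALSE)
  if (anyNA(mat)) stop("response matrix contains missing values", call. = FALSE)
  J <- ncol(mat)
  var_items <- apply(mat, 2L, stats::var)
  var_total <- stats::var(rowSums(mat))
  if (var_total == 0)
    stop("total-score variance is zero; alpha is undefined", call. = FALSE)
  (J / (J - 1)) * (1 - sum(var_items) / var_total)
}

#' Scale-level reliability statistics
#'
#' Estimates the quantities classical test theory needs for the true-score
#' interval: Cronbach's alpha as the reliability estimate, the mean and
#' standard deviation of the observed total scores, and the standard error
#' of measurement \eqn{\hat\sigma_e = \hat\sigma_x \sqrt{1 - \hat\rho_{xx'}}}.
#'
#' A negative alpha is reported as estimated, but the SEM is computed with
#' alpha clamped to 0 (so the SEM never exceeds the score SD) and
#' `alpha_clamped` is set with a warning.
#'
#' @param mat numeric respondents x items matrix.
#' @return An object of class `"reliability_stats"`: a list with `alpha`,
#'   `mean_score`, `sd_score`, `sem`, `n_respondents`, `alpha_clamped`.
#' @seealso [cronbach_alpha()], [ets_interval()]
#' @export
estimate_reliability <- function(mat) {
  mat <- as.matrix(mat)
  alpha <- cronbach_alpha(mat)
  scores <- rowSums(mat)
  sd_score <- stats::sd(scores)
  clamped <- alpha < 0
  if (clamped)
    warning(sprintf("alpha = %.3f is negative; SEM computed with alpha = 0",
                    alpha), call. = FALSE)
  sem <- sd_score * sqrt(1 - max(alpha, 0))
  structure(
    list(alpha = alpha, mean_score = mean(scores), sd_score = sd_score,
         sem = sem, n_respondents = nrow(mat), alpha_clamped = clamped),
    class = "reliability_stats"
  )
}

#' @export
print.reliability_stats <- function(x, ...) {
  cat(sprintf(
    "Reliability (n = %d): alpha = %.3f%s, mean = %.2f, SD = %.2f, SEM = %.3f\n",
    x$n_respondents, x$alpha, if (x$alpha_clamped) " (clamped to 0 for SEM)" else "",
    x$mean_score, x$sd_score, x$sem))
  invisible(x)
}

#' Classical true-score point estimate
#'
#' Shrinks an observed score toward the group mean by the reliability:
#' \deqn{V' = \hat\rho_{xx'} X + (1 - \hat\rho_{xx'}) \hat\mu_x}
#'
#' @param score observed total score(s) X.
#' @param stats a [estimate_reliability()] result.
#' @return Estimated true score(s), same length as `score`.
#' @export
ets_true_score <- function(score, stats) {
  stopifnot(inherits(stats, "reliability_stats"))
  stats$alpha * score + (1 - stats$alpha) * stats$mean_score
}

# z multiplier for a confidence level. Two-sided 0.95 -> 1.959964...;
# one-sided 0.95 -> 1.644854... With paper_rounding the conventional
# printed values 1.96 / 1.64 are used instead.
z_value <- function(level, sidedness, paper_rounding = FALSE) {
  if (paper_rounding && isTRUE(all.equal(level, 0.95)))
    return(if (sidedness == "two_sided") 1.96 else 1.64)
  p <- if (sidedness == "two_sided") (1 + level) / 2 else level
  stats::qnorm(p)
}

new_conf_int <- function(lower, upper, level, sidedness, method, center,
                         out_of_range = NA) {
  structure(
    list(lower = lower, upper = upper, level = level, sidedness = sidedness,
         method = method, center = center, out_of_range = out_of_range),
    class = "conf_int"
  )
}

#' @export
print.conf_int <- function(x, digits = 2, ...) {
  cat(sprintf("%s %g%% %s CI: [%.*f, %.*f] (center %.*f)%s\n",
              x$method, 100 * x$level, x$sidedness,
              digits, x$lower, digits, x$upper, digits, x$center,
              if (isTRUE(x$out_of_range)) "  [outside score range]" else ""))
  invisible(x)
}

#' Classical (ETS) confidence interval for the true score
#'
#' The Gulliksen-style interval around the estimated true score:
#' \eqn{V' \pm z \hat\sigma_e} for a two-sided interval. For one-sided use,
#' only one bound is computed from the data (`"upper_only"` gives
#' \eqn{V' + z\hat\sigma_e}, `"lower_only"` gives \eqn{V' - z\hat\sigma_e},
#' with the one-sided z) and the other bound is the corresponding limit of
#' the score range.
#'
#' Bounds are deliberately not clipped to the possible score range: limits
#' outside \eqn{[J\,\mathrm{min}, J\,\mathrm{max}]} are a known property of
#' the classical interval, and the `out_of_range` flag records when it
#' happens (requires `spec`).
#'
#' @param score observed total score X.
#' @param stats a [estimate_reliability()] result.
#' @param level confidence level in (0, 1); default 0.95.
#' @param sidedness `"two_sided"`, `"lower_only"` or `"upper_only"`.
#' @param spec optional [scale_spec()]; required for one-sided intervals
#'   (supplies the scale-limit bound) and for out-of-range flagging.
#' @param paper_rounding use the conventional printed multipliers 1.96 / 1.64
#'   at the 95% level instead of exact normal quantiles.
#' @return A `"conf_int"` object with `method = "ETS"`.
#' @examples
#' m <- matrix(sample(1:5, 200, TRUE), 20, 10)
#' st <- estimate_reliability(m)
#' ets_interval(total_score(m[1, ]), st)
#' @export
ets_interval <- function(score, stats, level = 0.95,
                         sidedness = c("two_sided", "lower_only", "upper_only"),
                         spec = NULL, paper_rounding = FALSE) {
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(stats, "reliability_stats"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must be a probability strictly between 0 and 1", call. = FALSE)
  if (sidedness != "two_sided" && is.null(spec))
    stop("one-sided ETS intervals need `spec` for the scale-limit bound",
         call. = FALSE)
  v <- ets_true_score(score, stats)
  z <- z_value(level, sidedness, paper_rounding)
  half <- z * stats$sem
  rng <- if (!is.null(spec)) score_range(spec) else c(-Inf, Inf)
  bounds <- switch(sidedness,
    two_sided  = c(v - half, v + half),
    lower_only = c(v - half, rng[2L]),
    upper_only = c(rng[1L], v + half))
  oor <- if (is.null(spec)) NA else {
    fin <- switch(sidedness, two_sided = c(1L, 2L), lower_only = 1L,
                  upper_only = 2L)
    any(bounds[fin] < rng[1L] | bounds[fin] > rng[2L])
  }
  new_conf_int(bounds[1L], bounds[2L], level, sidedness, "ETS", v,
               out_of_range = oor)
}
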