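#' Simulation configuration
#'
#' Bundles the parameters of the synthetic data-generating process and of
#' the detection run applied to it. Responses follow a latent-trait
#' ordinal model: respondent i has a latent trait theta_i drawn from
#' Normal(`true_score_mean`, `true_score_sd`) on the item response scale,
#' and the response to item j is `round(theta_i + e_ij)` with
#' `e_ij ~ Normal(0, item_noise_sd)`, clipped to the response bounds.
#' Administrations are conditionally independent given theta; an
#' intervention shifts theta by `change_delta` latent units.
#'
#' Defaults mirror a 24-item five-point Likert half-test answered by a
#' moderately homogeneous sample: theta ~ Normal(3, 0.6), item noise SD
#' 0.8, 1000 respondents, B = 1000 bootstrap repetitions, 95% level.
#'
#' @param n_respondents respondents per replication.
#' @param n_items items per administration (J).
#' @param scale_min,scale_max response bounds.
#' @param true_score_mean,true_score_sd latent trait distribution, on the
#'   per-item response scale.
#' @param item_noise_sd SD of the per-item measurement noise.
#' @param change_delta latent shift between occasions (0 under the null).
#' @param n_replications independent replications of the whole study.
#' @param B bootstrap repetitions for the BSI intervals.
#' @param level confidence level.
#' @param seed integer seed for the whole study.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_respondents = 1000, n_items = 24,
                       scale_min = 1, scale_max = 5,
                       true_score_mean = 3, true_score_sd = 0.6,
                       item_noise_sd = 0.8, change_delta = 0,
                       n_replications = 1, B = 1000, level = 0.95,
                       seed = 1) {
  stopifnot(true_score_sd >= 0, item_noise_sd >= 0, n_items >= 2,
            n_respondents >= 1, n_replications >= 1)
  structure(
    list(n_respondents = as.integer(n_respondents),
         n_items = as.integer(n_items),
         scale_min = as.integer(scale_min),
         scale_max = as.integer(scale_max),
         true_score_mean = true_score_mean, true_score_sd = true_score_sd,
         item_noise_sd = item_noise_sd, change_delta = change_delta,
         n_replications = as.integer(n_replications), B = as.integer(B),
         level = level, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate one administration of the test
#'
#' Draws the respondents x items response matrix for one occasion from the
#' latent-trait model: `round(theta_i + e_ij)` clipped to the scale bounds.
#' With `item_noise_sd = 0` and integer in-bounds theta every response
#' equals theta, producing degenerate (constant) respondents — the path the
#' exclusion rule exists for.
#'
#' @param theta latent trait per respondent (length = number of rows).
#' @param config a [sim_config()].
#' @param seed integer seed for this administration's noise.
#' @return Integer matrix, `length(theta)` rows x `config$n_items` columns.
#' @export
generate_administration <- function(theta, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- length(theta)
  J <- config$n_items
  e <- matrix(stats::rnorm(n * J, 0, config$item_noise_sd), n, J)
  x <- round(theta + e)
  x[x < config$scale_min] <- config$scale_min
  x[x > config$scale_max] <- config$scale_max
  storage.mode(x) <- "integer"
  x
}

sim_spec <- function(config, direction = "two_sided") {
  scale_spec(config$n_items, config$scale_min, config$scale_max,
             direction = direction)
}

# One replication: draw theta, generate occasions, run detection, return
# per-method significant-change proportions on the evaluable denominator.
run_one_replication <- function(config, direction, rep_seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rep_seed)
  theta <- stats::rnorm(config$n_respondents, config$true_score_mean,
                        config$true_score_sd)
  seeds <- sample.int(.Machine$integer.max, 3L)
  pre <- generate_administration(theta, config, seeds[1L])
  post <- generate_administration(theta + config$change_delta, config,
                                  seeds[2L])
  spec <- sim_spec(config, direction)
  fit <- reliable_change(pre, post, spec, method = "both",
                         level = config$level, B = config$B,
                         seed = seeds[3L])
  res <- lapply(fit$summaries, function(s)
    list(rate = if (s$n_evaluated == 0) NA_real_
                else s$n_significant / s$n_evaluated,
         n_evaluated = s$n_evaluated,
         n_indeterminate = s$n_indeterminate))
  res
}

sim_result <- function(config, condition, direction, per_rep) {
  methods <- names(per_rep[[1L]])
  out <- lapply(methods, function(m) {
    rates <- vapply(per_rep, function(r) r[[m]]$rate, numeric(1))
    n_eval <- vapply(per_rep, function(r) r[[m]]$n_evaluated, numeric(1))
    n_ind <- vapply(per_rep, function(r) r[[m]]$n_indeterminate, numeric(1))
    rate <- mean(rates, na.rm = TRUE)
    mc_se <- if (length(rates) > 1L)
      stats::sd(rates) / sqrt(length(rates))
    else sqrt(rate * (1 - rate) / max(sum(n_eval), 1))
    data.frame(method = m, condition = condition, direction = direction,
               rate_significant = rate, mc_se = mc_se,
               n_indeterminate = sum(n_ind),
               n_replications = length(rates),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "config") <- config
  class(res) <- c("sim_result", "data.frame")
  res
}

#' Null-condition calibration study
#'
#' Simulates the no-change regime: one latent trait per respondent, two
#' conditionally independent administrations generated from it, two-sided
#' detection by both ETS and BSI. Every significant verdict is a false
#' positive, so the resulting rates estimate each method's empirical type I
#' error, which the strict non-overlap rule keeps below the nominal alpha.
#'
#' @param config a [sim_config()] with `change_delta = 0`.
#' @return A `"sim_result"` data frame, one row per method, with
#'   `rate_significant`, the Monte-Carlo standard error `mc_se`, and the
#'   count of degenerate respondents excluded.
#' @export
run_null_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$change_delta != 0)
    stop("null study requires change_delta = 0", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$n_replications)
  per_rep <- lapply(rep_seeds, function(s)
    run_one_replication(config, "two_sided", s))
  sim_result(config, "null", "two_sided", per_rep)
}

#' Intervention (power) study
#'
#' Simulates a true latent shift of `change_delta` between occasions and
#' applies the directional one-sided detection rule (direction inferred
#' from the sign of the shift; `change_delta = 0` degenerates to the
#' two-sided null regime, so power curves connect continuously to the null
#' rate). The reported rate is the detection rate (power).
#'
#' @param config a [sim_config()].
#' @param direction override for the direction tested; by default the sign
#'   of `change_delta` decides (`> 0` increase, `< 0` decrease, `0`
#'   two-sided).
#' @return A `"sim_result"` data frame, one row per method.
#' @export
run_change_study <- function(config, direction = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(direction))
    direction <- if (config$change_delta > 0) "increase"
                 else if (config$change_delta < 0) "decrease"
                 else "two_sided"
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$n_replications)
  per_rep <- lapply(rep_seeds, function(s)
    run_one_replication(config, direction, s))
  sim_result(config, if (config$change_delta == 0) "null" else "change",
             direction, per_rep)
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Simulation (%s condition): n = %d, J = %d, delta = %g, B = %d, level = %g\n",
    x$condition[1L], cfg$n_respondents, cfg$n_items, cfg$change_delta,
    cfg$B, cfg$level))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s rate = %5.1f%%  (MC SE %.1f pp, %d indeterminate)\n",
                x$method[i], 100 * x$rate_significant[i], 100 * x$mc_se[i],
                x$n_indeterminate[i]))
  invisible(x)
}
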