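#' Detect reliable individual change between two administrations
#'
#' The central procedure of the package. For every respondent it builds a
#' confidence interval for the score at each occasion — with the classical
#' true-score method (ETS), the item bootstrap (BSI), or both — and declares
#' a reliable change when the two intervals do not overlap in the direction
#' tested. Respondents with a constant response pattern at either occasion
#' have no bootstrap distribution; they are marked `indeterminate` and
#' excluded from rate denominators for every method, so the methods are
#' compared on the same respondents.
#'
#' The direction comes from `spec$direction`: `"two_sided"` compares
#' two-sided intervals for non-overlap in either direction; `"increase"`
#' uses one-sided intervals and requires the lower limit of the post
#' interval to exceed the upper limit of the pre interval; `"decrease"` the
#' mirror image.
#'
#' @param pre,post respondents x items response matrices for the two
#'   occasions, rows matched by rowname (respondent id) or by position when
#'   unnamed. Inverse items are recoded here according to `spec`.
#' @param spec a [scale_spec()].
#' @param method `"both"` (ETS and BCa-adjusted BSI, the default), `"ets"`,
#'   `"bsi_bca"` or `"bsi_percentile"`.
#' @param level confidence level (0.95 default).
#' @param B bootstrap repetitions per respondent and occasion.
#' @param seed integer seed; per-respondent bootstrap seeds are derived from
#'   it, so the whole analysis is reproducible.
#' @param paper_rounding use z = 1.96 / 1.64 instead of exact normal
#'   quantiles for the ETS interval at the 95% level.
#' @param one_sided_percentile for one-sided BSI intervals, read the raw
#'   5th/95th percentile instead of applying the BCa adjustment.
#' @param stats_source which administration supplies the ETS scale
#'   statistics (alpha, mean, SD): `"each"` (every occasion uses its own,
#'   the default), `"pre"`, or `"pooled"` (rows of both stacked).
#' @return An object of class `"reliable_change"`: per-respondent results
#'   table (`$respondents`), decision lists and [summarize_rates()]
#'   summaries per method, the reliability statistics used, and a config
#'   echo. Has `print()` and `summary()` methods.
#' @examples
#' sp <- scale_spec(8, 1, 5, direction = "increase")
#' pre <- matrix(sample(1:4, 20 * 8, TRUE), 20, 8)
#' post <- pmin(pre + rbinom(length(pre), 1, 0.4), 5)
#' fit <- reliable_change(pre, post, sp, B = 500, seed = 1)
#' fit
#' @export
reliable_change <- function(pre, post, spec,
                            method = c("both", "ets", "bsi_bca",
                                       "bsi_percentile"),
                            level = 0.95, B = 3000, seed,
                            paper_rounding = FALSE,
                            one_sided_percentile = FALSE,
                            stats_source = c("each", "pre", "pooled")) {
  method <- match.arg(method)
  stats_source <- match.arg(stats_source)
  stopifnot(inherits(spec, "scale_spec"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  check_level(level)
  pre <- recode_inverse(validate_matrix(pre, spec), spec)
  post <- recode_inverse(validate_matrix(post, spec), spec)
  if (nrow(pre) != nrow(post))
    stop("pre and post matrices have different numbers of respondents",
         call. = FALSE)
  ids <- rownames(pre)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(pre)))
  if (!is.null(rownames(post)) && !identical(ids, rownames(post)))
    stop("respondent ids differ between pre and post matrices", call. = FALSE)

  methods <- switch(method,
    both = c("ETS", "BSI_bca"),
    ets = "ETS",
    bsi_bca = "BSI_bca",
    bsi_percentile = "BSI_percentile")
  direction <- spec$direction
  # sidedness of the per-occasion intervals under the directional rule
  sided <- switch(direction,
    two_sided = c(pre = "two_sided", post = "two_sided"),
    increase  = c(pre = "upper_only", post = "lower_only"),
    decrease  = c(pre = "lower_only", post = "upper_only"))

  n <- nrow(pre)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  boot_seeds <- matrix(sample.int(.Machine$integer.max, 2L * n), nrow = n)

  need_ets <- "ETS" %in% methods
  need_bsi <- any(grepl("^BSI", methods))
  if (need_ets) {
    stat_for <- function(occ_mat) estimate_reliability(occ_mat)
    rel <- switch(stats_source,
      each   = list(pre = stat_for(pre), post = stat_for(post)),
      pre    = { s <- stat_for(pre); list(pre = s, post = s) },
      pooled = { s <- stat_for(rbind(pre, post)); list(pre = s, post = s) })
  } else rel <- NULL

  degenerate <- vapply(seq_len(n), function(i)
    is_degenerate(pre[i, ]) || is_degenerate(post[i, ]), logical(1))

  decisions <- stats::setNames(
    replicate(length(methods), vector("list", n), simplify = FALSE), methods)
  rows <- vector("list", n)
  bsi_method <- if ("BSI_percentile" %in% methods) "percentile" else "bca"

  for (i in seq_len(n)) {
    row <- list(id = ids[i], pre_score = sum(pre[i, ]),
                post_score = sum(post[i, ]), degenerate = degenerate[i])
    for (m in methods) {
      if (degenerate[i]) {
        decisions[[m]][[i]] <- indeterminate_decision(ids[i], direction)
        row[paste0(m, c("_pre_lo", "_pre_hi", "_post_lo", "_post_hi"))] <-
          NA_real_
        row[[paste0(m, "_verdict")]] <- "indeterminate"
        if (m == "ETS") row$ets_out_of_range <- NA
        row[[paste0(m, "_tie")]] <- FALSE
        next
      }
      if (m == "ETS") {
        ci_pre <- ets_interval(row$pre_score, rel$pre, level,
                               sided[["pre"]], spec, paper_rounding)
        ci_post <- ets_interval(row$post_score, rel$post, level,
                                sided[["post"]], spec, paper_rounding)
      } else {
        use <- if (direction != "two_sided" && one_sided_percentile)
          "percentile" else bsi_method
        ci_pre <- bsi_interval(pre[i, ], level, sided[["pre"]], B, use,
                               seed = boot_seeds[i, 1L], spec, id = ids[i])
        ci_post <- bsi_interval(post[i, ], level, sided[["post"]], B, use,
                                seed = boot_seeds[i, 2L], spec, id = ids[i])
      }
      dec <- detect_change(ci_pre, ci_post, direction, id = ids[i])
      decisions[[m]][[i]] <- dec
      row[[paste0(m, "_pre_lo")]] <- ci_pre$lower
      row[[paste0(m, "_pre_hi")]] <- ci_pre$upper
      row[[paste0(m, "_post_lo")]] <- ci_post$lower
      row[[paste0(m, "_post_hi")]] <- ci_post$upper
      row[[paste0(m, "_verdict")]] <- dec$verdict
      if (m == "ETS")
        row$ets_out_of_range <- isTRUE(ci_pre$out_of_range) ||
          isTRUE(ci_post$out_of_range)
      row[[paste0(m, "_tie")]] <- dec$tie
    }
    rows[[i]] <- row
  }

  respondents <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(respondents) <- NULL
  summaries <- lapply(methods, function(m)
    summarize_rates(decisions[[m]], method = m))
  names(summaries) <- methods

  structure(
    list(respondents = respondents, decisions = decisions,
         summaries = summaries, reliability = rel, spec = spec,
         config = list(method = method, level = level, B = B,
                       seed = as.integer(seed),
                       direction = direction,
                       paper_rounding = paper_rounding,
                       one_sided_percentile = one_sided_percentile,
                       stats_source = stats_source)),
    class = "reliable_change"
  )
}

#' @export
print.reliable_change <- function(x, ...) {
  cat(sprintf(
    "Reliable change analysis: %d respondents, %d items, %g%% level, direction: %s\n",
    nrow(x$respondents), x$spec$n_items, 100 * x$config$level,
    x$config$direction))
  for (s in x$summaries) print(s)
  n_tie <- sum(vapply(x$summaries, function(s) s$n_ties, integer(1)))
  if (n_tie > 0)
    cat(sprintf("Note: %d exact tie(s) at compared bounds (count as overlap)\n",
                n_tie))
  invisible(x)
}

#' @export
summary.reliable_change <- function(object, ...) {
  print(object)
  if (!is.null(object$reliability)) {
    cat("\nETS scale statistics:\n")
    cat("  pre : "); print(object$reliability$pre)
    cat("  post: "); print(object$reliability$post)
  }
  cfg <- object$config
  cat(sprintf("\nConfig: method=%s level=%g B=%d seed=%d paper_rounding=%s stats_source=%s\n",
              cfg$method, cfg$level, cfg$B, cfg$seed, cfg$paper_rounding,
              cfg$stats_source))
  if (any(isTRUE(object$respondents$ets_out_of_range)) ||
      any(object$respondents$ets_out_of_range %in% TRUE))
    cat(sprintf("ETS bounds outside the possible score range for %d respondent(s)\n",
                sum(object$respondents$ets_out_of_range %in% TRUE)))
  invisible(object)
}
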