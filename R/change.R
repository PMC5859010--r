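#' Non-overlap decision for reliable change
#'
#' Compares the pre- and post-occasion confidence intervals and declares a
#' reliable (significant) change when they do not overlap, with strict
#' inequalities so that intervals sharing a bound count as overlapping:
#' \itemize{
#'   \item `two_sided`: significant iff `pre$lower > post$upper` or
#'     `post$lower > pre$upper`;
#'   \item `increase`: significant iff `post$lower > pre$upper`;
#'   \item `decrease`: significant iff `pre$lower > post$upper`.
#' }
#' Exact ties at the compared bounds are flagged (`tie = TRUE`); ties favour
#' no-change.
#'
#' @param pre,post `"conf_int"` objects built by the same method and level.
#' @param direction `"two_sided"`, `"increase"` or `"decrease"`.
#' @param id optional respondent identifier.
#' @return An object of class `"change_decision"`: list with `respondent_id`,
#'   `pre`, `post`, `verdict` (`"significant"` / `"not_significant"`),
#'   `direction_tested`, `tie`.
#' @export
detect_change <- function(pre, post,
                          direction = c("two_sided", "increase", "decrease"),
                          id = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(pre, "conf_int"), inherits(post, "conf_int"))
  if (pre$method != post$method)
    stop(sprintf("pre and post intervals use different methods (%s vs %s)",
                 pre$method, post$method), call. = FALSE)
  if (!isTRUE(all.equal(pre$level, post$level)))
    stop("pre and post intervals use different confidence levels", call. = FALSE)
  up <- post$lower > pre$upper    # post above pre
  down <- pre$lower > post$upper  # post below pre
  sig <- switch(direction,
    two_sided = up || down,
    increase  = up,
    decrease  = down)
  tie <- switch(direction,
    two_sided = post$lower == pre$upper || pre$lower == post$upper,
    increase  = post$lower == pre$upper,
    decrease  = pre$lower == post$upper)
  structure(
    list(respondent_id = id, pre = pre, post = post,
         verdict = if (sig) "significant" else "not_significant",
         direction_tested = direction, tie = tie),
    class = "change_decision"
  )
}

# An indeterminate decision for a respondent whose interval could not be
# computed (degenerate responses at either occasion).
indeterminate_decision <- function(id = NULL,
                                   direction = "two_sided") {
  structure(
    list(respondent_id = id, pre = NULL, post = NULL,
         verdict = "indeterminate", direction_tested = direction,
         tie = FALSE),
    class = "change_decision"
  )
}

#' @export
print.change_decision <- function(x, ...) {
  cat(sprintf("Respondent %s: %s (%s)%s\n",
              if (is.null(x$respondent_id)) "?" else x$respondent_id,
              x$verdict, x$direction_tested,
              if (isTRUE(x$tie)) " [exact tie at compared bounds]" else ""))
  invisible(x)
}

# Half-up rounding to `digits` decimals (R's round() is half-even).
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarise change decisions as a rate
#'
#' Counts significant verdicts among the evaluable (non-indeterminate)
#' respondents of a group, in the "n (percent)" style of rate tables:
#' the percentage is computed on the evaluated denominator and rounded
#' half-up to one decimal.
#'
#' @param decisions a list of [detect_change()] decisions.
#' @param group_label text label for the group.
#' @param method interval method label carried into the summary.
#' @return An object of class `"rate_summary"`: `group_label`, `method`,
#'   `n_evaluated`, `n_indeterminate`, `n_significant`, `n_ties`,
#'   `percent_significant` (NA when nothing was evaluable).
#' @export
summarize_rates <- function(decisions, group_label = "", method = "") {
  if (!length(decisions)) stop("no decisions to summarise", call. = FALSE)
  verdicts <- vapply(decisions, function(d) d$verdict, character(1))
  n_ind <- sum(verdicts == "indeterminate")
  n_eval <- length(verdicts) - n_ind
  n_sig <- sum(verdicts == "significant")
  pct <- if (n_eval == 0) NA_real_ else round_half_up(100 * n_sig / n_eval, 1)
  structure(
    list(group_label = group_label, method = method, n_evaluated = n_eval,
         n_indeterminate = n_ind, n_significant = n_sig,
         n_ties = sum(vapply(decisions, function(d) isTRUE(d$tie), logical(1))),
         percent_significant = pct),
    class = "rate_summary"
  )
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("%s%s (N = %d%s): %d (%s)\n",
              if (nzchar(x$group_label)) paste0(x$group_label, " ") else "",
              x$method, x$n_evaluated,
              if (x$n_indeterminate)
                sprintf(", %d indeterminate excluded", x$n_indeterminate)
              else "",
              x$n_significant,
              if (is.na(x$percent_significant)) "-"
              else sprintf("%.1f", x$percent_significant)))
  invisible(x)
}
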