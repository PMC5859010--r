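#' Order items by sample mean
#'
#' Sorts item indices by descending average score in the sample (inverse
#' items must already be recoded); ties are broken by ascending original
#' index, so the order is stable.
#'
#' @param mat respondents x items response matrix, inverse items recoded.
#' @return Integer vector of item indices, highest mean first.
#' @export
order_items_by_mean <- function(mat) {
  means <- colMeans(as.matrix(mat))
  order(-means, seq_along(means))
}

#' ABBA assignment of ordered items to two half-tests
#'
#' Walks the mean-ordered item list assigning items in the repeating
#' pattern A, B, B, A: of the two items with the highest mean the first
#' goes to half 1 and the second to half 2; of the next two, the first
#' goes to half 2 and the second to half 1; and so on. The pattern keeps
#' the half-test total scores as similar as possible. Odd leftover items
#' continue the pattern, so the halves differ by at most one item.
#'
#' @param ordered item indices in descending-mean order.
#' @return List with `half1_items` and `half2_items` (original indices in
#'   assignment order).
#' @export
abba_assign <- function(ordered) {
  n <- length(ordered)
  if (n < 2L) stop("need at least 2 items to split", call. = FALSE)
  pattern <- rep_len(c(1L, 2L, 2L, 1L), n)
  list(half1_items = ordered[pattern == 1L],
       half2_items = ordered[pattern == 2L])
}

#' Split one administration into two parallel half-tests
#'
#' Implements the parallel-forms construction used when only a single
#' administration exists: recode inverse items, order items by sample
#' mean, assign them to halves by the ABBA pattern, then check that the
#' halves are equivalent in mean (paired t-test on the half-score
#' differences) and variance (Pitman-Morgan test on the correlation
#' between half-score sums and differences). The two halves can then be
#' treated as parallel forms administered at the same time, between which
#' no real change should exist.
#'
#' @param mat respondents x items response matrix (raw; inverse items are
#'   recoded here using `spec`).
#' @param spec a [scale_spec()].
#' @param alpha_level significance level for the equivalence tests.
#' @return An object of class `"split_result"`: `half1_items`,
#'   `half2_items`, per-respondent `half1_scores` / `half2_scores`,
#'   `mean_test_p`, `variance_test_p`, `equivalent`, `odd_j` flag.
#' @examples
#' sp <- scale_spec(8, 1, 5)
#' m <- matrix(sample(1:5, 30 * 8, TRUE), 30, 8)
#' split_half(m, sp)
#' @export
split_half <- function(mat, spec, alpha_level = 0.05) {
  stopifnot(inherits(spec, "scale_spec"))
  mat <- recode_inverse(validate_matrix(mat, spec), spec)
  halves <- abba_assign(order_items_by_mean(mat))
  if (spec$n_items %% 2L == 1L)
    warning(sprintf("odd number of items (%d): halves have %d and %d items and half-scores are not rescaled",
                    spec$n_items, length(halves$half1_items),
                    length(halves$half2_items)), call. = FALSE)
  s1 <- rowSums(mat[, halves$half1_items, drop = FALSE])
  s2 <- rowSums(mat[, halves$half2_items, drop = FALSE])
  tests <- check_parallel(s1, s2, alpha_level)
  structure(
    c(halves,
      list(half1_scores = s1, half2_scores = s2,
           mean_test_p = tests$mean_test_p,
           variance_test_p = tests$variance_test_p,
           equivalent = tests$equivalent,
           alpha_level = alpha_level,
           odd_j = spec$n_items %% 2L == 1L)),
    class = "split_result"
  )
}

#' Equivalence tests for two half-tests
#'
#' Paired-samples t-test for equal means of the half scores, and the
#' Pitman-Morgan test for equal variances of paired measurements (a t-test
#' of the correlation between the sums and differences of the paired half
#' scores, which is zero iff the variances are equal). The halves are
#' declared equivalent when neither test rejects at `alpha_level`.
#'
#' @param half1,half2 per-respondent half-test total scores (same length,
#'   >= 3 respondents).
#' @param alpha_level significance level.
#' @return List with `mean_test_p`, `variance_test_p`, `equivalent`.
#'   Degenerate inputs make a test not applicable: identical half scores
#'   (all differences zero) leave the p-values `NA` and non-rejecting,
#'   while a constant nonzero offset between the halves is a sure mean
#'   difference (`mean_test_p = 0`).
#' @export
check_parallel <- function(half1, half2, alpha_level = 0.05) {
  if (length(half1) != length(half2) || length(half1) < 3L)
    stop("need paired half scores for at least 3 respondents", call. = FALSE)
  d <- half1 - half2
  s <- half1 + half2
  # a constant difference has no sampling variance: identical halves are
  # equivalent by construction, a constant nonzero offset differs surely
  mean_p <- if (stats::sd(d) == 0) {
    if (mean(d) == 0) NA_real_ else 0
  } else stats::t.test(d)$p.value
  var_p <- if (stats::sd(d) == 0 || stats::sd(s) == 0) NA_real_
           else stats::cor.test(s, d)$p.value
  rejects <- function(p) !is.na(p) && p <= alpha_level
  list(mean_test_p = mean_p, variance_test_p = var_p,
       equivalent = !rejects(mean_p) && !rejects(var_p))
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("ABBA split: halves of %d and %d items\n",
              length(x$half1_items), length(x$half2_items)))
  cat("  half 1 items:", paste(x$half1_items, collapse = ", "), "\n")
  cat("  half 2 items:", paste(x$half2_items, collapse = ", "), "\n")
  fmt_p <- function(p) if (is.na(p)) "n/a (degenerate)" else sprintf("%.3f", p)
  cat(sprintf("  mean test p = %s, variance test p = %s -> %s at alpha = %g\n",
              fmt_p(x$mean_test_p), fmt_p(x$variance_test_p),
              if (x$equivalent) "parallel" else "NOT parallel",
              x$alpha_level))
  invisible(x)
}
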