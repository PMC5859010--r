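#' Define a measurement scale
#'
#' A scale specification describes the fixed properties of the instrument:
#' the number of items J, the bounds of the ordinal response format (e.g.
#' 1--5 for a five-point Likert scale), which items are inverse-keyed, and
#' the direction in which an intervention is expected to move scores.
#'
#' @param n_items number of items J (>= 2).
#' @param scale_min,scale_max integer response bounds, `scale_min < scale_max`.
#' @param inverse_items integer vector of 1-based indices of inverse-keyed
#'   items (recoded by reflection about the scale midpoint before scoring).
#' @param direction expected direction of true change: `"two_sided"` when no
#'   direction is assumed (parallel-forms, test-retest without intervention),
#'   `"increase"` or `"decrease"` when the intervention has a known expected
#'   effect and one-sided intervals are appropriate.
#'
#' @return An object of class `"scale_spec"`.
#' @examples
#' scale_spec(8, 1, 5)
#' scale_spec(48, 1, 5, inverse_items = c(2, 7), direction = "two_sided")
#' @export
scale_spec <- function(n_items, scale_min, scale_max, inverse_items = integer(),
                       direction = c("two_sided", "increase", "decrease")) {
  direction <- match.arg(direction)
  n_items <- as.integer(n_items)
  scale_min <- as.integer(scale_min)
  scale_max <- as.integer(scale_max)
  if (length(n_items) != 1L || is.na(n_items) || n_items < 2L)
    stop("`n_items` must be a single integer >= 2", call. = FALSE)
  if (anyNA(c(scale_min, scale_max)) || scale_min >= scale_max)
    stop("`scale_min` must be strictly less than `scale_max`", call. = FALSE)
  inverse_items <- sort(unique(as.integer(inverse_items)))
  if (length(inverse_items) &&
      (min(inverse_items) < 1L || max(inverse_items) > n_items))
    stop("`inverse_items` must be indices in 1..n_items", call. = FALSE)
  structure(
    list(n_items = n_items, scale_min = scale_min, scale_max = scale_max,
         inverse_items = inverse_items, direction = direction),
    class = "scale_spec"
  )
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("Scale: %d items, responses in [%d, %d], direction: %s\n",
              x$n_items, x$scale_min, x$scale_max, x$direction))
  if (length(x$inverse_items))
    cat("Inverse-keyed items:", paste(x$inverse_items, collapse = ", "), "\n")
  invisible(x)
}

# Internal: validate a single response vector (or every row of a matrix)
# against the scale bounds; id/item context used in error messages.
validate_responses <- function(values, spec, id = NULL) {
  if (!is.numeric(values))
    stop("responses must be numeric", call. = FALSE)
  if (anyNA(values))
    stop(sprintf("missing response%s not allowed",
                 if (is.null(id)) "s" else sprintf("s for respondent '%s'", id)),
         call. = FALSE)
  if (any(values != round(values)))
    stop("responses must be integers", call. = FALSE)
  bad <- which(values < spec$scale_min | values > spec$scale_max)
  if (length(bad)) {
    who <- if (is.null(id)) "" else sprintf(" (respondent '%s')", id)
    stop(sprintf("response %g at item %d%s outside scale bounds [%d, %d]",
                 values[bad[1L]], bad[1L], who, spec$scale_min, spec$scale_max),
         call. = FALSE)
  }
  if (length(values) != spec$n_items)
    stop(sprintf("expected %d item responses, got %d%s", spec$n_items,
                 length(values),
                 if (is.null(id)) "" else sprintf(" for respondent '%s'", id)),
         call. = FALSE)
  invisible(values)
}

# Internal: coerce input to a numeric respondents x items matrix and check
# every cell against the scale bounds.
validate_matrix <- function(mat, spec) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("response matrix must be numeric", call. = FALSE)
  if (ncol(mat) != spec$n_items)
    stop(sprintf("matrix has %d columns but the scale has %d items",
                 ncol(mat), spec$n_items), call. = FALSE)
  ids <- rownames(mat)
  for (i in seq_len(nrow(mat)))
    validate_responses(mat[i, ], spec, id = if (is.null(ids)) i else ids[i])
  mat
}

#' Recode inverse-keyed items
#'
#' Reflects the responses of inverse-keyed items about the scale midpoint:
#' a value x becomes `scale_min + scale_max - x`. Applying the recode twice
#' restores the original responses.
#'
#' @param x a response vector of length J, or a respondents x items matrix.
#' @param spec a [scale_spec()]; its `inverse_items` are the columns recoded.
#' @return `x` with inverse items recoded; other values untouched.
#' @examples
#' sp <- scale_spec(3, 1, 5, inverse_items = 2)
#' recode_inverse(c(1, 2, 5), sp)   # 2 -> 4
#' @export
recode_inverse <- function(x, spec) {
  stopifnot(inherits(spec, "scale_spec"))
  if (!length(spec$inverse_items)) return(x)
  refl <- function(v) spec$scale_min + spec$scale_max - v
  if (is.matrix(x) || is.data.frame(x)) {
    x <- validate_matrix(x, spec)
    x[, spec$inverse_items] <- refl(x[, spec$inverse_items])
  } else {
    validate_responses(x, spec)
    x[spec$inverse_items] <- refl(x[spec$inverse_items])
  }
  x
}

#' Total test score
#'
#' The observed score X is the sum of the item responses. For a matrix,
#' one score per respondent (row).
#'
#' @param x a response vector or a respondents x items matrix.
#' @return A numeric scalar, or a vector of row sums.
#' @export
total_score <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) rowSums(as.matrix(x)) else sum(x)
}

# Range of possible total scores for a scale.
score_range <- function(spec) {
  c(spec$n_items * spec$scale_min, spec$n_items * spec$scale_max)
}
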