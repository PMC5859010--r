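# Shared fixtures and independent oracles used across the test files.

# Random respondents x items matrix of bounded integer responses.
random_matrix <- function(n, J, lo = 1, hi = 5) {
  matrix(sample(lo:hi, n * J, replace = TRUE), n, J)
}

# Correlated responses from a latent trait (positive inter-item
# correlation, so alpha is comfortably positive).
trait_matrix <- function(n, J, lo = 1, hi = 5, noise = 0.8) {
  theta <- stats::rnorm(n, (lo + hi) / 2, 0.8)
  x <- round(theta + matrix(stats::rnorm(n * J, 0, noise), n, J))
  x[x < lo] <- lo; x[x > hi] <- hi
  storage.mode(x) <- "integer"
  x
}

# Random non-degenerate response vector.
random_rv <- function(J, lo = 1, hi = 5) {
  repeat {
    v <- sample(lo:hi, J, replace = TRUE)
    if (length(unique(v)) > 1L) return(v)
  }
}

# Independent Cronbach's alpha oracle via the covariance matrix:
# alpha = J/(J-1) * (1 - trace(C)/sum(C)).
alpha_cov_oracle <- function(mat) {
  J <- ncol(mat)
  C <- stats::cov(mat)
  (J / (J - 1)) * (1 - sum(diag(C)) / sum(C))
}

# Reliability stats with prescribed values, for closed-form ETS checks.
make_stats <- function(alpha, mean_score, sd_score) {
  structure(
    list(alpha = alpha, mean_score = mean_score, sd_score = sd_score,
         sem = sd_score * sqrt(1 - max(alpha, 0)), n_respondents = 100L,
         alpha_clamped = alpha < 0),
    class = "reliability_stats")
}

# Bootstrap-distribution object with prescribed scores, for interval tests
# that need full control of the distribution.
make_dist <- function(scores, values, observed = sum(values)) {
  structure(
    list(scores = sort(scores), observed = observed, B = length(scores),
         J = length(values), values = values, seed = 0L),
    class = "bsi_dist")
}

# Plain conf_int for decision-rule tests.
make_ci <- function(lower, upper, level = 0.95, sidedness = "two_sided",
                    method = "ETS", center = (lower + upper) / 2) {
  structure(
    list(lower = lower, upper = upper, level = level, sidedness = sidedness,
         method = method, center = center, out_of_range = FALSE),
    class = "conf_int")
}

# Exact resampling distribution of the total score for small J: all J^J
# equally likely ordered draws (enumeration oracle).
enumerate_resample_scores <- function(values) {
  J <- length(values)
  grids <- rep(list(values), J)
  rowSums(as.matrix(expand.grid(grids)))
}
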