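#' Read a response matrix from CSV
#'
#' Expects comma-separated UTF-8 text with a header row, the first column
#' named `id` holding respondent identifiers and the remaining columns one
#' item each, integer responses only. Missing cells are rejected rather
#' than imputed: the bootstrap resamples the empirical response set, and
#' imputation would silently change the resampling population. Every
#' violation is reported with its row and column.
#'
#' @param path CSV file path.
#' @param spec a [scale_spec()]; column count and response bounds are
#'   enforced against it.
#' @return Integer respondents x items matrix with respondent ids as
#'   rownames.
#' @export
read_responses <- function(path, spec) {
  stopifnot(inherits(spec, "scale_spec"))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L)
    stop("file must have an id column plus at least one item column",
         call. = FALSE)
  if (tolower(names(df)[1L]) != "id")
    stop("first column must be named 'id'", call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicated respondent id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  if (ncol(df) - 1L != spec$n_items)
    stop(sprintf("file has %d item columns but the scale has %d items",
                 ncol(df) - 1L, spec$n_items), call. = FALSE)
  cells <- as.matrix(df[, -1L, drop = FALSE])
  for (i in seq_len(nrow(cells))) {
    for (j in seq_len(ncol(cells))) {
      v <- trimws(cells[i, j])
      if (!nzchar(v) || is.na(v) || toupper(v) == "NA")
        stop(sprintf("missing response at row %d (id '%s'), item column %d ('%s')",
                     i, ids[i], j, colnames(cells)[j]), call. = FALSE)
      if (!grepl("^-?[0-9]+$", v))
        stop(sprintf("non-integer response '%s' at row %d (id '%s'), item column %d ('%s')",
                     v, i, ids[i], j, colnames(cells)[j]), call. = FALSE)
      x <- as.integer(v)
      if (x < spec$scale_min || x > spec$scale_max)
        stop(sprintf("response %d at row %d (id '%s'), item column %d ('%s') outside scale bounds [%d, %d]",
                     x, i, ids[i], j, colnames(cells)[j],
                     spec$scale_min, spec$scale_max), call. = FALSE)
    }
  }
  mat <- matrix(as.integer(cells), nrow = nrow(cells),
                dimnames = list(ids, colnames(cells)))
  mat
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_responses()]: writes an `id` column from the rownames
#' followed by one column per item. A write-then-read round trip restores
#' the matrix exactly.
#'
#' @param mat respondents x items matrix (rownames used as ids; row numbers
#'   if absent).
#' @param path output CSV path.
#' @export
write_responses <- function(mat, path) {
  mat <- as.matrix(mat)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  items <- colnames(mat)
  if (is.null(items)) items <- paste0("item", seq_len(ncol(mat)))
  df <- data.frame(id = ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", items)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Describe a response matrix
#'
#' Scale-level description used before any change analysis: Cronbach's
#' alpha, total-score mean and SD, the standard error of measurement, item
#' means, and the count of degenerate (constant-response) respondents.
#'
#' @param mat respondents x items matrix (or CSV path).
#' @param spec a [scale_spec()]; inverse items are recoded before summary.
#' @return A list with `reliability` (a `"reliability_stats"`),
#'   `item_means`, `n_degenerate`.
#' @export
describe_responses <- function(mat, spec) {
  if (is.character(mat)) mat <- read_responses(mat, spec)
  mat <- recode_inverse(validate_matrix(mat, spec), spec)
  list(reliability = estimate_reliability(mat),
       item_means = colMeans(mat),
       n_degenerate = sum(apply(mat, 1L, is_degenerate)))
}

#' Two-administration change detection from files or matrices
#'
#' End-to-end pre/post workflow: read and validate both administrations,
#' align respondents by id, run [reliable_change()], and optionally write
#' the per-respondent TSV report plus text and JSON summaries.
#'
#' @param pre,post CSV paths (see [read_responses()]) or matrices.
#' @param spec a [scale_spec()]; `spec$direction` selects the decision
#'   rule.
#' @param ... passed to [reliable_change()] (`method`, `level`, `B`,
#'   `seed`, `paper_rounding`, `one_sided_percentile`, `stats_source`).
#' @param intersect when ids differ between files, analyse the common
#'   respondents instead of aborting.
#' @param output_prefix if non-NULL, write `<prefix>_respondents.tsv`,
#'   `<prefix>_summary.txt` and `<prefix>_summary.json`.
#' @return The `"reliable_change"` object, invisibly when a report is
#'   written.
#' @export
run_detect <- function(pre, post, spec, ..., intersect = FALSE,
                       output_prefix = NULL) {
  if (is.character(pre)) pre <- read_responses(pre, spec)
  if (is.character(post)) post <- read_responses(post, spec)
  if (!is.null(rownames(pre)) && !is.null(rownames(post)) &&
      !identical(rownames(pre), rownames(post))) {
    common <- intersect(rownames(pre), rownames(post))
    missing_ids <- union(setdiff(rownames(pre), common),
                         setdiff(rownames(post), common))
    if (!intersect)
      stop(sprintf("respondent ids differ between administrations (%s); use intersect = TRUE to analyse the %d common respondents",
                   paste(missing_ids, collapse = ", "), length(common)),
           call. = FALSE)
    if (length(common) == 0L)
      stop("no common respondent ids between administrations", call. = FALSE)
    pre <- pre[common, , drop = FALSE]
    post <- post[common, , drop = FALSE]
  }
  fit <- reliable_change(pre, post, spec, ...)
  if (!is.null(output_prefix)) {
    write_report(fit, output_prefix)
    return(invisible(fit))
  }
  fit
}

#' Single-administration split-half workflow
#'
#' For a single administration treated as two simultaneous parallel forms:
#' recode inverse items, construct ABBA half-tests, then run the two-sided
#' change detection between the half-test scores. All significant verdicts
#' are false positives by construction, so the resulting rates estimate
#' each method's empirical false-positive behaviour on this sample.
#'
#' @param mat CSV path or respondents x items matrix (single
#'   administration).
#' @param spec a [scale_spec()] for the full test.
#' @param ... passed to [reliable_change()].
#' @param alpha_level level for the parallel-forms equivalence tests.
#' @param output_prefix as in [run_detect()].
#' @return A list of class `"split_detect"`: `split` (the
#'   `"split_result"`) and `fit` (the `"reliable_change"` between halves).
#' @export
run_split <- function(mat, spec, ..., alpha_level = 0.05,
                      output_prefix = NULL) {
  if (is.character(mat)) mat <- read_responses(mat, spec)
  mat <- validate_matrix(mat, spec)
  sp <- split_half(mat, spec, alpha_level)
  recoded <- recode_inverse(mat, spec)
  h1 <- recoded[, sp$half1_items, drop = FALSE]
  h2 <- recoded[, sp$half2_items, drop = FALSE]
  # the halves may differ in size when J is odd; each gets its own spec
  spec1 <- scale_spec(ncol(h1), spec$scale_min, spec$scale_max,
                      direction = "two_sided")
  spec2 <- scale_spec(ncol(h2), spec$scale_min, spec$scale_max,
                      direction = "two_sided")
  if (ncol(h1) != ncol(h2)) {
    warning("halves differ in size; detection compares unequal half-tests",
            call. = FALSE)
    # detection needs a common item count; this path is flagged, not run
    fit <- NULL
  } else {
    fit <- reliable_change(h1, h2, spec1, ...)
  }
  out <- structure(list(split = sp, fit = fit, spec_half1 = spec1,
                        spec_half2 = spec2),
                   class = "split_detect")
  if (!is.null(output_prefix) && !is.null(fit)) {
    write_report(fit, output_prefix)
    return(invisible(out))
  }
  out
}

#' @export
print.split_detect <- function(x, ...) {
  print(x$split)
  if (!is.null(x$fit)) {
    cat("\n")
    print(x$fit)
  } else {
    cat("Detection between halves skipped (unequal half sizes)\n")
  }
  invisible(x)
}

#' Write the per-respondent and summary reports
#'
#' Produces the three report files for a [reliable_change()] fit:
#' a per-respondent TSV (scores, every interval bound, verdicts and flags),
#' a human-readable "n (percent)" summary, and a machine-readable JSON
#' summary. Every file carries the full configuration (seed, B, method,
#' level, package version) in its header for auditability, so reports
#' reproduce bit-identically from the inputs and the config.
#'
#' @param fit a `"reliable_change"` object.
#' @param prefix path prefix for the three output files.
#' @return The paths written, invisibly.
#' @export
write_report <- function(fit, prefix) {
  stopifnot(inherits(fit, "reliable_change"))
  cfg <- fit$config
  hdr <- sprintf(
    "# itemboot %s | method=%s level=%g B=%d seed=%d direction=%s paper_rounding=%s stats_source=%s",
    as.character(utils::packageVersion("itemboot")), cfg$method, cfg$level,
    cfg$B, cfg$seed, cfg$direction, cfg$paper_rounding, cfg$stats_source)

  tsv <- paste0(prefix, "_respondents.tsv")
  con <- file(tsv, "w")
  writeLines(hdr, con)
  utils::write.table(fit$respondents, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  close(con)

  txt <- paste0(prefix, "_summary.txt")
  lines <- c(hdr, "", "Cases classified as showing no overlap (significant change):")
  for (s in fit$summaries)
    lines <- c(lines, sprintf("  %-14s %d (%s)  [N evaluated = %d, indeterminate = %d]",
                              s$method, s$n_significant,
                              if (is.na(s$percent_significant)) "-"
                              else sprintf("%.1f", s$percent_significant),
                              s$n_evaluated, s$n_indeterminate))
  writeLines(lines, txt)

  json <- paste0(prefix, "_summary.json")
  payload <- list(
    config = cfg,
    version = as.character(utils::packageVersion("itemboot")),
    summaries = lapply(fit$summaries, function(s)
      s[c("method", "n_evaluated", "n_indeterminate", "n_significant",
          "n_ties", "percent_significant")]))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(c(tsv, txt, json))
}

#' Read a run configuration file
#'
#' Reads a YAML key-value file mirroring the analysis configuration:
#' scale fields (`n_items`, `scale_min`, `scale_max`, `inverse_items` with
#' 1-based indices, `direction`) plus `method`, `level`, `B`, `seed`,
#' `paper_rounding`, `one_sided_percentile`, `stats_source`.
#'
#' @param path YAML file path.
#' @return List with `spec` (a [scale_spec()]) and `args` (arguments for
#'   [reliable_change()] / [run_detect()]).
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("n_items", "scale_min", "scale_max")
  if (!all(need %in% names(cfg)))
    stop(sprintf("config must define %s", paste(need, collapse = ", ")),
         call. = FALSE)
  spec <- scale_spec(cfg$n_items, cfg$scale_min, cfg$scale_max,
                     inverse_items = cfg$inverse_items %||% integer(),
                     direction = cfg$direction %||% "two_sided")
  args <- cfg[intersect(names(cfg),
                        c("method", "level", "B", "seed", "paper_rounding",
                          "one_sided_percentile", "stats_source"))]
  list(spec = spec, args = args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
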