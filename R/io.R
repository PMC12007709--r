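#' Read and write design JSON
#'
#' The on-disk format is
#' `{"label": "...", "stages": [{"sensitive_prob": 0.2}, ...]}` with stages
#' in visit order; the writer echoes the derived continuation product `Q`
#' for human inspection (the reader ignores it and revalidates).
#'
#' @param path File path.
#' @return `read_design_json()` returns an [rr_design()];
#'   `write_design_json()` returns `path` invisibly.
#' @export
read_design_json <- function(path) {
  if (!file.exists(path)) {
    abort_rr(sprintf("design file not found: %s", path),
             class = "rrstage_error_parse")
  }
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    abort_rr(sprintf("cannot parse design JSON %s: %s",
                                     path, conditionMessage(e)),
                             class = "rrstage_error_parse")
                  })
  if (is.null(obj$stages) || length(obj$stages) == 0) {
    abort_rr(sprintf("design JSON %s has no stages", path),
             class = "rrstage_error_parse")
  }
  probs <- vapply(obj$stages, function(s) {
    v <- s$sensitive_prob
    if (is.null(v) || !is.numeric(v)) {
      abort_rr(sprintf("design JSON %s: every stage needs a numeric sensitive_prob", path),
               class = "rrstage_error_parse")
    }
    as.numeric(v)
  }, numeric(1))
  rr_design(sensitive = probs, label = obj$label %||% NULL)
}

#' @param design An [rr_design()].
#' @rdname read_design_json
#' @export
write_design_json <- function(design, path) {
  assert_design(design)
  jsonlite::write_json(
    list(
      label = design$label,
      stages = lapply(design$sensitive, function(p) list(sensitive_prob = p)),
      Q = design$Q
    ),
    path, auto_unbox = TRUE, digits = 12
  )
  invisible(path)
}

#' Read per-respondent answers into survey counts
#'
#' Expects a CSV with header `respondent_id,answer` and `answer` in
#' `{yes, no}` (any case). Any other token is a parse error naming the
#' offending line; an empty file (no data rows) is an empty-sample error.
#'
#' @param path CSV file path.
#' @return A list with `n` and `yes_count`.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) {
    abort_rr(sprintf("responses file not found: %s", path),
             class = "rrstage_error_parse")
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", strip.white = TRUE),
    error = function(e) {
      abort_rr(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
               class = "rrstage_error_parse")
    }
  )
  if (!all(c("respondent_id", "answer") %in% names(df))) {
    abort_rr(sprintf("%s: header must contain respondent_id,answer", path),
             class = "rrstage_error_parse")
  }
  if (nrow(df) == 0) {
    abort_rr(sprintf("%s: no respondents", path),
             class = "rrstage_error_empty_sample")
  }
  ans <- tolower(df$answer)
  bad <- which(!ans %in% c("yes", "no"))
  if (length(bad) > 0) {
    abort_rr(
      sprintf("%s: invalid answer '%s' on line %d (expected yes/no)",
              path, df$answer[bad[1]], bad[1] + 1L),
      class = "rrstage_error_parse"
    )
  }
  list(n = nrow(df), yes_count = sum(ans == "yes"))
}

#' Write a simulated survey to CSV
#'
#' Columns `respondent_id,answer`, plus `truth,terminal_stage` when the
#' survey was simulated with `keep_truth = TRUE`. Output is byte-identical
#' for identical survey objects.
#'
#' @param survey An `rr_survey` from [simulate_survey()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(survey, path) {
  if (!inherits(survey, "rr_survey")) {
    abort_rr("`survey` must be an rr_survey", class = "rrstage_error_parse")
  }
  df <- as.data.frame(survey$respondents)
  if ("truth" %in% names(df)) df$truth <- ifelse(df$truth, "true", "false")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
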