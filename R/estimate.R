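#' Estimate prevalence from randomized-response survey counts
#'
#' Inverts the affine yes-probability \eqn{\alpha = (1 - 2Q)\pi + Q}:
#' \deqn{\hat\pi = (\hat\alpha - Q) / (1 - 2Q), \qquad Q \ne 0.5,}
#' with \eqn{\hat\alpha} the sample fraction of "yes" answers. The raw
#' estimator is unbiased but can fall outside `[0, 1]`; both the raw value
#' and its truncation to the unit interval are reported. With `n >= 2` the
#' unbiased variance estimator
#' \eqn{\hat V = \hat\alpha(1 - \hat\alpha) (1 - 2Q)^{-2} / (n - 1)}
#' is attached.
#'
#' @param design An [rr_design()]; must not be singular (`Q` away from 0.5).
#' @param n Number of respondents (positive integer).
#' @param yes_count Number of "yes" answers, `0 <= yes_count <= n`.
#' @param conf_level Optional confidence level in `(0, 1)`; when supplied a
#'   Wald interval is attached (see [wald_interval()]).
#'
#' @return An `rr_estimate` object with fields `alpha_hat`, `pi_hat_raw`,
#'   `pi_hat` (truncated), `var_hat` (`NA` when `n < 2`), `n`, `yes_count`,
#'   `Q`, `label`, and optionally `conf_low`, `conf_high`, `conf_level`.
#'   Use [generics::tidy()] for a one-row tibble.
#'
#' @examples
#' d <- rr_design(continue_probs = c(0.8, 0.5, 0.5, 0.5))
#' estimate_pi(d, n = 1000, yes_count = 340, conf_level = 0.95)
#' @export
estimate_pi <- function(design, n, yes_count, conf_level = NULL) {
  assert_estimable(design)
  check_counts(n, yes_count)
  Q <- design$Q
  alpha_hat <- yes_count / n
  pi_hat_raw <- (alpha_hat - Q) / (1 - 2 * Q)
  var_hat <- if (n >= 2) {
    alpha_hat * (1 - alpha_hat) / ((1 - 2 * Q)^2 * (n - 1))
  } else {
    NA_real_
  }
  out <- structure(
    list(
      alpha_hat = alpha_hat,
      pi_hat_raw = pi_hat_raw,
      pi_hat = min(1, max(0, pi_hat_raw)),
      var_hat = var_hat,
      n = as.integer(n),
      yes_count = as.integer(yes_count),
      Q = Q,
      label = design$label
    ),
    class = "rr_estimate"
  )
  if (!is.null(conf_level)) out <- wald_interval(out, conf_level)
  out
}

check_counts <- function(n, yes_count) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    abort_rr("`n` must be a positive integer", class = "rrstage_error_empty_sample")
  }
  if (length(yes_count) != 1L || is.na(yes_count) || yes_count < 0 ||
      yes_count > n || yes_count != round(yes_count)) {
    abort_rr("`yes_count` must be an integer in [0, n]",
             class = "rrstage_error_invalid_counts")
  }
  invisible(NULL)
}

#' Theoretical variance of the prevalence estimator
#'
#' \deqn{V(\hat\pi) = [\pi(1 - \pi) + Q(1 - Q)(1 - 2Q)^{-2}] / n:}
#' the binomial sampling term plus a design penalty that depends only on
#' \eqn{Q}. Vectorized over `pi`.
#'
#' @inheritParams estimate_pi
#' @param pi True prevalence in `[0, 1]`.
#' @return Non-negative variance (same length as `pi`).
#' @export
theoretical_variance <- function(design, pi, n) {
  assert_estimable(design)
  check_unit(pi, "pi")
  if (n < 1) abort_rr("`n` must be positive", class = "rrstage_error_empty_sample")
  Q <- design$Q
  (pi * (1 - pi) + Q * (1 - Q) / (1 - 2 * Q)^2) / n
}

#' Unbiased variance estimator
#'
#' \eqn{\hat V = \hat\alpha(1 - \hat\alpha)(1 - 2Q)^{-2}/(n - 1)}. Dividing
#' by `n - 1` rather than `n` is what makes \eqn{E[\hat V] = V(\hat\pi)},
#' since \eqn{E[\hat\alpha(1-\hat\alpha)] = \alpha(1-\alpha)(n-1)/n}.
#'
#' @inheritParams estimate_pi
#' @return The variance estimate (requires `n >= 2`).
#' @export
estimate_variance <- function(design, n, yes_count) {
  assert_estimable(design)
  check_counts(n, yes_count)
  if (n < 2) {
    abort_rr("variance estimation needs n >= 2",
             class = "rrstage_error_insufficient_sample")
  }
  alpha_hat <- yes_count / n
  alpha_hat * (1 - alpha_hat) / ((1 - 2 * design$Q)^2 * (n - 1))
}

#' Wald confidence interval for the prevalence
#'
#' Normal-approximation interval on the raw (unbiased) scale,
#' \eqn{\hat\pi_{raw} \pm z_{(1+level)/2} \sqrt{\hat V}}, clamped to
#' `[0, 1]` afterwards.
#'
#' @param result An `rr_estimate` from [estimate_pi()] with `var_hat` present.
#' @param level Confidence level in `(0, 1)`.
#' @return The `rr_estimate` with `conf_low`, `conf_high`, `conf_level` set.
#' @export
wald_interval <- function(result, level = 0.95) {
  if (!inherits(result, "rr_estimate")) {
    abort_rr("`result` must be an rr_estimate", class = "rrstage_error_invalid_design")
  }
  if (is.na(result$var_hat)) {
    abort_rr("no variance estimate available (n < 2)",
             class = "rrstage_error_missing_variance")
  }
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1) {
    abort_rr("`level` must lie strictly between 0 and 1",
             class = "rrstage_error_invalid_probability")
  }
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(result$var_hat)
  result$conf_low <- min(1, max(0, result$pi_hat_raw - half))
  result$conf_high <- min(1, max(0, result$pi_hat_raw + half))
  result$conf_level <- level
  result
}

#' @export
print.rr_estimate <- function(x, ...) {
  cat(sprintf("<rr_estimate> %s (Q = %.6g)\n", x$label, x$Q))
  cat(sprintf("  n = %d, yes = %d, alpha_hat = %.6g\n", x$n, x$yes_count, x$alpha_hat))
  cat(sprintf("  pi_hat = %.6g (raw %.6g), var_hat = %.6g\n",
              x$pi_hat, x$pi_hat_raw, x$var_hat))
  if (!is.null(x$conf_level)) {
    cat(sprintf("  %g%% Wald CI: [%.6g, %.6g]\n",
                100 * x$conf_level, x$conf_low, x$conf_high))
  }
  invisible(x)
}

#' Tidy a prevalence estimate
#'
#' @param x An `rr_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the estimate, raw estimate, standard error and
#'   any interval.
#' @method tidy rr_estimate
#' @export
tidy.rr_estimate <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    Q = x$Q,
    n = x$n,
    yes_count = x$yes_count,
    alpha_hat = x$alpha_hat,
    pi_hat = x$pi_hat,
    pi_hat_raw = x$pi_hat_raw,
    std_error = sqrt(x$var_hat),
    conf_low = x$conf_low %||% NA_real_,
    conf_high = x$conf_high %||% NA_real_,
    conf_level = x$conf_level %||% NA_real_
  )
}

#' @rdname tidy.rr_estimate
#' @method glance rr_estimate
#' @export
glance.rr_estimate <- function(x, ...) {
  tibble::tibble(n = x$n, Q = x$Q, pi_hat = x$pi_hat, var_hat = x$var_hat)
}
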