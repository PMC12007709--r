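#' Privacy-protection measure of a design
#'
#' Summarizes how much a single answer reveals about carrier status through
#' the posterior odds. With \eqn{\tau_y = (1-Q)/Q} and \eqn{\tau_n = Q/(1-Q)}
#' (the likelihood ratios of the two answers), the measure is
#' \deqn{M = \frac{(1 - 2Q)^2}{2 Q (1 - Q)} = \frac{\tau_y + \tau_n}{2} - 1.}
#' \eqn{M = 0} exactly at \eqn{Q = 0.5} (answers carry no information:
#' maximal privacy, but the estimator is undefined there); \eqn{M} grows
#' without bound as \eqn{Q \to 0} or \eqn{Q \to 1} (no privacy). Smaller
#' \eqn{M} means more privacy and, through [variance_via_privacy()], larger
#' estimator variance.
#'
#' @param design An [rr_design()].
#' @return An `rr_privacy` object: list with `tau_yes`, `tau_no`, `measure`,
#'   `unbounded` (TRUE when `Q` is 0 or 1, where the measure is infinite),
#'   `Q` and `label`. [generics::tidy()] gives a one-row tibble.
#' @examples
#' privacy_measure(rr_design(continue_probs = c(0.5, 0.5, 0.5, 0.8)))
#' @export
privacy_measure <- function(design) {
  assert_design(design)
  Q <- design$Q
  if (Q == 0 || Q == 1) {
    out <- list(tau_yes = Inf, tau_no = Inf, measure = Inf,
                unbounded = TRUE, Q = Q, label = design$label)
  } else {
    out <- list(
      tau_yes = (1 - Q) / Q,
      tau_no = Q / (1 - Q),
      measure = (1 - 2 * Q)^2 / (2 * Q * (1 - Q)),
      unbounded = FALSE, Q = Q, label = design$label
    )
  }
  structure(out, class = "rr_privacy")
}

#' @export
print.rr_privacy <- function(x, ...) {
  cat(sprintf("<rr_privacy> %s (Q = %.6g)\n", x$label, x$Q))
  if (x$unbounded) {
    cat("  no privacy: answers reveal status deterministically (measure unbounded)\n")
  } else {
    cat(sprintf("  tau_yes = %.6g, tau_no = %.6g, measure M = %.6g\n",
                x$tau_yes, x$tau_no, x$measure))
  }
  invisible(x)
}

#' @param x An `rr_privacy` object.
#' @param ... Unused.
#' @rdname privacy_measure
#' @method tidy rr_privacy
#' @export
tidy.rr_privacy <- function(x, ...) {
  tibble::tibble(
    label = x$label, Q = x$Q,
    tau_yes = x$tau_yes, tau_no = x$tau_no,
    measure = x$measure, unbounded = x$unbounded
  )
}

#' Estimator variance through the privacy decomposition
#'
#' The variance splits exactly into a sampling term and a privacy term:
#' \deqn{V(\hat\pi) = \frac{\pi(1-\pi)}{n} + \frac{1}{2 n M},}
#' where \eqn{M} is [privacy_measure()]. This equals [theoretical_variance()]
#' identically (the module's central self-check): more privacy (smaller
#' \eqn{M}) costs variance.
#'
#' @inheritParams theoretical_variance
#' @return The variance, identical to [theoretical_variance()].
#' @export
variance_via_privacy <- function(design, pi, n) {
  assert_estimable(design)
  check_unit(pi, "pi")
  pm <- privacy_measure(design)
  if (pm$measure == 0) {
    abort_rr("singular design: privacy measure is zero, variance unbounded",
             class = "rrstage_error_singular")
  }
  pi * (1 - pi) / n + 1 / (2 * n * pm$measure)
}
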