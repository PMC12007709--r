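#' Construct a j-stage randomized-response design
#'
#' A j-stage randomizing device presents, at each stage visited, either the
#' direct sensitive question (with the stage's *sensitive* probability) or
#' passes the respondent to the next stage (the complementary *continuation*
#' probability). At the final stage the continuation branch is instead the
#' Warner-style complement question ("do you NOT carry the attribute?"). All
#' inference depends on the design only through
#' \eqn{Q = \prod_g q_g}, the product of the continuation probabilities.
#'
#' Probabilities are supplied in visit order (stage 1 first). Exactly one of
#' `sensitive` and `continue_probs` must be given; they are complements.
#' Endpoint values 0 and 1 are allowed (degenerate but well-defined devices);
#' only designs with \eqn{Q} within `1e-9` of 0.5 are flagged singular, because
#' the prevalence estimator \eqn{(\hat\alpha - Q)/(1 - 2Q)} is undefined there.
#' Probability evaluation still works on singular designs; estimation errors.
#'
#' @param sensitive Numeric vector in `[0, 1]`: per-stage probability that the
#'   sensitive question is presented, stage 1 first.
#' @param continue_probs Numeric vector in `[0, 1]`: per-stage continuation
#'   (final stage: complement-question) probabilities; `1 - sensitive`.
#' @param label Optional character label carried through reports.
#'
#' @return An object of class `rr_design`: a list with elements `sensitive`,
#'   `continue_probs`, `Q` (the continuation product), `j` (stage count),
#'   `singular` (logical) and `label`.
#'
#' @examples
#' rr_design(continue_probs = c(0.8, 0.5, 0.5, 0.5)) # Q = 0.1
#' warner_design(q1 = 0.3)
#' @export
rr_design <- function(sensitive = NULL, continue_probs = NULL, label = NULL) {
  if (is.null(sensitive) == is.null(continue_probs)) {
    abort_rr("supply exactly one of `sensitive` or `continue_probs`",
             class = "rrstage_error_invalid_design")
  }
  p <- if (is.null(sensitive)) 1 - continue_probs else sensitive
  if (length(p) < 1L) {
    abort_rr("a design needs at least one stage",
             class = "rrstage_error_invalid_design")
  }
  if (!is.numeric(p) || anyNA(p)) {
    abort_rr("stage probabilities must be numeric and non-missing",
             class = "rrstage_error_invalid_probability")
  }
  if (any(p < 0 | p > 1)) {
    abort_rr("stage probabilities must lie in [0, 1]",
             class = "rrstage_error_invalid_probability")
  }
  p <- as.numeric(p)
  q <- 1 - p
  Q <- prod(q)
  structure(
    list(
      sensitive = p,
      continue_probs = q,
      Q = Q,
      j = length(p),
      singular = abs(Q - 0.5) < singular_tol(),
      label = label %||% paste0(length(p), "-stage design")
    ),
    class = "rr_design"
  )
}

# Q = 0.5 exclusion band for estimation
singular_tol <- function() 1e-9

#' @export
print.rr_design <- function(x, ...) {
  cat(sprintf("<rr_design> %s\n", x$label))
  cat(sprintf("  stages (sensitive prob, visit order): %s\n",
              paste(format(x$sensitive), collapse = ", ")))
  cat(sprintf("  Q = %s%s\n", format(x$Q, digits = 12),
              if (x$singular) "  [singular: estimation disabled]" else ""))
  invisible(x)
}

#' @describeIn rr_design Warner's one-stage design: with probability
#'   `p1 = 1 - q1` the sensitive question, otherwise its complement.
#' @param q1,q2,q3 Continuation probabilities of the named special cases.
#' @export
warner_design <- function(q1, label = "Warner") {
  rr_design(continue_probs = q1, label = label)
}

#' @describeIn rr_design Mangat & Singh's two-stage design.
#' @export
mangat_singh_design <- function(q1, q2, label = "Mangat-Singh") {
  rr_design(continue_probs = c(q1, q2), label = label)
}

#' @describeIn rr_design The three-stage design of Aboalkhair.
#' @export
aboalkhair_design <- function(q1, q2, q3, label = "Aboalkhair") {
  rr_design(continue_probs = c(q1, q2, q3), label = label)
}

assert_design <- function(design) {
  if (!inherits(design, "rr_design")) {
    abort_rr("`design` must be an rr_design object",
             class = "rrstage_error_invalid_design")
  }
  invisible(design)
}

assert_estimable <- function(design) {
  assert_design(design)
  if (design$singular) {
    abort_rr(
      sprintf("design is singular (Q = %.12g is within 1e-9 of 0.5); the estimator is undefined",
              design$Q),
      class = "rrstage_error_singular"
    )
  }
  invisible(design)
}

#' Probability of a "yes" answer under a design
#'
#' Computes \eqn{\alpha = P(\mathrm{yes})} for a given prevalence \eqn{\pi}.
#' The closed form is affine in \eqn{\pi}: \eqn{\alpha = (1 - 2Q)\pi + Q}.
#' `method = "recursive"` instead walks the device stage by stage — the
#' final Warner stage contributes \eqn{p_j \pi + q_j (1 - \pi)} and each
#' earlier stage \eqn{g} wraps it as \eqn{p_g \pi + q_g \cdot (\cdot)} —
#' and serves as the reference implementation the closed form is checked
#' against.
#'
#' @param design An [rr_design()].
#' @param pi Prevalence of the sensitive attribute, in `[0, 1]`. Vectorized
#'   for the closed form.
#' @param method `"closed"` (default, vectorized) or `"recursive"`.
#' @return Probability of a "yes" answer.
#' @export
alpha_of_pi <- function(design, pi, method = c("closed", "recursive")) {
  assert_design(design)
  method <- match.arg(method)
  check_unit(pi, "pi")
  if (method == "closed") {
    return((1 - 2 * design$Q) * pi + design$Q)
  }
  vapply(pi, function(pp) {
    p <- design$sensitive
    q <- design$continue_probs
    j <- design$j
    acc <- p[j] * pp + q[j] * (1 - pp)
    g <- j - 1L
    while (g >= 1L) {
      acc <- p[g] * pp + q[g] * acc
      g <- g - 1L
    }
    acc
  }, numeric(1))
}

#' Answer probabilities conditional on carrier status
#'
#' For a carrier the answer is "yes" unless the complement branch of the
#' final stage is reached, so \eqn{P(\mathrm{yes} \mid D) = 1 - Q} and
#' \eqn{P(\mathrm{yes} \mid \bar D) = Q}.
#'
#' @inheritParams alpha_of_pi
#' @return A tibble with one row per answer (`"yes"`, `"no"`) and columns
#'   `given_carrier`, `given_noncarrier`; each column sums to 1.
#' @export
conditional_probs <- function(design) {
  assert_design(design)
  Q <- design$Q
  tibble::tibble(
    answer = c("yes", "no"),
    given_carrier = c(1 - Q, Q),
    given_noncarrier = c(Q, 1 - Q)
  )
}

#' Posterior carrier probabilities given the answer
#'
#' Bayes' rule applied to [conditional_probs()]:
#' \eqn{P(D \mid \mathrm{yes}) = \pi (1 - Q) / \alpha} and
#' \eqn{P(D \mid \mathrm{no}) = \pi Q / (1 - \alpha)}. An answer that has
#' probability zero under the design and prevalence has no defined posterior
#' and raises an error.
#'
#' @inheritParams alpha_of_pi
#' @return A tibble with columns `answer` and `posterior`
#'   (\eqn{P(D \mid \mathrm{answer})}).
#' @export
posterior_probs <- function(design, pi) {
  assert_design(design)
  check_unit(pi, "pi")
  Q <- design$Q
  alpha <- alpha_of_pi(design, pi)
  if (alpha == 0 || alpha == 1) {
    abort_rr(
      sprintf("answer '%s' has probability zero; its posterior is undefined",
              if (alpha == 0) "yes" else "no"),
      class = "rrstage_error_undefined_posterior"
    )
  }
  tibble::tibble(
    answer = c("yes", "no"),
    posterior = c(pi * (1 - Q) / alpha, pi * Q / (1 - alpha))
  )
}

check_unit <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort_rr(sprintf("`%s` must lie in [0, 1]", name),
             class = "rrstage_error_invalid_probability")
  }
  invisible(x)
}

abort_rr <- function(message, class) {
  rlang::abort(message, class = c(class, "rrstage_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
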