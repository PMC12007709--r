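#' Design-dependent variance component
#'
#' The estimator variance is \eqn{[\pi(1-\pi) + f(Q)]/n} with
#' \deqn{f(Q) = \frac{Q(1-Q)}{(1-2Q)^2}.}
#' \eqn{f} is symmetric about 0.5 (\eqn{f(Q) = f(1-Q)}), zero at the
#' endpoints, strictly increasing on `(0, 0.5)` and unbounded at the
#' singular point. Because the sampling term \eqn{\pi(1-\pi)/n} is common to
#' all same-`n` designs, every efficiency comparison in the package reduces
#' to comparing `f` values — free of both \eqn{\pi} and `n`.
#'
#' @param Q Continuation product(s) in `[0, 1]`, away from 0.5. Vectorized.
#' @return `f(Q)`.
#' @examples
#' variance_component(0.1) # 0.140625
#' @export
variance_component <- function(Q) {
  check_unit(Q, "Q")
  if (any(abs(Q - 0.5) < singular_tol())) {
    abort_rr("Q = 0.5 is the singular point; the variance component is unbounded",
             class = "rrstage_error_singular")
  }
  Q * (1 - Q) / (1 - 2 * Q)^2
}

#' Compare the efficiency of two designs
#'
#' Reports `diff = f(Q_b) - f(Q_a)` where `f` is [variance_component()];
#' `diff` equals \eqn{n (V_b - V_a)} for any prevalence and sample size, so
#' `a` dominates (is more efficient than) `b` exactly when `diff > 0`. When
#' `b`'s continuation probabilities are a visit-order prefix of `a`'s — the
#' nested case of a j-stage device against its own first j-g stages — the
#' closed-form dominance inequality (see [nested_condition()]) is also
#' evaluated and reported as `condition_holds`; otherwise that column is `NA`.
#'
#' @param a,b [rr_design()] objects, both non-singular.
#' @return A one-row tibble: labels, `Q_a`, `Q_b`, `f_a`, `f_b`, `diff`,
#'   `a_dominates`, `condition_holds`.
#' @export
compare_designs <- function(a, b) {
  assert_estimable(a)
  assert_estimable(b)
  f_a <- variance_component(a$Q)
  f_b <- variance_component(b$Q)
  nested <- b$j < a$j &&
    isTRUE(all.equal(a$continue_probs[seq_len(b$j)], b$continue_probs,
                     tolerance = 1e-12))
  cond <- if (nested) nested_condition(a, g = a$j - b$j) else NA
  tibble::tibble(
    label_a = a$label, label_b = b$label,
    Q_a = a$Q, Q_b = b$Q,
    f_a = f_a, f_b = f_b,
    diff = f_b - f_a,
    a_dominates = f_b - f_a > 0,
    condition_holds = cond
  )
}

#' Closed-form dominance condition for nested designs
#'
#' A j-stage design beats the sub-design made of its own first `j - g`
#' stages if and only if
#' \deqn{\prod_{\text{last } g \text{ stages}} q < \frac{1 - Q_{j-g}}{1 - Q_j},}
#' where \eqn{Q_{j-g}} is the prefix's continuation product. The inequality
#' is equivalent to \eqn{Q_j(1-Q_j) < Q_{j-g}(1-Q_{j-g})}, i.e. to a direct
#' comparison of variance components; both routes are property-tested
#' against each other.
#'
#' @param design A non-singular [rr_design()] with at least two stages.
#' @param g Number of trailing stages dropped, `1 <= g <= j - 1`; the prefix
#'   design (also required non-singular) keeps the first `j - g` stages.
#' @return Logical: does the full design strictly dominate its prefix?
#' @export
nested_condition <- function(design, g) {
  assert_estimable(design)
  j <- design$j
  if (length(g) != 1L || is.na(g) || g != round(g) || g < 1 || g > j - 1) {
    abort_rr("`g` must be an integer in [1, j - 1]",
             class = "rrstage_error_index")
  }
  q <- design$continue_probs
  Q_prefix <- prod(q[seq_len(j - g)])
  if (abs(Q_prefix - 0.5) < singular_tol()) {
    abort_rr("the (j - g)-stage prefix design is singular",
             class = "rrstage_error_singular")
  }
  trailing <- prod(q[(j - g + 1L):j])
  trailing < (1 - Q_prefix) / (1 - design$Q)
}

#' Single-stage design with matching efficiency
#'
#' Finds the Warner continuation probability `q` in `(0, 0.5)` whose
#' variance component equals the input design's: the root of
#' `f(q) = f(Q)`. By the symmetry of `f` this is `min(Q, 1 - Q)` in closed
#' form; the root is located numerically and checked against that value.
#'
#' @param design A non-singular [rr_design()] with `0 < Q < 1`.
#' @param tol Root-finding tolerance.
#' @return The matched single-stage continuation probability in `(0, 0.5)`.
#' @examples
#' matched_single_stage_q(rr_design(continue_probs = c(0.8, 0.5, 0.5, 0.5))) # 0.1
#' @export
matched_single_stage_q <- function(design, tol = 1e-12) {
  assert_estimable(design)
  Q <- design$Q
  if (Q == 0 || Q == 1) {
    abort_rr("degenerate design (Q of 0 or 1) has zero variance component; any match is trivial",
             class = "rrstage_error_infeasible")
  }
  target <- variance_component(Q)
  root <- stats::uniroot(
    function(q) variance_component(q) - target,
    lower = 1e-12, upper = 0.5 - 1e-9, tol = tol, extendInt = "no"
  )$root
  closed <- min(Q, 1 - Q)
  stopifnot(abs(root - closed) < 1e-6)
  closed
}

#' Leading continuation probability matching a target efficiency
#'
#' Given fixed trailing continuation probabilities, returns the leading
#' probability `q1` such that the design `(q1, trailing...)` has the same
#' variance component as `design`:
#' `q1 = min(Q, 1 - Q) / prod(trailing)` on the sub-0.5 branch of the total
#' product. Errors when the required `q1` falls outside `(0, 1)`.
#'
#' @inheritParams matched_single_stage_q
#' @param fixed_trailing Numeric vector of trailing continuation
#'   probabilities for the comparison family (e.g. `0.5` for a two-stage
#'   match, `c(0.5, 0.5)` for three stages).
#' @return The matched leading continuation probability.
#' @examples
#' d <- rr_design(continue_probs = c(0.8, 0.5, 0.5, 0.5)) # Q = 0.1
#' matched_leading_q(d, 0.5)         # two-stage match: 0.2
#' matched_leading_q(d, c(0.5, 0.5)) # three-stage match: 0.4
#' @export
matched_leading_q <- function(design, fixed_trailing) {
  assert_estimable(design)
  check_unit(fixed_trailing, "fixed_trailing")
  Q <- design$Q
  if (Q == 0 || Q == 1) {
    abort_rr("degenerate design (Q of 0 or 1): no nontrivial match",
             class = "rrstage_error_infeasible")
  }
  target_Q <- min(Q, 1 - Q)
  q1 <- target_Q / prod(fixed_trailing)
  if (!is.finite(q1) || q1 <= 0 || q1 >= 1) {
    abort_rr(
      sprintf("matched leading probability %.6g falls outside (0, 1): infeasible with the given trailing probabilities", q1),
      class = "rrstage_error_infeasible"
    )
  }
  q1
}

#' Efficiency-difference surface over a grid of stage probabilities
#'
#' Expands a grid over the four continuation probabilities of a four-stage
#' design and tabulates the efficiency difference
#' `diff = f(Q_baseline) - f(Q_proposed)` against a baseline family built
#' from the leading probabilities of the same grid point: `"warner"` uses
#' `q1`, `"mangat_singh"` uses `q1 q2`, `"aboalkhair"` uses `q1 q2 q3`, and
#' `"prefix"` uses the first `prefix_stages` probabilities. Positive `diff`
#' means the four-stage design is more efficient at that grid point. Grid
#' points where either design is singular are kept and flagged, with `diff`
#' set to `NA`.
#'
#' @param q1,q2,q3,q4 Numeric vectors of continuation probabilities; the
#'   grid is their Cartesian product. Defaults span the practicable range
#'   `0.1..0.4` for `q1`..`q2` and `0.1..0.9` for the varied axes.
#' @param baseline One of `"warner"`, `"mangat_singh"`, `"aboalkhair"`,
#'   `"prefix"`.
#' @param prefix_stages Number of leading stages kept when
#'   `baseline = "prefix"`.
#' @return A tibble with columns `q1..q4`, `Q_proposed`, `Q_baseline`,
#'   `diff`, `singular`.
#' @export
efficiency_surface <- function(q1 = seq(0.1, 0.4, by = 0.1),
                               q2 = seq(0.1, 0.4, by = 0.1),
                               q3 = seq(0.1, 0.9, by = 0.1),
                               q4 = seq(0.1, 0.9, by = 0.1),
                               baseline = c("warner", "mangat_singh",
                                            "aboalkhair", "prefix"),
                               prefix_stages = 1L) {
  baseline <- match.arg(baseline)
  for (v in list(q1, q2, q3, q4)) check_unit(v, "q")
  k <- switch(baseline,
    warner = 1L, mangat_singh = 2L, aboalkhair = 3L,
    prefix = as.integer(prefix_stages)
  )
  if (k < 1L || k > 3L) {
    abort_rr("`prefix_stages` must be 1, 2 or 3",
             class = "rrstage_error_index")
  }
  grid <- tidyr::expand_grid(q1 = q1, q2 = q2, q3 = q3, q4 = q4)
  Qp <- grid$q1 * grid$q2 * grid$q3 * grid$q4
  Qb <- switch(k, grid$q1, grid$q1 * grid$q2, grid$q1 * grid$q2 * grid$q3)
  singular <- abs(Qp - 0.5) < singular_tol() | abs(Qb - 0.5) < singular_tol()
  f_safe <- function(Q, bad) ifelse(bad, NA_real_, Q * (1 - Q) / (1 - 2 * Q)^2)
  out <- dplyr::mutate(
    grid,
    Q_proposed = Qp,
    Q_baseline = Qb,
    diff = f_safe(Qb, singular) - f_safe(Qp, singular),
    singular = singular
  )
  attr(out, "baseline") <- baseline
  class(out) <- c("rr_surface", class(out))
  out
}

#' Variance curves of the four nested estimators
#'
#' For each leading continuation probability `q1`, evaluates the theoretical
#' variance at prevalence `pi` and sample size `n` of the four-stage design
#' `(q1, trailing...)` and of the nested one-, two- and three-stage designs
#' sharing its leading probabilities (Warner, Mangat-Singh, three-stage).
#' With all trailing probabilities at 0.5 the four-stage curve lies below
#' every baseline wherever all are defined.
#'
#' @param q1_values Numeric vector of leading continuation probabilities.
#' @param trailing Three trailing continuation probabilities of the
#'   four-stage design (default `c(0.5, 0.5, 0.5)`).
#' @param pi Prevalence used for the curves.
#' @param n Sample size used for the curves.
#' @return A tibble with columns `q1`, `v_proposed`, `v_aboalkhair`,
#'   `v_mangat_singh`, `v_warner`; singular rows carry `NA` in the affected
#'   columns and are flagged in `singular`.
#' @export
variance_curves <- function(q1_values, trailing = c(0.5, 0.5, 0.5),
                            pi = 0.3, n = 1000) {
  check_unit(q1_values, "q1_values")
  check_unit(trailing, "trailing")
  if (length(trailing) != 3L) {
    abort_rr("`trailing` must have length 3", class = "rrstage_error_index")
  }
  check_unit(pi, "pi")
  v_at <- function(Q) {
    ifelse(abs(Q - 0.5) < singular_tol(), NA_real_,
           (pi * (1 - pi) + Q * (1 - Q) / (1 - 2 * Q)^2) / n)
  }
  Qw <- q1_values
  Qms <- q1_values * trailing[1]
  Qak <- Qms * trailing[2]
  Qp <- Qak * trailing[3]
  out <- tibble::tibble(
    q1 = q1_values,
    v_proposed = v_at(Qp),
    v_aboalkhair = v_at(Qak),
    v_mangat_singh = v_at(Qms),
    v_warner = v_at(Qw),
    singular = abs(cbind(Qw, Qms, Qak, Qp) - 0.5) |>
      apply(1, function(r) any(r < singular_tol()))
  )
  attr(out, "pi") <- pi
  attr(out, "n") <- n
  class(out) <- c("rr_curves", class(out))
  out
}

#' Plot an efficiency surface
#'
#' Tile map of the efficiency difference over the `q3`-`q4` plane, faceted
#' by `q1` and `q2`.
#'
#' @param object An `rr_surface` from [efficiency_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rr_surface
#' @export
autoplot.rr_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q3, y = .data$q4,
                                       fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(ggplot2::vars(.data$q1), ggplot2::vars(.data$q2),
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      title = sprintf("Efficiency advantage over the %s baseline",
                      attr(object, "baseline")),
      fill = "n(V_base - V_prop)"
    )
}

#' Plot variance curves
#'
#' @param object An `rr_curves` from [variance_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rr_curves
#' @export
autoplot.rr_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), -"singular"),
    -"q1", names_to = "estimator", values_to = "variance"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$q1, y = .data$variance,
                                     colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = sprintf("Estimator variance (pi = %g, n = %g)",
                      attr(object, "pi"), attr(object, "n")),
      x = "leading continuation probability q1", y = "variance"
    )
}
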