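#' Simulate one respondent's walk through the device
#'
#' Walks the stages in visit order: at each stage before the last, the
#' sensitive question is presented with that stage's sensitive probability
#' (the answer then reports the latent status truthfully) and otherwise the
#' respondent continues; at the final stage the alternative branch is the
#' Warner complement question, so the answer negates the latent status.
#' Truthful reporting is assumed throughout. Uses the current RNG stream;
#' seed control belongs to [simulate_survey()].
#'
#' @param design An [rr_design()].
#' @param has_attribute Logical: the respondent's latent carrier status.
#' @return A one-row tibble: `has_attribute`, `terminal_stage`, `answer`
#'   (`"yes"`/`"no"`).
#' @export
simulate_respondent <- function(design, has_attribute) {
  assert_design(design)
  stopifnot(is.logical(has_attribute), length(has_attribute) == 1L)
  j <- design$j
  p <- design$sensitive
  stage <- 1L
  repeat {
    direct <- stats::runif(1) < p[stage]
    if (stage == j) {
      ans <- if (direct) has_attribute else !has_attribute
      break
    }
    if (direct) {
      ans <- has_attribute
      break
    }
    stage <- stage + 1L
  }
  tibble::tibble(
    has_attribute = has_attribute,
    terminal_stage = stage,
    answer = if (ans) "yes" else "no"
  )
}

#' Simulate a randomized-response survey
#'
#' Draws `n` latent carrier statuses independently with probability `pi` and
#' walks each respondent through the device (vectorized stage walk,
#' respondents consumed in order from a single seeded stream). Identical
#' `(design, pi, n, seed)` give identical output.
#'
#' @inheritParams simulate_respondent
#' @param pi True prevalence in `[0, 1]`.
#' @param n Number of respondents.
#' @param seed Integer seed; every random draw in the survey derives from it.
#' @param keep_truth Keep the latent status and terminal stage in the
#'   per-respondent table? Default `FALSE`: the default output is what a
#'   real interviewer would see (answers only).
#' @return An `rr_survey` object: list with `n`, `yes_count`, `design` label
#'   and `Q`, `pi`, `seed`, and `respondents`, a tibble with
#'   `respondent_id`, `answer` (plus `truth`, `terminal_stage` when
#'   `keep_truth = TRUE`).
#' @export
simulate_survey <- function(design, pi, n, seed, keep_truth = FALSE) {
  assert_design(design)
  check_unit(pi, "pi")
  if (n < 1 || n != round(n)) {
    abort_rr("`n` must be a positive integer", class = "rrstage_error_empty_sample")
  }
  n <- as.integer(n)
  p <- design$sensitive
  j <- design$j
  res <- withr::with_seed(as.integer(seed), {
    truth <- stats::runif(n) < pi
    answer <- logical(n)
    terminal <- integer(n)
    active <- rep(TRUE, n)
    for (g in seq_len(j)) {
      u <- stats::runif(sum(active))
      direct <- u < p[g]
      idx <- which(active)
      if (g < j) {
        stopped <- idx[direct]
        answer[stopped] <- truth[stopped]
        terminal[stopped] <- g
        active[stopped] <- FALSE
      } else {
        answer[idx[direct]] <- truth[idx[direct]]
        answer[idx[!direct]] <- !truth[idx[!direct]]
        terminal[idx] <- g
        active[idx] <- FALSE
      }
    }
    list(truth = truth, answer = answer, terminal = terminal)
  })
  respondents <- tibble::tibble(
    respondent_id = seq_len(n),
    answer = ifelse(res$answer, "yes", "no")
  )
  if (keep_truth) {
    respondents$truth <- res$truth
    respondents$terminal_stage <- res$terminal
  }
  structure(
    list(
      n = n,
      yes_count = sum(res$answer),
      label = design$label,
      Q = design$Q,
      pi = pi,
      seed = as.integer(seed),
      respondents = respondents
    ),
    class = "rr_survey"
  )
}

#' @export
print.rr_survey <- function(x, ...) {
  cat(sprintf("<rr_survey> %s (Q = %.6g): n = %d, yes = %d (seed %d)\n",
              x$label, x$Q, x$n, x$yes_count, x$seed))
  invisible(x)
}

#' Monte-Carlo validation of the estimator theory
#'
#' Repeats the survey many times and aggregates the per-replicate estimates,
#' checking the theory empirically: the raw estimator should be unbiased,
#' its empirical variance should match the theoretical variance, the mean of
#' the unbiased variance estimator should match it too, and the Wald
#' interval should cover near its nominal level.
#'
#' The default `method = "binomial"` draws each replicate's yes-count
#' directly from Binomial(n, alpha) — the exact marginal distribution of the
#' yes-count over n independent respondents — so large studies run in
#' milliseconds. `method = "respondent"` walks every respondent through the
#' device instead; the two are statistically indistinguishable (a tested
#' property).
#'
#' @inheritParams simulate_survey
#' @param replicates Number of simulated surveys (>= 100).
#' @param level Confidence level for the coverage check.
#' @param method `"binomial"` (exact marginal, fast) or `"respondent"`.
#' @return An `rr_mc` object; `tidy()` gives the one-row summary with
#'   `mean_pi_hat`, `bias`, `empirical_var`, `theoretical_var`,
#'   `mean_var_hat`, `var_ratio` (empirical/theoretical),
#'   `var_hat_ratio` (mean estimated/theoretical) and `coverage`.
#' @export
monte_carlo_study <- function(design, pi, n, replicates, level = 0.95,
                              seed = 1L, method = c("binomial", "respondent")) {
  assert_estimable(design)
  check_unit(pi, "pi")
  method <- match.arg(method)
  if (replicates < 100) {
    abort_rr("`replicates` must be at least 100", class = "rrstage_error_index")
  }
  Q <- design$Q
  alpha <- alpha_of_pi(design, pi)
  yes <- withr::with_seed(as.integer(seed), {
    if (method == "binomial") {
      stats::rbinom(replicates, n, alpha)
    } else {
      vapply(seq_len(replicates), function(r) {
        truth <- stats::runif(n) < pi
        walk_yes_count(design, truth)
      }, numeric(1))
    }
  })
  alpha_hat <- yes / n
  pi_raw <- (alpha_hat - Q) / (1 - 2 * Q)
  var_hat <- alpha_hat * (1 - alpha_hat) / ((1 - 2 * Q)^2 * (n - 1))
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(var_hat)
  v_theory <- theoretical_variance(design, pi, n)
  structure(
    list(
      replicates = as.integer(replicates),
      n = as.integer(n),
      pi = pi,
      Q = Q,
      label = design$label,
      mean_pi_hat = mean(pi_raw),
      bias = mean(pi_raw) - pi,
      empirical_var = stats::var(pi_raw),
      theoretical_var = v_theory,
      mean_var_hat = mean(var_hat),
      var_ratio = stats::var(pi_raw) / v_theory,
      var_hat_ratio = mean(var_hat) / v_theory,
      coverage = mean(pi_raw - half <= pi & pi <= pi_raw + half),
      level = level,
      seed = as.integer(seed),
      method = method
    ),
    class = "rr_mc"
  )
}

# yes-count of a full respondent walk given latent statuses (single stream)
walk_yes_count <- function(design, truth) {
  n <- length(truth)
  p <- design$sensitive
  j <- design$j
  answer <- logical(n)
  active <- rep(TRUE, n)
  for (g in seq_len(j)) {
    u <- stats::runif(sum(active))
    direct <- u < p[g]
    idx <- which(active)
    if (g < j) {
      stopped <- idx[direct]
      answer[stopped] <- truth[stopped]
      active[stopped] <- FALSE
    } else {
      answer[idx[direct]] <- truth[idx[direct]]
      answer[idx[!direct]] <- !truth[idx[!direct]]
    }
  }
  sum(answer)
}

#' @export
print.rr_mc <- function(x, ...) {
  cat(sprintf("<rr_mc> %s (Q = %.6g), pi = %g, n = %d, %d replicates (seed %d)\n",
              x$label, x$Q, x$pi, x$n, x$replicates, x$seed))
  cat(sprintf("  bias = %.3e, var ratio (emp/theory) = %.4f, E[Vhat]/V = %.4f\n",
              x$bias, x$var_ratio, x$var_hat_ratio))
  cat(sprintf("  %g%% Wald coverage = %.4f\n", 100 * x$level, x$coverage))
  invisible(x)
}

#' Tidy a Monte-Carlo report
#'
#' @param x An `rr_mc` object.
#' @param ... Unused.
#' @return One-row tibble of the summary statistics.
#' @method tidy rr_mc
#' @export
tidy.rr_mc <- function(x, ...) {
  tibble::tibble(
    label = x$label, Q = x$Q, pi = x$pi, n = x$n,
    replicates = x$replicates, seed = x$seed, method = x$method,
    mean_pi_hat = x$mean_pi_hat, bias = x$bias,
    empirical_var = x$empirical_var, theoretical_var = x$theoretical_var,
    mean_var_hat = x$mean_var_hat, var_ratio = x$var_ratio,
    var_hat_ratio = x$var_hat_ratio,
    coverage = x$coverage, level = x$level
  )
}

#' @rdname tidy.rr_mc
#' @method glance rr_mc
#' @export
glance.rr_mc <- function(x, ...) {
  tibble::tibble(bias = x$bias, var_ratio = x$var_ratio,
                 var_hat_ratio = x$var_hat_ratio, coverage = x$coverage)
}
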