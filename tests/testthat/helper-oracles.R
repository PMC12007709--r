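# Independent closed forms for the one-, two- and three-stage special cases,
# written directly from their published estimator/variance expressions (not
# via the package's Q-based route). Warner's design probability p1 = 1 - q1.

warner_pi_hat <- function(alpha_hat, p1) {
  (alpha_hat - (1 - p1)) / (2 * p1 - 1)
}

warner_var <- function(pi, n, p1) {
  pi * (1 - pi) / n + p1 * (1 - p1) / (n * (2 * p1 - 1)^2)
}

ms_pi_hat <- function(alpha_hat, p1, p2) {
  (alpha_hat - (1 - p2) * (1 - p1)) / (2 * p1 - 1 + 2 * p2 * (1 - p1))
}

ms_var <- function(pi, n, p1, p2) {
  w <- (1 - p2) * (1 - p1)
  pi * (1 - pi) / n + w * (1 - w) / (n * (2 * p1 - 1 + 2 * p2 * (1 - p1))^2)
}

ak_pi_hat <- function(alpha_hat, q1, q2, q3) {
  (alpha_hat - q1 * q2 * q3) / (1 - 2 * q1 * q2 * q3)
}

ak_var <- function(pi, n, q1, q2, q3) {
  Q <- q1 * q2 * q3
  (pi * (1 - pi) + Q * (1 - Q) / (1 - 2 * Q)^2) / n
}

# Warner privacy measure written from its own special-case expression
warner_privacy <- function(q1) (1 - 2 * q1)^2 / (2 * q1 * (1 - q1))

# random non-singular design for property loops
random_design <- function(j = sample(1:8, 1), avoid_singular = TRUE) {
  repeat {
    q <- runif(j, 0.02, 0.98)
    d <- rr_design(continue_probs = q)
    if (!avoid_singular || abs(d$Q - 0.5) > 1e-3) return(d)
  }
}
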