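test_that("variance component f(Q) has the right values, symmetry and monotonicity", {
  expect_equal(variance_component(0.1), 0.140625)
  expect_equal(variance_component(0), 0)
  expect_equal(variance_component(1), 0)
  expect_equal(variance_component(0.4), 6.0)
  expect_error(variance_component(0.5), class = "rrstage_error_singular")

  qs <- seq(0.01, 0.49, by = 0.01)
  expect_equal(variance_component(qs), variance_component(1 - qs), tolerance = 1e-9)
  expect_true(all(diff(variance_component(qs)) > 0))
  expect_true(all(diff(variance_component(1 - qs)) > 0)) # decreasing in Q on (0.5, 1)
})

test_that("pairwise comparison is the pi- and n-free variance difference", {
  a <- rr_design(continue_probs = c(0.6, 0.5, 0.5, 0.5), label = "four-stage")
  b <- warner_design(0.4)
  cmp <- compare_designs(a, b)
  expect_equal(cmp$diff, variance_component(0.4) - variance_component(0.075))
  expect_true(cmp$a_dominates)
  # diff equals n*(V_b - V_a) at any pi and n
  for (pi in c(0.1, 0.5, 0.9)) {
    expect_equal(cmp$diff,
                 1000 * (theoretical_variance(b, pi, 1000) -
                           theoretical_variance(a, pi, 1000)),
                 tolerance = 1e-9)
  }

  self <- compare_designs(a, a)
  expect_equal(self$diff, 0)
  expect_false(self$a_dominates)

  # mirrored products tie by symmetry of f
  m1 <- warner_design(0.3)
  m2 <- warner_design(0.7)
  expect_equal(compare_designs(m1, m2)$diff, 0, tolerance = 1e-12)

  expect_error(compare_designs(a, rr_design(sensitive = 0.5)),
               class = "rrstage_error_singular")
})

test_that("nested closed-form condition equals direct dominance", {
  d <- rr_design(continue_probs = c(0.1, 0.5, 0.5, 0.5))
  # literal inequality: trailing product vs (1 - Q_prefix)/(1 - Q_full)
  expect_equal(nested_condition(d, 3), 0.125 < (1 - 0.1) / (1 - 0.0125))
  expect_true(nested_condition(d, 3))

  # trailing continuation probabilities of 1 leave the design unchanged: no strict gain
  d_id <- rr_design(continue_probs = c(0.3, 1, 1))
  expect_false(nested_condition(d_id, 2))

  # four-stage vs three-stage prefix, literal published inequality
  q <- c(0.4, 0.5, 0.5, 0.5)
  d4 <- rr_design(continue_probs = q)
  lhs <- q[4]
  rhs <- (1 - prod(q[1:3])) / (1 - prod(q))
  expect_equal(nested_condition(d4, 1), lhs < rhs)

  expect_error(nested_condition(d, 4), class = "rrstage_error_index")
  expect_error(nested_condition(d, 0), class = "rrstage_error_index")

  # property: condition == f-comparison over random nested pairs, and
  # compare_designs() reports it on genuinely nested inputs
  set.seed(17)
  for (i in 1:500) {
    j <- sample(2:6, 1)
    repeat {
      q <- runif(j, 0.02, 0.98)
      g <- sample(j - 1, 1)
      Qf <- prod(q)
      Qp <- prod(q[seq_len(j - g)])
      if (abs(Qf - 0.5) > 1e-3 && abs(Qp - 0.5) > 1e-3) break
    }
    full <- rr_design(continue_probs = q)
    prefix <- rr_design(continue_probs = q[seq_len(j - g)])
    direct <- variance_component(Qp) - variance_component(Qf) > 0
    expect_identical(nested_condition(full, g), direct)
    cmp <- compare_designs(full, prefix)
    expect_identical(cmp$condition_holds, cmp$a_dominates)
  }
})

test_that("matched single-stage and leading-probability solves hit the known values", {
  d <- rr_design(continue_probs = c(0.8, 0.5, 0.5, 0.5)) # Q = 0.1
  expect_equal(matched_single_stage_q(d), 0.1, tolerance = 1e-9)
  expect_equal(matched_leading_q(d, 0.5), 0.2, tolerance = 1e-9)
  expect_equal(matched_leading_q(d, c(0.5, 0.5)), 0.4, tolerance = 1e-9)

  # fixed point for a single-stage input
  expect_equal(matched_single_stage_q(warner_design(0.3)), 0.3)
  # above-0.5 product maps to its mirror
  d9 <- rr_design(continue_probs = rep(0.9, 4))
  m <- matched_single_stage_q(d9)
  expect_equal(m, 1 - 0.9^4)
  expect_equal(variance_component(m), variance_component(d9$Q), tolerance = 1e-9)

  expect_error(matched_leading_q(d, 0.05), class = "rrstage_error_infeasible")
  expect_error(matched_single_stage_q(rr_design(sensitive = 1)),
               class = "rrstage_error_infeasible")
})

test_that("efficiency surfaces are positive on the practicable grid and flag singular points", {
  grid <- seq(0.1, 0.4, by = 0.1)
  for (fam in c("warner", "mangat_singh", "aboalkhair")) {
    surf <- efficiency_surface(grid, grid, grid, grid, baseline = fam)
    expect_equal(nrow(surf), length(grid)^4)
    expect_false(any(surf$singular))
    expect_true(all(surf$diff > 0))
  }

  # proposed vs itself: use prefix on a degenerate axis check instead
  surf0 <- efficiency_surface(0.2, 1, 1, 1, baseline = "warner")
  expect_equal(surf0$diff, 0)

  # diff increases as q4 decreases, other axes fixed (vs three-stage baseline)
  surf4 <- efficiency_surface(0.3, 0.3, 0.3, seq(0.9, 0.1, by = -0.1),
                              baseline = "aboalkhair")
  expect_true(all(diff(surf4$diff[order(-surf4$q4)]) > 0))

  # singular baseline point flagged, not dropped
  ssing <- efficiency_surface(0.5, 1, 0.2, 0.2, baseline = "warner")
  expect_equal(nrow(ssing), 1L)
  expect_true(ssing$singular)
  expect_true(is.na(ssing$diff))
})

test_that("variance curves keep the four-stage design below its nested baselines", {
  q1 <- setdiff(seq(0.05, 0.95, by = 0.05), 0.5)
  tab <- variance_curves(q1, c(0.5, 0.5, 0.5), pi = 0.3, n = 1000)
  ok <- !tab$singular
  # beats the two- and three-stage baselines regardless of q1 ...
  expect_true(all(tab$v_proposed[ok] < tab$v_mangat_singh[ok]))
  expect_true(all(tab$v_proposed[ok] < tab$v_aboalkhair[ok]))
  # ... and Warner exactly where the nested dominance condition holds
  for (q in q1[ok]) {
    d4 <- rr_design(continue_probs = c(q, 0.5, 0.5, 0.5))
    row <- tab[tab$q1 == q, ]
    expect_identical(row$v_proposed < row$v_warner, nested_condition(d4, 3))
  }

  # the four-stage device at q1 = 0.8 ties Warner at q1 = 0.1
  t8 <- variance_curves(0.8, c(0.5, 0.5, 0.5), pi = 0.3, n = 1000)
  w1 <- variance_curves(0.1, c(0.5, 0.5, 0.5), pi = 0.3, n = 1000)
  expect_equal(t8$v_proposed, w1$v_warner, tolerance = 1e-12)

  # 1/n scaling and additive separability in pi
  t_n <- variance_curves(0.2, c(0.5, 0.5, 0.5), pi = 0.3, n = 2000)
  expect_equal(t_n$v_proposed * 2,
               variance_curves(0.2, c(0.5, 0.5, 0.5), pi = 0.3, n = 1000)$v_proposed)
  t_p5 <- variance_curves(0.2, c(0.5, 0.5, 0.5), pi = 0.5, n = 1000)
  t_p3 <- variance_curves(0.2, c(0.5, 0.5, 0.5), pi = 0.3, n = 1000)
  for (col in c("v_proposed", "v_aboalkhair", "v_mangat_singh", "v_warner")) {
    expect_equal(t_p5[[col]] - t_p3[[col]], (0.25 - 0.21) / 1000, tolerance = 1e-12)
  }
})

test_that("surface and curve autoplot methods return ggplot objects", {
  surf <- efficiency_surface(0.2, 0.3, c(0.2, 0.4), c(0.2, 0.4))
  expect_s3_class(autoplot(surf), "ggplot")
  crv <- variance_curves(c(0.1, 0.2, 0.3))
  expect_s3_class(autoplot(crv), "ggplot")
})
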