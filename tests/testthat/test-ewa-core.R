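# Core learning equations: pay-offs, attraction updates, choice rules, links.

test_that("pay-off is zero on failure and inverse-log duration on success", {
  expect_identical(payoff_from_outcome(FALSE, 500), 0)
  expect_equal(payoff_from_outcome(TRUE, 95), 1 / log(95))
  # vectorized over bouts
  expect_equal(payoff_from_outcome(c(TRUE, FALSE), c(95, 95)),
               c(1 / log(95), 0))
  # strictly decreasing in duration across the plausible range
  d <- exp(seq(log(2), log(1e4), length.out = 200))
  p <- payoff_from_outcome(rep(TRUE, 200), d)
  expect_true(all(diff(p) < 0))
  # faster technique pays more (29 s vs 211 s medians)
  expect_gt(payoff_from_outcome(TRUE, 29), payoff_from_outcome(TRUE, 211))
  # clamp guards the log near zero duration
  expect_equal(payoff_from_outcome(TRUE, 0.5), 1 / log(2))
  expect_error(payoff_from_outcome(TRUE, -3), "positive duration")
})

test_that("attraction update is a convex combination toward the pay-off", {
  st <- ewa_state(c("a", "b"), c("t1", "t2"))
  # phi = 0 leaves the state unchanged
  st0 <- update_attractions(st, "a", "t1", payoff = 0.7, phi_j = 0)
  expect_equal(st0$A, st$A)
  # phi = 1 jumps straight to the pay-off
  st1 <- update_attractions(st, "a", "t1", payoff = 0.7, phi_j = 1)
  expect_equal(st1$A["a", "t1"], 0.7)
  # only the actor x chosen cell moves
  st2 <- update_attractions(st, "a", "t1", payoff = 0.5, phi_j = 0.3)
  expect_equal(st2$A["a", "t2"], 0)
  expect_equal(st2$A["b", "t1"], 0)
  expect_equal(st2$t, st$t + 1L)
  expect_error(update_attractions(st, "zz", "t1", 0.5, 0.3), "unknown actor")
  expect_error(update_attractions(st, "a", "zz", 0.5, 0.3), "unknown technique")
})

test_that("attraction recursion matches its closed form under constant pay-off", {
  # A_t = pi (1 - (1 - phi)^t) + (1 - phi)^t A_0
  pi_ <- 0.5; phi <- 0.15
  st <- ewa_state("a", "t1")
  for (i in 1:3) st <- update_attractions(st, "a", "t1", pi_, phi)
  expect_equal(st$A["a", "t1"], 0.5 * (1 - 0.85^3), tolerance = 1e-12)
  expect_equal(st$A["a", "t1"], 0.19294, tolerance = 1e-4)
  # general A0 and longer horizon, to 1e-12
  for (phi in c(0.05, 0.5, 0.9)) {
    A0 <- 0.31
    st <- ewa_state("a", "t1", A0 = matrix(A0, 1, 1))
    for (t in 1:100) {
      st <- update_attractions(st, "a", "t1", pi_, phi)
      closed <- pi_ * (1 - (1 - phi)^t) + (1 - phi)^t * A0
      expect_equal(st$A["a", "t1"], closed, tolerance = 1e-12)
    }
  }
})

test_that("soft-max choice has the stated limits and invariances", {
  st <- ewa_state("a", paste0("t", 1:7),
                  A0 = matrix(rnorm(7), 1, 7))
  # lambda = 0: uniform regardless of attractions
  expect_equal(unname(individual_choice_probs(st, "a", 0)), rep(1 / 7, 7),
               tolerance = 1e-15)
  # two-option closed form at the published sensitivity
  st2 <- ewa_state("a", c("t1", "t2"), A0 = matrix(c(0.2, 0.1), 1, 2))
  p <- individual_choice_probs(st2, "a", 20.97)
  expect_equal(unname(p["t1"]), stats::plogis(20.97 * 0.1), tolerance = 1e-12)
  expect_equal(unname(p["t1"]), 0.8905, tolerance = 1e-3)
  # translation invariance
  set.seed(7)
  for (i in 1:10) {
    A <- matrix(rnorm(5), 1, 5)
    sa <- ewa_state("a", paste0("t", 1:5), A0 = A)
    sb <- ewa_state("a", paste0("t", 1:5), A0 = A + 3.7)
    pa <- individual_choice_probs(sa, "a", 4.2)
    pb <- individual_choice_probs(sb, "a", 4.2)
    expect_equal(sum(pa), 1, tolerance = 1e-12)
    expect_true(all(pa >= 0 & pa <= 1))
    expect_lt(max(abs(pa - pb)), 1e-12)
  }
  # large lambda concentrates on the argmax
  st3 <- ewa_state("a", c("t1", "t2", "t3"), A0 = matrix(c(0.3, 0.1, 0.2), 1))
  expect_gt(individual_choice_probs(st3, "a", 500)["t1"], 0.999)
})

test_that("individual/social mixture is affine in gamma and handles absence", {
  p_ind <- c(0.6, 0.4); p_soc <- c(0.1, 0.9)
  expect_equal(combine_probs(p_ind, p_soc, 0), p_ind)
  expect_equal(combine_probs(p_ind, p_soc, 1), p_soc)
  expect_equal(combine_probs(p_ind, p_soc, 0.14), c(0.530, 0.470),
               tolerance = 1e-12)
  # no social information: individual probabilities pass through
  expect_equal(combine_probs(p_ind, NULL, 0.9), p_ind)
  # affine: midpoint of the two degenerate ends
  m <- (combine_probs(p_ind, p_soc, 0) + combine_probs(p_ind, p_soc, 1)) / 2
  expect_equal(combine_probs(p_ind, p_soc, 0.5), m, tolerance = 1e-15)
  expect_equal(sum(combine_probs(p_ind, p_soc, 0.37)), 1, tolerance = 1e-12)
  expect_error(combine_probs(p_ind, c(0.2, 0.3, 0.5), 0.5), "length")
})

test_that("logistic age link hits known values and is monotone", {
  expect_equal(link_learning_param(0, 0, 1.3), 0.5)
  # intercept chosen to invert to the published posterior median of phi
  expect_equal(link_learning_param(qlogis(0.15), 0, 0), 0.15, tolerance = 1e-12)
  ages <- seq(-2, 2, length.out = 9)
  out <- link_learning_param(-1.7346, -0.11, ages)
  expect_true(all(diff(out) < 0))
  expect_true(all(out > 0 & out < 1))
})
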