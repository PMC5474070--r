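# The agent-based forward simulator.

test_that("outcome sampler reproduces the configured success rate and median", {
  set.seed(1)
  prof <- tibble::tibble(name = "canine_seam", p_success = 0.885,
                         duration_med_s = 42, duration_sigma = 0.95)
  out <- sample_outcome(prof, n = 1e4)
  expect_equal(mean(out$success), 0.885, tolerance = 0.01)
  expect_equal(median(out$duration_s[out$success]), 42, tolerance = 0.05 * 42)
  expect_true(all(out$duration_s >= 2))
  # a never-successful technique always pays zero
  prof0 <- tibble::tibble(name = "pound", p_success = 0, duration_med_s = 60,
                          duration_sigma = 0.95)
  out0 <- sample_outcome(prof0, n = 500)
  expect_true(!any(out0$success))
  expect_true(all(payoff_from_outcome(out0$success, out0$duration_s) == 0))
})

test_that("simulation is byte-identical under a fixed seed", {
  a <- make_fixture("tiny")$bouts
  b <- make_fixture("tiny")$bouts
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- make_fixture("tiny", seed = 999)$bouts
  expect_false(identical(nrow(a), nrow(c)) && identical(a$technique, c$technique))
})

test_that("simulated bout tables satisfy the schema invariants", {
  fx <- make_fixture("table1-like")
  b <- fx$bouts
  r <- fx$config$roster
  expect_true(all(b$actor %in% r$id))
  expect_true(all(b$day >= 1))
  expect_false(any(mapply(function(a, aud) a %in% aud, b$actor, b$audience)))
  expect_true(all(lengths(b$audience) <= 3))
  expect_identical(order(b$day, b$seq), seq_len(nrow(b)))
  expect_true(all(b$duration_s[b$success] > 0))
  # field scale: ~1437 bouts over 75 days
  expect_gt(nrow(b), 1000)
  expect_lt(nrow(b), 2000)
})

test_that("random-choice limit gives uniform technique frequencies", {
  cfg <- sim_config(
    roster = make_roster(10),
    techniques = capuchin_techniques(),
    true_params = population_params(
      lambda = 0, gamma = 0, f = 1,
      beta = c(pay = 0, rank = 0, kin = 0, coho = 0, age = 0),
      mu_phi = 0, mu_gamma = 0,
      sigma = list(phi = 0.66, gamma = 0, f = 0, beta = rep(0, 5))
    ),
    n_days = 50, bouts_per_day = 100, seed = 99
  )
  b <- simulate_group(cfg)
  freq <- table(factor(b$technique, levels = capuchin_techniques()$name))
  n <- nrow(b)
  se <- sqrt((1 / 7) * (6 / 7) / n)
  expect_true(all(abs(freq / n - 1 / 7) < 3 * se))
})

test_that("with gamma = 0 choices are independent of other agents' histories", {
  # causal check: with the social channel off, the realized bout table is a
  # deterministic function of the seed and the individual-learning
  # parameters alone — wildly different social-cue parameters change nothing
  cfg1 <- make_fixture("individual-only", simulate = FALSE)$config
  cfg2 <- cfg1
  cfg2$true_params$beta <- c(pay = 5, rank = -5, kin = 5, coho = -5, age = 5)
  cfg2$true_params$log_f <- log(8)
  b1 <- simulate_group(cfg1)
  b2 <- simulate_group(cfg2)
  for (col in c("day", "seq", "actor", "technique", "success", "duration_s")) {
    expect_identical(b1[[col]], b2[[col]])
  }

  # statistical check: with choice also unconditioned on own attractions
  # (lambda = 0), realized choices are iid uniform, so they carry no
  # association with the actor's witnessed window majority
  cfg3 <- cfg1
  cfg3$true_params$lambda <- 0
  cfg3$seed <- 17
  b3 <- simulate_group(cfg3)
  dat <- prepare_ewa_data(b3, cfg3$roster, 14, cfg3$techniques$name)
  has_info <- rowSums(dat$N) > 0
  maj <- apply(dat$N[has_info, , drop = FALSE], 1, which.max)
  chosen <- dat$tech_idx[has_info]
  p <- suppressWarnings(chisq.test(table(chosen, maj))$p.value)
  expect_gt(p, 0.01)
})

test_that("conformity fixes a variant while anti-conformity preserves diversity", {
  late_max_freq <- function(f_val, seed) {
    cfg <- make_fixture("conformist", simulate = FALSE)$config
    cfg$true_params$log_f <- log(f_val)
    cfg$seed <- seed
    b <- simulate_group(cfg)
    late <- b[b$day > 70, ]
    max(table(late$technique)) / nrow(late)
  }
  conf <- vapply(1:5, function(s) late_max_freq(3, 600 + s), numeric(1))
  anti <- vapply(1:5, function(s) late_max_freq(0.38, 600 + s), numeric(1))
  expect_gte(sum(conf > 0.9), 3)   # fixation in most replicates
  expect_gte(sum(anti < 0.9), 3)   # polymorphism maintained in most
})

test_that("mean simulated pay-off converges to p_success x E[1/log T]", {
  set.seed(5)
  prof <- tibble::tibble(name = "x", p_success = 0.7, duration_med_s = 60,
                         duration_sigma = 0.8)
  out <- sample_outcome(prof, n = 4e4)
  mc <- mean(payoff_from_outcome(out$success, out$duration_s))
  integrand <- function(t) {
    (1 / log(pmax(t, 2))) * stats::dlnorm(t, log(60), 0.8)
  }
  expected <- 0.7 * stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
  expect_equal(mc, expected, tolerance = 0.02 * expected)
})

test_that("fixtures honour their contracts and unknown names fail loudly", {
  tiny <- make_fixture("tiny")
  expect_equal(nrow(tiny$config$roster), 4)
  expect_equal(nrow(tiny$config$techniques), 2)
  expect_lt(nrow(tiny$bouts), 200)

  io <- make_fixture("individual-only", simulate = FALSE)
  expect_false(is.finite(io$config$true_params$a_gam))   # gamma exactly 0
  expect_true(all(io$config$true_params$beta == 0))

  pb <- make_fixture("payoff-biased", simulate = FALSE)
  expect_gt(pb$config$true_params$beta[["pay"]], 0)
  expect_equal(exp(pb$config$true_params$log_f), 1)

  expect_error(make_fixture("nope"), "tiny")
})

test_that("an experienced innovator with pay-off-biased copying seeds diffusion", {
  # one knowledgeable agent starts with high attraction for the fastest,
  # most successful technique; strong pay-off bias spreads it
  runs <- vapply(1:5, function(s) {
    techs <- dplyr::filter(
      capuchin_techniques(), name %in% c("canine_seam", "bite_and_pop",
                                         "chew_hole", "pound"))
    A0 <- matrix(0, 12, 4)
    A0[1, match("canine_seam", techs$name)] <- 0.3
    cfg <- sim_config(
      roster = make_roster(12), techniques = techs,
      true_params = population_params(
        gamma = 0.4, f = 1,
        beta = c(pay = 4, rank = 0, kin = 0, coho = 0, age = 0),
        mu_phi = 0, mu_gamma = 0,
        sigma = list(phi = 0.66, gamma = 0.3, f = 0, beta = rep(0, 5))
      ),
      n_days = 75, bouts_per_day = 19, seed = 700 + s,
      initial_attractions = A0
    )
    b <- simulate_group(cfg)
    f1 <- mean(b$technique[b$day <= 5] == "canine_seam")
    f75 <- mean(b$technique[b$day > 70] == "canine_seam")
    f75 > f1
  }, logical(1))
  expect_gte(sum(runs), 4)
})

test_that("per-age availability masks keep juveniles off masked techniques", {
  techs <- tibble::tibble(name = c("easy", "hard"), p_success = 0.7,
                          duration_med_s = 80, duration_sigma = 0.9)
  r <- make_roster(6)
  avail <- matrix(TRUE, 6, 2)
  avail[r$age_years < 10, 2] <- FALSE
  cfg <- sim_config(r, techs, population_params(f = 1), n_days = 20,
                    bouts_per_day = 10, seed = 3, availability = avail)
  b <- simulate_group(cfg)
  juv <- r$id[r$age_years < 10]
  expect_false(any(b$technique[b$actor %in% juv] == "hard"))
})
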