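# Agent-based forward simulator of the field experiment: the generative
# process the statistical model assumes, with known learning parameters, for
# parameter-recovery and model-comparison studies.

#' Population-level learning parameters
#'
#' Means, age slopes and between-individual SDs of the learning parameters,
#' on the scales the hierarchical model uses: phi and gamma vary on the
#' log-odds scale, f on the log scale, the cue influences beta on the
#' identity scale; the soft-max sensitivity lambda is shared by everyone.
#' Defaults are the posterior medians from the capuchin panama experiment
#' (lambda 20.97, phi 0.15, gamma 0.14, f 0.38, beta_pay 1.02, ...); age
#' slopes are per standardized-age unit (the published per-year slopes of
#' about -0.11 and -0.10 scaled by a typical group age SD of ~7 years).
#'
#' @param lambda global soft-max sensitivity (>= 0).
#' @param phi population-median updating rate in (0, 1); 0 < phi < 1.
#' @param gamma population-median social-information weight in \[0, 1);
#'   `gamma = 0` turns social learning off exactly.
#' @param f population-median frequency-dependence exponent (> 0).
#' @param beta named cue-influence means, order `pay, rank, kin, coho, age`.
#' @param mu_phi,mu_gamma age slopes on the log-odds scale per standardized
#'   age.
#' @param sigma list of between-individual SDs: `phi`, `gamma` (log-odds
#'   scale), `f` (log scale), `beta` (identity scale, length 5).
#' @return a `population_params` object.
#' @export
population_params <- function(lambda = 20.97,
                              phi = 0.15,
                              gamma = 0.14,
                              f = 0.38,
                              beta = c(pay = 1.02, rank = -0.11, kin = 0.19,
                                       coho = 0.48, age = 0.69),
                              mu_phi = -0.75,
                              mu_gamma = -0.70,
                              sigma = list(phi = 0.66, gamma = 0.69, f = 1.29,
                                           beta = c(pay = 0.28, rank = 0.26,
                                                    kin = 0.25, coho = 0.26,
                                                    age = 0.25))) {
  stopifnot(lambda >= 0, phi > 0, phi < 1, gamma >= 0, gamma < 1, f > 0)
  beta <- beta[CUE_NAMES]
  if (any(is.na(beta))) stop("beta must be named with ", paste(CUE_NAMES, collapse = ", "),
                             call. = FALSE)
  sb <- sigma$beta
  sigma$beta <- if (!is.null(names(sb)) && all(CUE_NAMES %in% names(sb))) {
    unname(sb[CUE_NAMES])
  } else {
    rep_len(unname(sb), 5)
  }
  stopifnot(sigma$phi >= 0, sigma$gamma >= 0, sigma$f >= 0, all(sigma$beta >= 0))
  structure(
    list(lambda = lambda,
         a_phi = stats::qlogis(phi),
         a_gam = if (gamma == 0) -Inf else stats::qlogis(gamma),
         log_f = log(f),
         beta = beta,
         mu_phi = mu_phi,
         mu_gamma = mu_gamma,
         sigma = sigma),
    class = "population_params"
  )
}

#' Deterministic roster for simulated groups
#'
#' Ages are evenly spread over 1-24 years (a realistic capuchin group age
#' span), matrilines cycle over four maternal kin groups, and the oldest
#' individual is the alpha.
#'
#' @param n group size.
#' @return roster tibble with `id`, `age_years`, `matriline`, `alpha`.
#' @export
make_roster <- function(n) {
  stopifnot(n >= 2)
  ages <- round(seq(1, 24, length.out = n), 1)
  tibble::tibble(
    id = sprintf("ID%02d", seq_len(n)),
    age_years = ages,
    matriline = rep_len(paste0("M", 1:4), n),
    alpha = seq_len(n) == which.max(ages)
  )
}

#' Simulation configuration
#'
#' @param roster individual table (`id`, `age_years`, `matriline`, `alpha`).
#' @param techniques technique-profile table (see [technique_profiles()]).
#' @param true_params a [population_params()] object.
#' @param n_days number of experimental days (field experiment: 75).
#' @param bouts_per_day mean bouts per day; per-day counts are Poisson. The
#'   default 19 reproduces the field scale of ~1437 bouts over 75 days.
#' @param audience_probs probabilities of 0-3 observers per bout (1-4
#'   individuals could forage at a platform at once).
#' @param window_days social-information window width in days.
#' @param seed integer seed; a fixed seed makes [simulate_group()] output
#'   byte-identical.
#' @param initial_attractions `NULL` (all naive, A = 0) or a matrix
#'   (individual x technique) seeding experienced individuals.
#' @param availability optional logical matrix (individual x technique);
#'   `FALSE` entries mark techniques an individual cannot perform (e.g. a
#'   jaw-strength constraint on juveniles). Off (`NULL`) by default.
#' @return an `ewa_sim_config` object.
#' @export
sim_config <- function(roster, techniques, true_params = population_params(),
                       n_days = 75, bouts_per_day = 19,
                       audience_probs = c(0.25, 0.25, 0.25, 0.25),
                       window_days = 14, seed = NULL,
                       initial_attractions = NULL, availability = NULL) {
  roster <- validate_roster(roster)
  techniques <- technique_profiles(techniques)
  stopifnot(inherits(true_params, "population_params"),
            n_days >= 1, bouts_per_day > 0, window_days >= 1,
            length(audience_probs) == 4, all(audience_probs >= 0),
            sum(audience_probs) > 0)
  J <- nrow(roster); K <- nrow(techniques)
  if (!is.null(initial_attractions)) {
    stopifnot(is.matrix(initial_attractions),
              nrow(initial_attractions) == J, ncol(initial_attractions) == K,
              all(is.finite(initial_attractions)))
  }
  if (!is.null(availability)) {
    stopifnot(is.matrix(availability), nrow(availability) == J,
              ncol(availability) == K, all(rowSums(availability) > 0))
  }
  structure(
    list(roster = roster, techniques = techniques, true_params = true_params,
         n_days = as.integer(n_days), bouts_per_day = bouts_per_day,
         audience_probs = audience_probs / sum(audience_probs),
         window_days = as.integer(window_days), seed = seed,
         initial_attractions = initial_attractions,
         availability = availability),
    class = "ewa_sim_config"
  )
}

#' Draw per-individual learning parameters from the population model
#'
#' Non-centered draws: phi_j and gamma_j are logistic transforms of
#' intercept + age slope x standardized age + sigma x standard-normal
#' deviate; f_j is log-normal around the population median; beta_jk normal.
#'
#' @param pop a [population_params()] object.
#' @param roster validated roster.
#' @return tibble: one row per individual with `id`, `phi`, `gam`, `f`, and
#'   the five `beta_*` columns.
#' @export
draw_learner_params <- function(pop, roster) {
  roster <- validate_roster(roster)
  J <- nrow(roster)
  s <- pop$sigma
  phi <- logistic(pop$a_phi + pop$mu_phi * roster$age_std +
                    s$phi * stats::rnorm(J))
  gam <- logistic(pop$a_gam + pop$mu_gamma * roster$age_std +
                    s$gamma * stats::rnorm(J))
  if (!is.finite(pop$a_gam)) gam <- rep(0, J)
  f <- exp(pop$log_f + s$f * stats::rnorm(J))
  beta <- matrix(rep(pop$beta, each = J), J, 5,
                 dimnames = list(roster$id, CUE_NAMES)) +
    matrix(stats::rnorm(J * 5), J, 5) %*% diag(s$beta)
  tibble::tibble(
    id = roster$id, phi = phi, gam = gam, f = f,
    beta_pay = beta[, 1], beta_rank = beta[, 2], beta_kin = beta[, 3],
    beta_coho = beta[, 4], beta_age = beta[, 5]
  )
}

#' Sample the outcome of one processing attempt
#'
#' Success is Bernoulli with the technique's success probability; opening
#' time is log-normal with the technique's median and log-scale SD. Failed
#' attempts still take time (handling before giving up), drawn from the same
#' log-normal scaled by 1.5. Durations are clamped below at 2 s.
#'
#' @param profile one row of a technique-profile table.
#' @param n number of attempts to draw.
#' @return tibble with logical `success` and numeric `duration_s`.
#' @export
sample_outcome <- function(profile, n = 1) {
  success <- stats::runif(n) < profile$p_success
  dur <- stats::rlnorm(n, meanlog = log(profile$duration_med_s),
                       sdlog = profile$duration_sigma)
  dur[!success] <- dur[!success] * 1.5
  tibble::tibble(success = success, duration_s = pmax(dur, 2))
}

#' Forward-simulate the group experiment
#'
#' Replays the hypothesized data-generating process: each bout an actor is
#' drawn, its social-information window (the bouts it witnessed in the
#' previous `window_days` days plus earlier the same day) is tallied, a
#' technique is sampled from the individual/social probability mixture, an
#' outcome is sampled from the technique profile, and the actor's attraction
#' to the chosen technique is updated with the realized pay-off. Audiences
#' of 0-3 observers are drawn per bout. Deterministic under a fixed seed.
#'
#' @param config an [sim_config()] object.
#' @return bout tibble (`day`, `seq`, `actor`, `technique`, `success`,
#'   `duration_s`, list-column `audience`) with attributes
#'   `learner_params` (the realized per-individual parameters) and `config`.
#' @export
simulate_group <- function(config) {
  stopifnot(inherits(config, "ewa_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  roster <- config$roster
  tech <- config$techniques
  J <- nrow(roster); K <- nrow(tech)
  ids <- roster$id
  pair <- pair_cues(roster)
  lp <- draw_learner_params(config$true_params, roster)
  beta_mat <- as.matrix(lp[, paste0("beta_", CUE_NAMES)])
  lambda <- config$true_params$lambda
  W <- config$window_days

  counts <- stats::rpois(config$n_days, config$bouts_per_day)
  n <- sum(counts)
  day <- rep(seq_len(config$n_days), counts)
  seqs <- unlist(lapply(counts, seq_len), use.names = FALSE)
  if (n == 0) {
    out <- tibble::tibble(day = integer(0), seq = integer(0),
                          actor = character(0), technique = character(0),
                          success = logical(0), duration_s = numeric(0),
                          audience = list())
    attr(out, "learner_params") <- lp
    attr(out, "config") <- config
    return(out)
  }

  A <- config$initial_attractions %||% matrix(0, J, K)
  actor_idx <- integer(n); tech_idx <- integer(n)
  success <- logical(n); duration <- numeric(n); pay <- numeric(n)
  audM <- matrix(FALSE, n, J)
  audience <- vector("list", n)

  # first row of history still inside the window for each bout
  lo <- findInterval(day - W - 1L, day) + 1L

  for (t in seq_len(n)) {
    j <- sample.int(J, 1)
    n_aud <- sample.int(4, 1, prob = config$audience_probs) - 1L
    n_aud <- min(n_aud, J - 1L)
    aud <- if (n_aud > 0) sort(sample(setdiff(seq_len(J), j), n_aud)) else integer(0)

    p_ind <- softmax(lambda * A[j, ])
    p <- p_ind
    if (lp$gam[j] > 0 && t > 1 && lo[t] <= t - 1) {
      rs <- lo[t]:(t - 1L)
      rs <- rs[audM[rs, j]]
      if (length(rs) > 0) {
        sm <- tally_from_rows(rs, j, actor_idx, tech_idx, pay, pair, K)
        p_soc <- social_choice_probs(sm, f_j = lp$f[j], beta_j = beta_mat[j, ])
        p <- combine_probs(p_ind, p_soc, lp$gam[j])
      }
    }
    if (!is.null(config$availability)) {
      p <- p * config$availability[j, ]
      p <- if (sum(p) > 0) p / sum(p) else config$availability[j, ] / sum(config$availability[j, ])
    }
    i <- sample.int(K, 1, prob = p)
    out <- sample_outcome(tech[i, ], 1)

    actor_idx[t] <- j; tech_idx[t] <- i
    success[t] <- out$success; duration[t] <- out$duration_s
    pay[t] <- payoff_from_outcome(out$success, out$duration_s)
    audM[t, aud] <- TRUE
    audience[[t]] <- ids[aud]
    A[j, i] <- (1 - lp$phi[j]) * A[j, i] + lp$phi[j] * pay[t]
  }

  out <- tibble::tibble(
    day = day, seq = seqs, actor = ids[actor_idx],
    technique = tech$name[tech_idx], success = success,
    duration_s = duration, audience = audience
  )
  attr(out, "learner_params") <- lp
  attr(out, "config") <- config
  out
}

#' Canonical simulation fixtures
#'
#' Small, deterministic scenarios with known generating parameters, reused
#' across tests and examples:
#' * `tiny`: 4 individuals, 2 techniques, 10 days (< 200 bouts);
#' * `table1-like`: the full field scale — 25 individuals, the seven
#'   published technique profiles, 75 days, ~19 bouts/day;
#' * `conformist`: strong positive frequency dependence (f = 3, all beta 0,
#'   gamma 0.4, lambda 5) over two equal-pay-off techniques;
#' * `payoff-biased`: pure pay-off bias (beta_pay = 2, f = 1) over four
#'   techniques spanning the observed pay-off range;
#' * `individual-only`: gamma = 0, no social learning.
#'
#' @param name fixture name (hyphens and underscores interchangeable).
#' @param seed overrides the fixture's fixed default seed (used for
#'   replicate runs).
#' @param simulate if `FALSE`, return only the config without running the
#'   simulator.
#' @return list with elements `config` and (unless `simulate = FALSE`)
#'   `bouts`.
#' @export
make_fixture <- function(name, seed = NULL, simulate = TRUE) {
  key <- gsub("-", "_", tolower(name))
  fixtures <- c("tiny", "table1_like", "conformist", "payoff_biased",
                "individual_only")
  if (!key %in% fixtures) {
    stop("unknown fixture '", name, "'; valid fixtures: ",
         paste(gsub("_", "-", fixtures), collapse = ", "), call. = FALSE)
  }
  cfg <- switch(key,
    tiny = sim_config(
      roster = make_roster(4),
      techniques = tibble::tibble(name = c("fast", "slow"),
                                  p_success = c(0.8, 0.5),
                                  duration_med_s = c(40, 150),
                                  duration_sigma = 0.95),
      true_params = population_params(f = 1),
      n_days = 10, bouts_per_day = 8, seed = seed %||% 101
    ),
    table1_like = sim_config(
      roster = make_roster(25),
      techniques = capuchin_techniques(),
      true_params = population_params(),
      n_days = 75, bouts_per_day = 19, seed = seed %||% 2017
    ),
    conformist = sim_config(
      roster = make_roster(10),
      techniques = tibble::tibble(name = c("tech_a", "tech_b"),
                                  p_success = 0.65,
                                  duration_med_s = 100,
                                  duration_sigma = 0.95),
      # strong-conformity regime: near-obligate social learners. With
      # individual learning holding (1 - gamma) of the choice mass, the
      # long-run ceiling on the majority's frequency is about
      # 0.5 + gamma / 2 once both attractions equalize, so conformist
      # fixation requires a high social weight.
      true_params = population_params(
        gamma = 0.85, f = 3,
        beta = c(pay = 0, rank = 0, kin = 0, coho = 0, age = 0),
        mu_phi = 0, mu_gamma = 0,
        sigma = list(phi = 0.66, gamma = 0.3, f = 0,
                     beta = rep(0, 5))
      ),
      n_days = 75, bouts_per_day = 12, seed = seed %||% 303
    ),
    # strong pay-off-bias regime: substantial social weight so that the
    # pay-off cue actually steers choice (a regime fixture, like
    # `conformist`, not the field-posterior parameter set)
    payoff_biased = sim_config(
      roster = make_roster(12),
      techniques = payoff_contrast_techniques(),
      true_params = population_params(
        gamma = 0.4, f = 1,
        beta = c(pay = 2, rank = 0, kin = 0, coho = 0, age = 0),
        mu_phi = 0, mu_gamma = 0,
        sigma = list(phi = 0.66, gamma = 0.3, f = 0, beta = rep(0, 5))
      ),
      n_days = 75, bouts_per_day = 27, seed = seed %||% 404
    ),
    # Equal-pay-off techniques: with gamma = 0 each agent locks onto an
    # idiosyncratic technique, so other agents' histories carry no signal
    # about a focal agent's choices. (With strongly unequal pay-offs all
    # agents converge on the best technique independently and the social
    # window becomes a proxy for individual attractions — the equifinality
    # confound — which would make the no-social-learning regime
    # indistinguishable from social copying.)
    individual_only = sim_config(
      roster = make_roster(10),
      techniques = tibble::tibble(name = c("tech_a", "tech_b", "tech_c"),
                                  p_success = 0.65,
                                  duration_med_s = 100,
                                  duration_sigma = 0.95),
      true_params = population_params(
        gamma = 0, f = 1,
        beta = c(pay = 0, rank = 0, kin = 0, coho = 0, age = 0),
        mu_phi = 0, mu_gamma = 0,
        sigma = list(phi = 0.66, gamma = 0, f = 0, beta = rep(0, 5))
      ),
      n_days = 30, bouts_per_day = 20, seed = seed %||% 505
    )
  )
  if (!simulate) return(list(config = cfg))
  list(config = cfg, bouts = simulate_group(cfg))
}

# Four techniques spanning the observed pay-off range: high success/fast,
# low success/fast, moderate success/slow, never successful.
payoff_contrast_techniques <- function() {
  dplyr::filter(capuchin_techniques(),
                .data$name %in% c("canine_seam", "bite_and_pop",
                                  "chew_hole", "pound"))
}
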