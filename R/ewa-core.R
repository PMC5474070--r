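# Core experience-weighted attraction (EWA) learning equations.
#
# An EWA model has two parts: attraction scores A[j, i] that accumulate each
# individual j's experienced pay-offs with each technique i, and a choice rule
# mapping attractions (and, separately, social cues) to the probability of
# each technique on the next attempt.

#' Pay-off of a single processing attempt
#'
#' A failed attempt earns pay-off 0. A successful attempt earns the inverse
#' log of the opening time, `1 / log(duration_s)`: pay-offs decline as
#' handling time grows, with the steepest declines at short durations.
#' Durations are clamped below at 2 s so the log is strictly positive;
#' observed handling times are tens to hundreds of seconds, so the clamp only
#' guards degenerate synthetic input.
#'
#' @param success logical vector; was the fruit opened?
#' @param duration_s numeric vector of handling times in seconds. Must be
#'   positive wherever `success` is `TRUE`.
#' @return numeric vector of non-negative pay-offs.
#' @examples
#' payoff_from_outcome(c(TRUE, FALSE), c(95, 95)) # 1/log(95), 0
#' @export
payoff_from_outcome <- function(success, duration_s) {
  success <- as.logical(success)
  n <- max(length(success), length(duration_s))
  success <- rep_len(success, n)
  duration_s <- rep_len(as.numeric(duration_s), n)
  if (any(success & !(duration_s > 0))) {
    stop("successful attempts require a positive duration", call. = FALSE)
  }
  out <- numeric(n)
  ok <- success
  out[ok] <- 1 / log(pmax(duration_s[ok], 2))
  out
}

#' Create an attraction-score state
#'
#' @param ids character vector of individual ids.
#' @param techniques character vector of technique labels (unique, non-empty).
#' @param A0 initial attractions: a single number (default 0, naive), or a
#'   matrix `length(ids)` x `length(techniques)` (rows may be named by id) to
#'   seed experienced individuals.
#' @return an `ewa_state`: list with matrix `A` (individual x technique,
#'   dimnames set) and decision counter `t`.
#' @export
ewa_state <- function(ids, techniques, A0 = 0) {
  ids <- as.character(ids)
  techniques <- as.character(techniques)
  stopifnot(length(ids) > 0, length(techniques) > 0)
  if (anyDuplicated(techniques)) stop("technique labels must be unique", call. = FALSE)
  if (is.matrix(A0)) {
    stopifnot(nrow(A0) == length(ids), ncol(A0) == length(techniques))
    A <- A0
  } else {
    A <- matrix(as.numeric(A0), length(ids), length(techniques))
  }
  if (any(!is.finite(A))) stop("attractions must be finite", call. = FALSE)
  dimnames(A) <- list(ids, techniques)
  structure(list(A = A, t = 0L), class = "ewa_state")
}

#' Update attractions after one observed pay-off
#'
#' The actor's attraction to the chosen technique moves by the updating rate
#' `phi_j` toward the realized pay-off:
#' `A <- (1 - phi_j) * A + phi_j * payoff`. `phi_j` controls the importance
#' of recent pay-offs relative to accumulated experience. Attractions for
#' unchosen techniques, and for all other individuals, are unchanged.
#'
#' @param state an [ewa_state()].
#' @param actor individual id.
#' @param chosen technique label.
#' @param payoff realized pay-off (see [payoff_from_outcome()]).
#' @param phi_j updating rate in (0, 1); the closed form under constant
#'   pay-off is `A_t = payoff * (1 - (1 - phi)^t) + (1 - phi)^t * A_0`.
#' @return the updated `ewa_state` with `t` incremented.
#' @export
update_attractions <- function(state, actor, chosen, payoff, phi_j) {
  stopifnot(inherits(state, "ewa_state"))
  if (!actor %in% rownames(state$A)) stop("unknown actor: ", actor, call. = FALSE)
  if (!chosen %in% colnames(state$A)) stop("unknown technique: ", chosen, call. = FALSE)
  if (!(phi_j >= 0 && phi_j <= 1)) stop("phi_j must lie in [0, 1]", call. = FALSE)
  state$A[actor, chosen] <- (1 - phi_j) * state$A[actor, chosen] + phi_j * payoff
  state$t <- state$t + 1L
  state
}

#' Individual-learning choice probabilities (soft-max)
#'
#' Multinomial-logistic choice over techniques:
#' `P(i) = exp(lam * A[j, i]) / sum_k exp(lam * A[j, k])`. When `lam = 0`
#' choice is uniform; as `lam` grows the technique with the largest
#' attraction is chosen almost always. Invariant to adding a constant to all
#' of the actor's attractions.
#'
#' @param state an [ewa_state()].
#' @param actor individual id.
#' @param lam soft-max sensitivity, `lam >= 0`.
#' @return named probability vector over techniques.
#' @export
individual_choice_probs <- function(state, actor, lam) {
  stopifnot(inherits(state, "ewa_state"), lam >= 0)
  if (!actor %in% rownames(state$A)) stop("unknown actor: ", actor, call. = FALSE)
  softmax(lam * state$A[actor, ])
}

#' Mix individual and social choice probabilities
#'
#' Realized choice probability is `(1 - gam_j) * p_ind + gam_j * p_soc`,
#' where `gam_j` in (0, 1) is the weight on social cues. When no social
#' information exists for the decision (`p_soc = NULL`), the individual
#' component is returned unchanged: social cues cannot influence a decision
#' that had none available.
#'
#' @param p_ind probability vector from [individual_choice_probs()].
#' @param p_soc probability vector from [social_choice_probs()], or `NULL`.
#' @param gam_j social-information weight in \[0, 1\].
#' @return probability vector summing to 1.
#' @export
combine_probs <- function(p_ind, p_soc, gam_j) {
  if (!(gam_j >= 0 && gam_j <= 1)) stop("gam_j must lie in [0, 1]", call. = FALSE)
  if (is.null(p_soc)) return(p_ind)
  if (length(p_ind) != length(p_soc)) {
    stop("individual and social probability vectors differ in length", call. = FALSE)
  }
  (1 - gam_j) * p_ind + gam_j * p_soc
}

#' Logistic link from age to a learning parameter
#'
#' Per-individual learning parameters such as the updating rate phi and the
#' social weight gamma are logistic transforms of a linear predictor:
#' `logistic(alpha_j + mu * age_std)`, with a varying intercept `alpha_j`
#' per individual and a population-level age slope `mu` on the log-odds
#' scale. Ages are standardized (see [standardize_age()]).
#'
#' @param alpha_j intercept(s) on the log-odds scale.
#' @param mu age slope on the log-odds scale.
#' @param age_std standardized age(s).
#' @return value(s) in (0, 1), strictly monotone in age with the sign of `mu`.
#' @export
link_learning_param <- function(alpha_j, mu, age_std) {
  stopifnot(all(is.finite(mu)), all(is.finite(age_std)))
  logistic(alpha_j + mu * age_std)
}
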