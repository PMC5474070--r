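# Naive per-bout replay of the learning model, written independently of the
# package's vectorized/compiled likelihood path. It composes the exported
# single-step primitives (ewa_state, tally_window, social_choice_probs,
# individual_choice_probs, combine_probs, update_attractions) one bout at a
# time, exactly as the model is defined.
naive_loglik <- function(bouts, roster, params, techniques, window_days = 14,
                         A0 = NULL) {
  J <- nrow(roster)
  rep_j <- function(x) if (length(x) == 1) rep(x, J) else x
  phi <- rep_j(params$phi)
  gam <- rep_j(params$gam %||% 0)
  f <- rep_j(params$f %||% 1)
  beta <- params$beta %||% rep(0, 5)
  if (is.null(dim(beta))) beta <- matrix(rep(as.numeric(beta), each = J), J, 5)
  state <- ewa_state(roster$id, techniques,
                     A0 = if (is.null(A0)) 0 else A0)
  n <- nrow(bouts)
  pointwise <- numeric(n)
  for (t in seq_len(n)) {
    actor <- bouts$actor[t]
    j <- match(actor, roster$id)
    p_ind <- individual_choice_probs(state, actor, params$lambda)
    p_soc <- NULL
    if (gam[j] > 0) {
      # restrict to past bouts that could possibly fall in the window
      # (pure day arithmetic; tally_window re-applies the full rule)
      past <- bouts[seq_len(t - 1), , drop = FALSE]
      past <- past[past$day >= bouts$day[t] - window_days, , drop = FALSE]
      sm <- tally_window(past, roster,
                         observer = actor, now_day = bouts$day[t],
                         window_days = window_days,
                         now_seq = bouts$seq[t], techniques = techniques)
      p_soc <- social_choice_probs(sm, f_j = f[j], beta_j = beta[j, ])
    }
    p <- combine_probs(p_ind, p_soc, gam[j])
    pointwise[t] <- log(p[[bouts$technique[t]]])
    pay <- payoff_from_outcome(bouts$success[t], bouts$duration_s[t])
    state <- update_attractions(state, actor, bouts$technique[t], pay, phi[j])
  }
  list(total = sum(pointwise), pointwise = pointwise)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
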