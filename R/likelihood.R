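# Likelihood of a bout table under the EWA learning model.
#
# The window counts N and mean cue values kappa for each decision depend only
# on the data and the window width, never on model parameters, so they are
# precomputed once per dataset; the parameter-dependent replay (attraction
# dynamics, soft-max, social mixture) runs in compiled code.

# Pairwise cue ingredients from a validated roster: kinship and
# age-similarity matrices (demonstrator x observer), alpha flags and
# standardized ages.
pair_cues <- function(roster) {
  J <- nrow(roster)
  kin <- outer(roster$matriline, roster$matriline, "==") * 1
  coho <- 1 / (1 + abs(outer(roster$age_years, roster$age_years, "-")))
  list(kin = kin, coho = coho, alpha = as.numeric(roster$alpha),
       age_std = roster$age_std)
}

# Tally candidate history rows rs (already inside the window and witnessed
# by observer o) into per-technique counts and mean cue values.
tally_from_rows <- function(rs, o, actor_idx, tech_idx, payoff, pair, K) {
  N <- tabulate(tech_idx[rs], K)
  kap <- matrix(0, K, 5, dimnames = list(NULL, CUE_NAMES))
  if (length(rs) > 0) {
    a <- actor_idx[rs]
    oo <- rep.int(o, length(rs))
    cues <- cbind(payoff[rs], pair$alpha[a], pair$kin[cbind(a, oo)],
                  pair$coho[cbind(a, oo)], pair$age_std[a])
    sums <- rowsum(cues, group = tech_idx[rs])
    idx <- as.integer(rownames(sums))
    kap[idx, ] <- sums / N[idx]
  }
  list(N = N, kappa = kap)
}

#' Precompute the parameter-free ingredients of the likelihood
#'
#' Indexes actors and techniques, computes realized pay-offs, and tallies
#' each bout's social-information window for its actor: observation counts
#' `N` and mean cue values `kappa` over the witnessed bouts of the previous
#' `window_days` days (plus earlier bouts the same day).
#'
#' @param bouts bout table sorted by `(day, seq)`.
#' @param roster individual table.
#' @param window_days moving-window width in days.
#' @param techniques technique labels fixing column order; default: sorted
#'   unique techniques in `bouts`.
#' @return an `ewa_data` list used by [ewa_loglik()] and [fit_ewa()].
#' @export
prepare_ewa_data <- function(bouts, roster, window_days = 14,
                             techniques = NULL) {
  roster <- validate_roster(roster)
  bouts <- validate_bouts(bouts, roster)
  assert_sorted_bouts(bouts)
  techniques <- techniques %||% sort(unique(bouts$technique))
  K <- length(techniques)
  J <- nrow(roster)
  n <- nrow(bouts)
  actor_idx <- match(bouts$actor, roster$id)
  tech_idx <- match(bouts$technique, techniques)
  if (anyNA(tech_idx)) {
    stop("bout technique(s) outside the supplied technique set", call. = FALSE)
  }
  payoff <- payoff_from_outcome(bouts$success, bouts$duration_s)
  pair <- pair_cues(roster)

  audM <- matrix(FALSE, max(n, 1), J)
  for (r in seq_len(n)) {
    aud <- match(bouts$audience[[r]], roster$id)
    audM[r, aud] <- TRUE
  }

  N <- matrix(0, max(n, 1), K)
  kappa <- array(0, dim = c(max(n, 1), K, 5))
  if (n > 0) {
    lo <- findInterval(bouts$day - window_days - 1L, bouts$day) + 1L
    for (t in seq_len(n)) {
      if (lo[t] > t - 1) next
      rs <- lo[t]:(t - 1L)
      rs <- rs[audM[rs, actor_idx[t]]]
      if (length(rs) == 0) next
      sm <- tally_from_rows(rs, actor_idx[t], actor_idx, tech_idx, payoff,
                            pair, K)
      N[t, ] <- sm$N
      kappa[t, , ] <- sm$kappa
    }
  }
  structure(
    list(n = n, J = J, K = K, techniques = techniques, roster = roster,
         actor_idx = actor_idx, tech_idx = tech_idx, payoff = payoff,
         N = N, logN = log(N), kappa = kappa,
         actor_rows = lapply(seq_len(J), function(j) which(actor_idx == j) - 1L),
         window_days = as.integer(window_days),
         age_std = roster$age_std),
    class = "ewa_data"
  )
}

# Expand possibly-scalar per-individual parameter inputs to full vectors.
expand_param <- function(x, J, name) {
  if (length(x) == 1) x <- rep(x, J)
  if (length(x) != J) stop(name, " must have length 1 or ", J, call. = FALSE)
  x
}

#' Log-likelihood of a bout table under given learning parameters
#'
#' Replays the bout series once in time order, accumulating the log of the
#' mixture probability of each realized technique choice and updating the
#' actor's attractions with each realized pay-off. The pointwise terms (one
#' per bout) sum to the total and feed WAIC.
#'
#' @param bouts bout table sorted by `(day, seq)`, or a precomputed
#'   [prepare_ewa_data()] object.
#' @param roster individual table (ignored if `bouts` is an `ewa_data`).
#' @param params list with `lambda` (scalar), `phi`, `gam`, `f` (scalar or
#'   per-individual, in roster order), and `beta` (length-5 vector or
#'   individual x 5 matrix, cue order `pay, rank, kin, coho, age`).
#' @param window_days moving-window width (ignored if `bouts` is an
#'   `ewa_data`).
#' @param techniques optional technique labels (ignored if `bouts` is an
#'   `ewa_data`).
#' @param A0 optional initial attraction matrix (individual x technique).
#' @param social set `FALSE` to drop the social term (gamma treated as 0).
#' @return list with `total` and `pointwise` (length `nrow(bouts)`).
#' @export
ewa_loglik <- function(bouts, roster = NULL, params, window_days = 14,
                       techniques = NULL, A0 = NULL, social = TRUE) {
  dat <- if (inherits(bouts, "ewa_data")) bouts
         else prepare_ewa_data(bouts, roster, window_days, techniques)
  J <- dat$J; K <- dat$K
  lambda <- params$lambda
  stopifnot(length(lambda) == 1, lambda >= 0)
  phi <- expand_param(params$phi, J, "phi")
  gam <- expand_param(params$gam %||% 0, J, "gam")
  f <- expand_param(params$f %||% 1, J, "f")
  stopifnot(all(phi >= 0 & phi <= 1), all(gam >= 0 & gam <= 1), all(f > 0))
  beta <- params$beta %||% rep(0, 5)
  if (is.null(dim(beta))) beta <- matrix(rep(as.numeric(beta), each = J), J, 5)
  stopifnot(nrow(beta) == J, ncol(beta) == 5)
  A0 <- A0 %||% matrix(0, J, K)
  stopifnot(nrow(A0) == J, ncol(A0) == K)
  if (dat$n == 0) return(list(total = 0, pointwise = numeric(0)))
  pw <- ewa_loglik_cpp(dat$actor_idx, dat$tech_idx, dat$payoff,
                       as.numeric(dat$logN), as.numeric(dat$kappa), A0,
                       lambda, phi, gam, f, beta, isTRUE(social))
  list(total = sum(pw), pointwise = pw)
}
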