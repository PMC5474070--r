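# Social cues: what an individual learned from watching others.
#
# Social information enters choice through the technique frequencies N_i an
# observer witnessed within a moving window of recent days, and through five
# demonstrator/outcome cues attached to each witnessed bout: pay-off,
# demonstrator rank, matrilineal kinship, age similarity, and demonstrator
# age. Choice keyed to frequency (with exponent f) captures conformity
# (f > 1) or anti-conformity (f < 1); the cue terms capture pay-off bias and
# model biases.

CUE_NAMES <- c("pay", "rank", "kin", "coho", "age")

#' Cue vector for one observed demonstration
#'
#' Computes the five social-cue values a focal observer extracts from one
#' witnessed bout:
#' * `pay`: the demonstrator's realized pay-off, `1/log(duration)` on
#'   success and 0 on failure;
#' * `rank`: 1 if the demonstrator is the alpha, else 0;
#' * `kin`: 1 if demonstrator and observer share a matriline, else 0;
#' * `coho` (age similarity): `1 / (1 + |age_dem - age_obs|)` in years;
#' * `age` (age bias): the demonstrator's standardized age.
#'
#' @param demonstrator,observer individual ids present in `roster`.
#' @param success,duration_s outcome of the witnessed bout.
#' @param roster individual table with columns `id`, `age_years`,
#'   `matriline`, `alpha`.
#' @return named numeric vector of length 5.
#' @export
cue_vector <- function(demonstrator, observer, success, duration_s, roster) {
  roster <- validate_roster(roster)
  d <- match(demonstrator, roster$id)
  o <- match(observer, roster$id)
  if (is.na(d)) stop("unknown demonstrator: ", demonstrator, call. = FALSE)
  if (is.na(o)) stop("unknown observer: ", observer, call. = FALSE)
  c(
    pay  = payoff_from_outcome(success, duration_s),
    rank = as.numeric(roster$alpha[d]),
    kin  = as.numeric(roster$matriline[d] == roster$matriline[o]),
    coho = 1 / (1 + abs(roster$age_years[d] - roster$age_years[o])),
    age  = roster$age_std[d]
  )
}

#' Tally an observer's social-information window
#'
#' Collects the bouts a focal observer witnessed (its id in the bout's
#' audience) within the moving window: bouts from the previous `window_days`
#' days — a bout exactly `window_days` days old is still inside, one day
#' older is not — plus same-day bouts earlier in sequence than `now_seq`.
#' Returns per-technique observation counts `N` and, for each technique, the
#' arithmetic mean of each cue value over the witnessed bouts of that
#' technique (techniques never witnessed get all-zero cue rows). Frequency
#' information enters choice through `N` alone; averaging the cues avoids
#' double-counting frequency.
#'
#' @param bouts bout table (see [simulate_group()] for the schema).
#' @param roster individual table.
#' @param observer focal individual id.
#' @param now_day integer day of the decision being informed.
#' @param window_days window width in days (the field default is 14;
#'   sensitivity set 7/14/21/28).
#' @param now_seq within-day sequence of the decision; same-day bouts with
#'   `seq < now_seq` are included. Default `Inf` includes the whole day.
#' @param techniques technique labels fixing the order of the summary;
#'   default: sorted unique techniques in `bouts`.
#' @return list with integer vector `N` (named by technique), matrix `kappa`
#'   (technique x 5 cues), and `window_days`.
#' @export
tally_window <- function(bouts, roster, observer, now_day,
                         window_days = 14, now_seq = Inf,
                         techniques = NULL) {
  stopifnot(window_days >= 1)
  roster <- validate_roster(roster)
  if (!observer %in% roster$id) stop("unknown observer: ", observer, call. = FALSE)
  bouts <- validate_bouts(bouts, roster)
  techniques <- techniques %||% sort(unique(bouts$technique))
  K <- length(techniques)
  N <- stats::setNames(integer(K), techniques)
  kappa <- matrix(0, K, length(CUE_NAMES), dimnames = list(techniques, CUE_NAMES))
  if (nrow(bouts) == 0 || K == 0) {
    return(list(N = N, kappa = kappa, window_days = as.integer(window_days)))
  }
  in_window <- (bouts$day >= now_day - window_days & bouts$day < now_day) |
    (bouts$day == now_day & bouts$seq < now_seq)
  saw <- vapply(bouts$audience, function(a) observer %in% a, logical(1))
  keep <- which(in_window & saw & bouts$actor != observer)
  for (r in keep) {
    tech <- bouts$technique[r]
    i <- match(tech, techniques)
    if (is.na(i)) stop("bout technique '", tech, "' not in technique set", call. = FALSE)
    kv <- cue_vector(bouts$actor[r], observer, bouts$success[r],
                     bouts$duration_s[r], roster)
    # running mean per technique
    N[i] <- N[i] + 1L
    kappa[i, ] <- kappa[i, ] + (kv - kappa[i, ]) / N[i]
  }
  list(N = N, kappa = kappa, window_days = as.integer(window_days))
}

#' Social-learning choice probabilities
#'
#' Probability of choosing each technique on the basis of social cues alone:
#' `S_i` proportional to `N_i^f * exp(sum_k beta_k * kappa_ki)`, normalized
#' over the techniques actually witnessed (`N_i > 0`); unwitnessed techniques
#' get probability 0. With `f = 1` and all `beta = 0`, techniques influence
#' choice in proportion to their observed frequency; `f > 1` is conformist
#' (majority over-weighted), `f < 1` anti-conformist (rare options
#' over-weighted). If nothing was witnessed (`all(N == 0)`) the social term
#' is undefined and `NULL` is returned; [combine_probs()] then falls back to
#' individual learning.
#'
#' @param summary a window summary from [tally_window()], or any list with
#'   elements `N` (counts) and `kappa` (technique x 5 cue matrix).
#' @param f_j frequency-dependence exponent, `f_j > 0`.
#' @param beta_j numeric cue-influence vector of length 5 in the order
#'   `r paste(CUE_NAMES, collapse = ", ")`.
#' @return named probability vector over techniques, or `NULL`.
#' @export
social_choice_probs <- function(summary, f_j, beta_j) {
  stopifnot(f_j > 0, length(beta_j) == length(CUE_NAMES))
  N <- summary$N
  if (all(N == 0)) return(NULL)
  kappa <- summary$kappa
  stopifnot(nrow(kappa) == length(N))
  B <- drop(kappa %*% beta_j)
  # work on the log scale for stability, over witnessed techniques only
  logw <- ifelse(N > 0, f_j * log(N) + B, -Inf)
  S <- stats::setNames(numeric(length(N)), names(N))
  seen <- N > 0
  S[seen] <- softmax(logw[seen])
  S
}

#' Social preference curve for a high-pay-off option
#'
#' For a two-option social environment — a high-pay-off technique with
#' pay-off cue `payoff_high` against a never-successful alternative (pay-off
#' cue 0) — evaluates the probability of choosing the high-pay-off option as
#' a function of its observed frequency among `n_total` witnessed bouts.
#' Under unbiased social learning (`f = 1`, `beta = 0`) the curve is the
#' diagonal; pay-off bias lifts it above the diagonal, anti-conformity
#' (`f < 1`) pulls it below near frequency 1.
#'
#' @param freq_grid frequencies in (0, 1); each must map to a whole count of
#'   `n_total`.
#' @param n_total total witnessed bouts split between the two options.
#' @param f_j frequency-dependence exponent.
#' @param beta_j either the scalar pay-off bias or a full 5-cue vector.
#' @param payoff_high pay-off cue value of the better option (e.g. 0.5).
#' @return tibble with columns `freq`, `n_high`, `n_low`, `p_high`.
#' @export
preference_curve <- function(freq_grid, n_total, f_j, beta_j, payoff_high) {
  stopifnot(n_total >= 2, all(freq_grid > 0 & freq_grid < 1))
  if (length(beta_j) == 1) {
    beta_j <- c(pay = beta_j, rank = 0, kin = 0, coho = 0, age = 0)
  }
  n_high <- freq_grid * n_total
  if (any(abs(n_high - round(n_high)) > 1e-8)) {
    stop("each frequency must map to an integer count of n_total", call. = FALSE)
  }
  n_high <- as.integer(round(n_high))
  kappa <- matrix(0, 2, length(CUE_NAMES),
                  dimnames = list(c("high", "low"), CUE_NAMES))
  kappa["high", "pay"] <- payoff_high
  p_high <- vapply(n_high, function(nh) {
    s <- social_choice_probs(
      list(N = c(high = nh, low = n_total - nh), kappa = kappa),
      f_j = f_j, beta_j = beta_j
    )
    s[["high"]]
  }, numeric(1))
  tibble::tibble(
    freq = freq_grid,
    n_high = n_high,
    n_low = n_total - n_high,
    p_high = p_high
  )
}
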