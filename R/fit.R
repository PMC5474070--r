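# Bayesian fitting of EWA learning models.
#
# The posterior is sampled on an unconstrained parameterization: log(lambda),
# log-odds intercepts and age slopes for phi and gamma, log-scale location
# for f, identity-scale cue influences beta, log between-individual SDs, and
# non-centered standard-normal deviates z for the varying effects. The
# sampler is an adaptive random-walk Metropolis-within-Gibbs: each coordinate
# gets a Gaussian proposal whose scale adapts toward a 0.44 acceptance rate
# during warmup and is frozen afterwards.

#' Weakly informative prior set
#'
#' Standard normal priors on cue influences, link-scale intercepts and age
#' slopes; half-normal on between-individual SDs; normal on log(lambda).
#' These keep the model sceptical of large effects and hold phi and gamma
#' away from the 0/1 boundaries a priori.
#'
#' @param intercept_sd,slope_sd,beta_sd normal prior SDs.
#' @param sigma_scale half-normal scale for between-individual SDs.
#' @param log_lambda_mean,log_lambda_sd normal prior on log(lambda).
#' @param log_f_sd normal prior SD on the log-scale location of f.
#' @return a `prior_set` list.
#' @export
default_priors <- function(intercept_sd = 1, slope_sd = 1, beta_sd = 1,
                           sigma_scale = 1, log_lambda_mean = 1,
                           log_lambda_sd = 1, log_f_sd = 1) {
  structure(list(intercept_sd = intercept_sd, slope_sd = slope_sd,
                 beta_sd = beta_sd, sigma_scale = sigma_scale,
                 log_lambda_mean = log_lambda_mean,
                 log_lambda_sd = log_lambda_sd, log_f_sd = log_f_sd),
            class = "prior_set")
}

# Coordinate layout of the unconstrained parameter vector for a spec.
# Types drive priors; the integer index map `ix` makes the transform to
# per-individual values cheap inside the sampler's inner loop.
build_pack <- function(spec, J) {
  nm <- character(0); type <- character(0)
  ix <- list()
  add <- function(n, t, key = n) {
    start <- length(nm) + 1L
    nm <<- c(nm, n); type <<- c(type, rep(t, length(n)))
    ix[[key]] <<- seq.int(start, length.out = length(n))
  }
  add("log_lambda", "log_lambda")
  add("a_phi", "intercept")
  if (spec$age_effects) add("mu_phi", "slope")
  if ("phi" %in% spec$varying) {
    add("log_sigma_phi", "log_sigma")
    add(paste0("z_phi[", seq_len(J), "]"), "z", key = "z_phi")
  }
  if (spec$social_learning) {
    add("a_gam", "intercept")
    if (spec$age_effects) add("mu_gam", "slope")
    if ("gam" %in% spec$varying) {
      add("log_sigma_gam", "log_sigma")
      add(paste0("z_gam[", seq_len(J), "]"), "z", key = "z_gam")
    }
    if (spec$frequency_dependence) {
      add("mu_lf", "log_f")
      if ("f" %in% spec$varying) {
        add("log_sigma_f", "log_sigma")
        add(paste0("z_f[", seq_len(J), "]"), "z", key = "z_f")
      }
    }
    for (cue in spec$cues) {
      add(paste0("b_", cue), "beta")
      if ("beta" %in% spec$varying) {
        add(paste0("log_sigma_b_", cue), "log_sigma")
        add(paste0("z_b_", cue, "[", seq_len(J), "]"), "z",
            key = paste0("z_b_", cue))
      }
    }
  }
  list(names = nm, type = type, d = length(nm), J = J, spec = spec, ix = ix,
       prior_ix = list(
         log_lambda = which(type == "log_lambda"),
         intercept = which(type == "intercept"),
         slope = which(type == "slope"),
         beta = which(type == "beta"),
         log_f = which(type == "log_f"),
         z = which(type == "z"),
         log_sigma = which(type == "log_sigma")
       ))
}

# Map an unconstrained vector to per-individual learning parameters.
unpack_params <- function(theta, pack, age_std) {
  ix <- pack$ix; J <- pack$J; spec <- pack$spec
  lambda <- exp(theta[ix$log_lambda])
  eta_phi <- theta[ix$a_phi]
  if (spec$age_effects) eta_phi <- eta_phi + theta[ix$mu_phi] * age_std
  if (!is.null(ix$z_phi)) {
    eta_phi <- eta_phi + exp(theta[ix$log_sigma_phi]) * theta[ix$z_phi]
  }
  phi <- logistic(rep_len(eta_phi, J))
  gam <- rep.int(0, J); f <- rep.int(1, J); beta <- matrix(0, J, 5)
  if (spec$social_learning) {
    eta_g <- theta[ix$a_gam]
    if (spec$age_effects) eta_g <- eta_g + theta[ix$mu_gam] * age_std
    if (!is.null(ix$z_gam)) {
      eta_g <- eta_g + exp(theta[ix$log_sigma_gam]) * theta[ix$z_gam]
    }
    gam <- logistic(rep_len(eta_g, J))
    if (spec$frequency_dependence) {
      eta_f <- theta[ix$mu_lf]
      if (!is.null(ix$z_f)) {
        eta_f <- eta_f + exp(theta[ix$log_sigma_f]) * theta[ix$z_f]
      }
      f <- exp(rep_len(eta_f, J))
    }
    for (cue in spec$cues) {
      b <- theta[ix[[paste0("b_", cue)]]]
      if (!is.null(ix[[paste0("z_b_", cue)]])) {
        b <- b + exp(theta[ix[[paste0("log_sigma_b_", cue)]]]) *
          theta[ix[[paste0("z_b_", cue)]]]
      }
      beta[, match(cue, CUE_NAMES)] <- rep_len(b, J)
    }
  }
  list(lambda = lambda, phi = phi, gam = gam, f = f, beta = beta)
}

# Log prior density (including Jacobians of the log transforms for sigma).
log_prior <- function(theta, pack, priors) {
  pi_ <- pack$prior_ix
  lp <- stats::dnorm(theta[pi_$log_lambda], priors$log_lambda_mean,
                     priors$log_lambda_sd, log = TRUE)
  if (length(pi_$intercept)) {
    lp <- lp + sum(stats::dnorm(theta[pi_$intercept], 0, priors$intercept_sd, log = TRUE))
  }
  if (length(pi_$slope)) {
    lp <- lp + sum(stats::dnorm(theta[pi_$slope], 0, priors$slope_sd, log = TRUE))
  }
  if (length(pi_$beta)) {
    lp <- lp + sum(stats::dnorm(theta[pi_$beta], 0, priors$beta_sd, log = TRUE))
  }
  if (length(pi_$log_f)) {
    lp <- lp + sum(stats::dnorm(theta[pi_$log_f], 0, priors$log_f_sd, log = TRUE))
  }
  if (length(pi_$z)) {
    lp <- lp - 0.5 * sum(theta[pi_$z]^2) - length(pi_$z) * 0.9189385332046727
  }
  if (length(pi_$log_sigma)) {
    s <- theta[pi_$log_sigma]
    sig <- exp(s)
    lp <- lp + sum(stats::dnorm(sig, 0, priors$sigma_scale, log = TRUE) +
                     log(2) + s)
  }
  lp
}

# One adaptive Metropolis-within-Gibbs chain, exploiting the factorization
# of the likelihood over actors: a proposal on a varying-effect coordinate
# re-evaluates only that individual's bouts; population-level coordinates
# re-evaluate everyone. Proposal scales adapt toward a 0.44 acceptance rate
# during warmup and are frozen afterwards.
run_chain <- function(init, iter, warmup, pack, dat, A0, priors,
                      coord_actor, target = 0.44) {
  d <- pack$d
  J <- dat$J
  logN_vec <- as.numeric(dat$logN)
  kappa_vec <- as.numeric(dat$kappa)
  social <- pack$spec$social_learning

  actor_ll <- function(j, pars) {
    ewa_loglik_actor_cpp(dat$actor_rows[[j]], dat$tech_idx, dat$payoff,
                         logN_vec, kappa_vec, A0[j, ], dat$n, pars$lambda,
                         pars$phi[j], pars$gam[j], pars$f[j], pars$beta[j, ],
                         social)
  }
  all_ll <- function(pars) {
    vapply(seq_len(J), actor_ll, numeric(1), pars = pars)
  }

  theta <- init
  pars <- unpack_params(theta, pack, dat$age_std)
  llj <- all_ll(pars)
  pr <- log_prior(theta, pack, priors)
  if (!is.finite(sum(llj) + pr)) {
    stop("initial log-posterior is not finite", call. = FALSE)
  }
  ls <- rep(log(0.3), d)
  keep <- matrix(NA_real_, iter - warmup, d)
  for (s in seq_len(iter)) {
    for (i in seq_len(d)) {
      prop <- theta
      prop[i] <- theta[i] + exp(ls[i]) * stats::rnorm(1)
      pars_prop <- unpack_params(prop, pack, dat$age_std)
      pr_prop <- log_prior(prop, pack, priors)
      j <- coord_actor[i]
      if (j == 0L) {
        llj_prop <- all_ll(pars_prop)
        delta <- sum(llj_prop) - sum(llj) + pr_prop - pr
      } else {
        ll_j_prop <- actor_ll(j, pars_prop)
        delta <- ll_j_prop - llj[j] + pr_prop - pr
      }
      alpha <- if (is.finite(delta)) min(1, exp(delta)) else 0
      if (stats::runif(1) < alpha) {
        theta <- prop
        pars <- pars_prop
        pr <- pr_prop
        if (j == 0L) llj <- llj_prop else llj[j] <- ll_j_prop
      }
      if (s <= warmup) {
        ls[i] <- ls[i] + min(0.25, 1 / sqrt(s)) * (alpha - target)
      }
    }
    if (s > warmup) keep[s - warmup, ] <- theta
  }
  keep
}

# Split-Rhat over a draws array (iterations x chains).
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  grp <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(grp)
  means <- colMeans(grp)
  vars <- apply(grp, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Crude effective sample size from combined-chain autocorrelations.
ess_basic <- function(x) {
  v <- as.numeric(x) - mean(x)
  n <- length(v)
  if (stats::sd(v) == 0) return(n)
  acf_v <- stats::acf(v, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- which(acf_v < 0)
  if (length(pos) > 0) acf_v <- acf_v[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(acf_v))
}

#' Fit an EWA learning model by MCMC
#'
#' Samples the posterior of the hierarchical learning model defined by an
#' [ewa_spec()] given a bout table, using weakly informative priors and the
#' package's adaptive random-walk Metropolis sampler. Refitting with the
#' same data, spec and seed reproduces the draws exactly.
#'
#' @param bouts bout table sorted by `(day, seq)`, or an `ewa_data` from
#'   [prepare_ewa_data()] (whose window width then takes precedence).
#' @param roster individual table.
#' @param spec an [ewa_spec()].
#' @param chains,iter,warmup MCMC schedule; `iter` counts total sweeps per
#'   chain including warmup.
#' @param seed integer seed controlling initialization and sampling.
#' @param priors a [default_priors()] object.
#' @param A0 optional initial attraction matrix.
#' @param techniques optional technique labels fixing the technique set.
#' @param n_loglik number of (evenly thinned) posterior draws used for the
#'   pointwise log-likelihood matrix that feeds WAIC.
#' @return an `ewa_fit` object; see [tidy.ewa_fit()], [glance.ewa_fit()],
#'   [waic()], [individual_params()].
#' @export
fit_ewa <- function(bouts, roster = NULL, spec = ewa_spec(), chains = 2,
                    iter = 1500, warmup = floor(iter / 2), seed = 1,
                    priors = default_priors(), A0 = NULL, techniques = NULL,
                    n_loglik = 400) {
  stopifnot(inherits(spec, "ewa_spec"), iter > warmup, warmup >= 1)
  dat <- if (inherits(bouts, "ewa_data")) bouts
         else prepare_ewa_data(bouts, roster, spec$window_days, techniques)
  pack <- build_pack(spec, dat$J)
  A0 <- A0 %||% matrix(0, dat$J, dat$K)
  kappa_vec <- as.numeric(dat$kappa)
  logN_vec <- as.numeric(dat$logN)

  # which individual each coordinate belongs to (0 = population-level)
  coord_actor <- integer(pack$d)
  for (key in grep("^z_", names(pack$ix), value = TRUE)) {
    coord_actor[pack$ix[[key]]] <- seq_len(dat$J)
  }

  init_base <- numeric(pack$d)
  init_base[pack$type == "log_lambda"] <- priors$log_lambda_mean
  init_base[pack$type == "log_sigma"] <- log(0.5)

  draws <- array(NA_real_, dim = c(iter - warmup, chains, pack$d),
                 dimnames = list(NULL, NULL, pack$names))
  for (ch in seq_len(chains)) {
    set.seed(seed + 7919L * (ch - 1L))
    init <- init_base + 0.1 * stats::rnorm(pack$d)
    draws[, ch, ] <- run_chain(init, iter, warmup, pack, dat, A0, priors,
                               coord_actor)
  }

  diag_tbl <- tibble::tibble(
    parameter = pack$names,
    rhat = vapply(seq_len(pack$d),
                  function(i) split_rhat(matrix(draws[, , i], ncol = chains)),
                  numeric(1)),
    ess = vapply(seq_len(pack$d), function(i) ess_basic(draws[, , i]), numeric(1))
  )
  converged <- all(is.na(diag_tbl$rhat) | diag_tbl$rhat < 1.1)

  flat <- matrix(draws, nrow = (iter - warmup) * chains, ncol = pack$d)
  colnames(flat) <- pack$names

  idx <- unique(round(seq(1, nrow(flat), length.out = min(n_loglik, nrow(flat)))))
  pwll <- matrix(NA_real_, length(idx), dat$n)
  for (r in seq_along(idx)) {
    pars <- unpack_params(flat[idx[r], ], pack, dat$age_std)
    pwll[r, ] <- ewa_loglik_cpp(dat$actor_idx, dat$tech_idx, dat$payoff,
                                logN_vec, kappa_vec, A0,
                                pars$lambda, pars$phi, pars$gam, pars$f,
                                pars$beta, spec$social_learning)
  }

  fit <- structure(
    list(draws = flat, draws_array = draws, pack = pack, spec = spec,
         data = dat, A0 = A0, priors = priors, seed = seed,
         chains = chains, iter = iter, warmup = warmup,
         pointwise_loglik = pwll, diagnostics = diag_tbl,
         converged = converged, n_params = pack$d),
    class = "ewa_fit"
  )
  if (!converged) {
    warning("some split-Rhat values exceed 1.1; treat estimates with caution",
            call. = FALSE)
  }
  fit
}

# Posterior draws of interpretable (natural-scale) quantities.
derived_draws <- function(fit) {
  flat <- fit$draws
  spec <- fit$spec
  out <- list(lambda = exp(flat[, "log_lambda"]),
              phi = logistic(flat[, "a_phi"]))
  if ("log_sigma_phi" %in% colnames(flat)) {
    out$sigma_phi <- exp(flat[, "log_sigma_phi"])
  }
  if (spec$age_effects) out$mu_phi <- flat[, "mu_phi"]
  if (spec$social_learning) {
    out$gamma <- logistic(flat[, "a_gam"])
    if ("log_sigma_gam" %in% colnames(flat)) {
      out$sigma_gam <- exp(flat[, "log_sigma_gam"])
    }
    if (spec$age_effects) out$mu_gam <- flat[, "mu_gam"]
    if (spec$frequency_dependence) out$f <- exp(flat[, "mu_lf"])
    for (cue in spec$cues) out[[paste0("beta_", cue)]] <- flat[, paste0("b_", cue)]
  }
  do.call(cbind, out)
}

#' Posterior summaries of interpretable parameters
#'
#' Posterior medians, SDs and central 89% credible intervals of the
#' natural-scale parameters: `lambda`, population-median `phi` and `gamma`
#' (at mean age), `f`, the cue influences `beta_*`, between-individual SDs
#' and age slopes where estimated.
#'
#' @param x an `ewa_fit`.
#' @param prob interval mass (default 0.89).
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.ewa_fit <- function(x, prob = 0.89, ...) {
  dd <- derived_draws(x)
  a <- (1 - prob) / 2
  tibble::tibble(
    term = colnames(dd),
    estimate = apply(dd, 2, stats::median),
    std.error = apply(dd, 2, stats::sd),
    conf.low = apply(dd, 2, stats::quantile, probs = a),
    conf.high = apply(dd, 2, stats::quantile, probs = 1 - a)
  )
}

#' One-row model summary
#'
#' @param x an `ewa_fit`.
#' @param ... unused.
#' @return tibble with bout count, parameter count, WAIC fields, max
#'   split-Rhat and a convergence flag.
#' @export
glance.ewa_fit <- function(x, ...) {
  w <- waic(x)
  tibble::tibble(
    n_bouts = x$data$n,
    n_params = x$n_params,
    lppd = w$lppd,
    p_waic = w$p_waic,
    waic = w$waic,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' @export
print.ewa_fit <- function(x, ...) {
  cat("<ewa_fit> model:", x$spec$label, "\n")
  cat("  ", x$data$n, " bouts, ", x$data$J, " individuals, ",
      x$data$K, " techniques; window ", x$data$window_days, " days\n", sep = "")
  cat("  ", x$chains, " chain(s) x ", x$iter, " iterations (",
      x$warmup, " warmup); ", x$n_params, " parameters; ",
      if (x$converged) "converged" else "NOT CONVERGED (max Rhat > 1.1)",
      "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Posterior medians of per-individual learning parameters
#'
#' Applies the logistic age links draw by draw to recover each individual's
#' updating rate `phi_j` and social weight `gamma_j`.
#'
#' @param fit an `ewa_fit`.
#' @return tibble: `id`, `age_years`, posterior median `phi` and (when the
#'   model has social learning) `gamma`.
#' @export
individual_params <- function(fit) {
  stopifnot(inherits(fit, "ewa_fit"))
  flat <- fit$draws; pack <- fit$pack; spec <- fit$spec
  roster <- fit$data$roster
  J <- pack$J
  med_par <- function(prefix, a_name, mu_name, sig_name) {
    eta <- matrix(flat[, a_name], nrow(flat), J)
    if (spec$age_effects && mu_name %in% colnames(flat)) {
      eta <- eta + outer(flat[, mu_name], fit$data$age_std)
    }
    zc <- paste0(prefix, "[", seq_len(J), "]")
    if (all(zc %in% colnames(flat))) {
      eta <- eta + exp(flat[, sig_name]) * flat[, zc]
    }
    apply(logistic(eta), 2, stats::median)
  }
  out <- tibble::tibble(
    id = roster$id, age_years = roster$age_years,
    phi = med_par("z_phi", "a_phi", "mu_phi", "log_sigma_phi")
  )
  if (spec$social_learning) {
    out$gamma <- med_par("z_gam", "a_gam", "mu_gam", "log_sigma_gam")
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
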