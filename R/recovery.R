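# Parameter-recovery harness: simulate under known parameters, fit, and
# check that the posterior recovers the generating values.

#' Parameter-recovery experiment
#'
#' For each replicate: forward-simulates the configured group experiment
#' with a fresh seed, fits `spec`, and records posterior median, SD and 89%
#' interval of each interpretable parameter alongside its generating value.
#' The summary reports per-parameter bias, RMSE and interval coverage.
#'
#' @param config an [sim_config()]; its `true_params` are the generating
#'   values.
#' @param spec the [ewa_spec()] to fit (should nest the generating process).
#' @param n_replicates number of simulate-and-fit replicates; 0 gives an
#'   empty report.
#' @param seeds integer seeds, one per replicate (default `1:n_replicates`).
#' @param prob interval mass for coverage (default 0.89).
#' @param ... passed to [fit_ewa()].
#' @return list with `summary` (per-parameter tibble: `term`, `truth`,
#'   `bias`, `rmse`, `coverage`, `n`) and `replicates` (per-replicate
#'   estimates).
#' @export
ewa_recovery <- function(config, spec, n_replicates = 10,
                         seeds = seq_len(n_replicates), prob = 0.89, ...) {
  stopifnot(inherits(config, "ewa_sim_config"), n_replicates >= 0,
            length(seeds) == n_replicates)
  truth <- recovery_truth(config$true_params, spec)
  if (n_replicates == 0) {
    return(list(
      summary = tibble::tibble(term = character(0), truth = numeric(0),
                               bias = numeric(0), rmse = numeric(0),
                               coverage = numeric(0), n = integer(0)),
      replicates = tibble::tibble()
    ))
  }
  reps <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- seeds[r]
    bouts <- simulate_group(cfg)
    fit <- suppressWarnings(
      fit_ewa(bouts, config$roster, spec, seed = seeds[r],
              techniques = config$techniques$name, ...)
    )
    td <- tidy(fit, prob = prob)
    td$replicate <- r
    td
  })
  replicates <- dplyr::bind_rows(reps)
  replicates <- dplyr::left_join(replicates, truth, by = "term")
  summary <- replicates |>
    dplyr::filter(!is.na(.data$truth)) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      truth = .data$truth[1],
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$conf.low <= .data$truth &
                        .data$truth <= .data$conf.high),
      n = dplyr::n(),
      .groups = "drop"
    )
  list(summary = summary, replicates = replicates)
}

# Generating values on the same natural scale tidy() reports.
recovery_truth <- function(pop, spec) {
  truth <- c(lambda = pop$lambda, phi = logistic(pop$a_phi))
  if ("phi" %in% spec$varying) truth["sigma_phi"] <- pop$sigma$phi
  if (spec$age_effects) truth["mu_phi"] <- pop$mu_phi
  if (spec$social_learning) {
    truth["gamma"] <- if (is.finite(pop$a_gam)) logistic(pop$a_gam) else 0
    if ("gam" %in% spec$varying) truth["sigma_gam"] <- pop$sigma$gamma
    if (spec$age_effects) truth["mu_gam"] <- pop$mu_gamma
    if (spec$frequency_dependence) truth["f"] <- exp(pop$log_f)
    for (cue in spec$cues) truth[paste0("beta_", cue)] <- pop$beta[[cue]]
  }
  tibble::tibble(term = names(truth), truth = unname(truth))
}
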