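# ggplot2 visualizations of simulated dynamics and fitted learning models.

#' Technique frequencies over time
#'
#' Daily population frequency of each technique — the diffusion curves a
#' transmission experiment produces.
#'
#' @param bouts bout table.
#' @param window smoothing window in days (simple centred moving average of
#'   daily frequencies; 1 = raw).
#' @return a ggplot.
#' @export
plot_technique_frequencies <- function(bouts, window = 5) {
  daily <- bouts |>
    dplyr::count(.data$day, .data$technique) |>
    dplyr::group_by(.data$day) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::complete(day = seq_len(max(bouts$day)),
                    technique = unique(bouts$technique),
                    fill = list(n = 0, freq = 0))
  if (window > 1) {
    daily <- daily |>
      dplyr::group_by(.data$technique) |>
      dplyr::arrange(.data$day) |>
      dplyr::mutate(freq = stats::filter(.data$freq, rep(1 / window, window),
                                         sides = 2)) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$freq))
  }
  ggplot2::ggplot(daily, ggplot2::aes(.data$day, .data$freq,
                                      colour = .data$technique)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "experimental day", y = "population frequency",
                  colour = "technique") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Social preference curves for a high-pay-off option
#'
#' Probability of socially choosing a high-pay-off option (pay-off cue
#' `payoff_high`, against a never-successful alternative) as a function of
#' its observed frequency, one curve per (f, beta_pay) pair. The diagonal is
#' unbiased social learning; pay-off bias lifts the curve, anti-conformity
#' (f < 1) bends it below the diagonal near frequency 1.
#'
#' @param curves tibble with columns `f` and `beta_pay` (e.g. posterior
#'   medians per individual), or an `ewa_fit` whose medians are used.
#' @param n_total witnessed bouts split between the options.
#' @param payoff_high pay-off cue of the better option.
#' @return a ggplot.
#' @export
plot_preference_curves <- function(curves, n_total = 10, payoff_high = 0.5) {
  if (inherits(curves, "ewa_fit")) {
    td <- tidy(curves)
    curves <- tibble::tibble(
      f = if ("f" %in% td$term) td$estimate[td$term == "f"] else 1,
      beta_pay = if ("beta_pay" %in% td$term) td$estimate[td$term == "beta_pay"] else 0
    )
  }
  stopifnot(all(c("f", "beta_pay") %in% names(curves)))
  grid <- seq_len(n_total - 1) / n_total
  dat <- purrr::pmap_dfr(
    list(curves$f, curves$beta_pay, seq_len(nrow(curves))),
    function(f, b, i) {
      cc <- preference_curve(grid, n_total, f_j = f, beta_j = b,
                             payoff_high = payoff_high)
      cc$curve <- i
      cc
    }
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$freq, .data$p_high,
                                    group = .data$curve)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "observed frequency of high-pay-off option",
                  y = "P(choose high-pay-off option)") +
    ggplot2::theme_minimal()
}

#' Age against per-individual learning parameters
#'
#' Posterior medians of each individual's updating rate phi and social
#' weight gamma plotted against age, with the population-level age trend
#' when the model estimates one.
#'
#' @param fit an `ewa_fit`.
#' @return a ggplot.
#' @export
plot_age_effects <- function(fit) {
  ip <- individual_params(fit)
  long <- tidyr::pivot_longer(ip, dplyr::any_of(c("phi", "gamma")),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$age_years, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "posterior median") +
    ggplot2::theme_minimal()
}

#' Posterior intervals of the interpretable parameters
#'
#' @param object an `ewa_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ewa_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate,
                                   stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::labs(x = "posterior median and 89% interval", y = NULL,
                  title = paste("model:", object$spec$label)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
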