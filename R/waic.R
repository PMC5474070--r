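# WAIC model comparison over the learning-strategy model set.

#' Widely applicable information criterion
#'
#' Computed from the pointwise posterior log-likelihood matrix (draws x
#' points, one point per bout-choice event):
#' `lppd = sum_i log mean_s exp(ll_si)`, `p_waic = sum_i var_s(ll_si)`,
#' `waic = -2 (lppd - p_waic)`. The standard error is
#' `sqrt(n * var_i(contrib_i))` over the pointwise contributions
#' `contrib_i = -2 (lppd_i - p_i)`.
#'
#' @param x a draws x points log-likelihood matrix, or an `ewa_fit`.
#' @param ... unused.
#' @return an `ewa_waic` list: `lppd`, `p_waic`, `waic`, `se`, `n_points`.
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.ewa_fit <- function(x, ...) waic(x$pointwise_loglik)

#' @rdname waic
#' @export
waic.default <- function(x, ...) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("WAIC needs at least 2 posterior draws", call. = FALSE)
  if (ncol(x) < 1) stop("WAIC needs at least 1 data point", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite pointwise log-likelihoods", call. = FALSE)
  # log mean exp per point, stabilized by the per-point max
  mx <- apply(x, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(x, 2, mx))))
  p_i <- apply(x, 2, stats::var)
  contrib <- -2 * (lppd_i - p_i)
  n <- ncol(x)
  structure(
    list(lppd = sum(lppd_i), p_waic = sum(p_i),
         waic = -2 * (sum(lppd_i) - sum(p_i)),
         se = sqrt(n * stats::var(contrib)),
         n_points = n),
    class = "ewa_waic"
  )
}

#' @export
print.ewa_waic <- function(x, ...) {
  cat(sprintf("WAIC %.2f (SE %.2f)  lppd %.2f  p_waic %.2f  n %d\n",
              x$waic, x$se, x$lppd, x$p_waic, x$n_points))
  invisible(x)
}

#' Compare fitted learning-strategy models by WAIC
#'
#' Ranks models by WAIC and converts WAIC differences to Akaike-style
#' weights `w_m` proportional to `exp(-delta_m / 2)`.
#'
#' @param fits named list of `ewa_fit` objects (or `ewa_waic` objects), all
#'   fitted to the same data.
#' @return tibble sorted by WAIC: `model`, `waic`, `se`, `lppd`, `p_waic`,
#'   `delta_waic`, `weight`.
#' @export
compare_ewa_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  labels <- names(fits) %||% paste0("model", seq_along(fits))
  ws <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "ewa_fit")) {
      if (is.null(names(fits))) labels[i] <<- f$spec$label
      waic(f)
    } else if (inherits(f, "ewa_waic")) f
    else stop("fits must be ewa_fit or ewa_waic objects", call. = FALSE)
  })
  npts <- vapply(ws, function(w) w$n_points, numeric(1))
  if (length(unique(npts)) != 1) {
    stop("models were not fitted to the same data (n_points differ)", call. = FALSE)
  }
  waics <- vapply(ws, function(w) w$waic, numeric(1))
  delta <- waics - min(waics)
  w <- exp(-delta / 2)
  out <- tibble::tibble(
    model = labels,
    waic = waics,
    se = vapply(ws, function(w) w$se, numeric(1)),
    lppd = vapply(ws, function(w) w$lppd, numeric(1)),
    p_waic = vapply(ws, function(w) w$p_waic, numeric(1)),
    delta_waic = delta,
    weight = w / sum(w)
  )
  dplyr::arrange(out, .data$waic)
}

#' Window-width sensitivity analysis
#'
#' Refits a learning-strategy model with the social-information window set
#' to each width in `widths` (field sensitivity set: 7, 14, 21 and 28 days)
#' and reports WAIC and the key posterior medians, to check that the sign
#' and rough magnitude of the social-learning parameters are stable.
#'
#' @param bouts,roster data as for [fit_ewa()].
#' @param spec an [ewa_spec()]; its `window_days` is overridden per row.
#' @param widths integer window widths in days.
#' @param ... passed to [fit_ewa()] (chains, iter, seed, ...).
#' @return tibble: one row per width with `window_days`, WAIC fields, and
#'   posterior medians of `gamma`, `f` and each estimated `beta_*`.
#' @export
window_sensitivity <- function(bouts, roster, spec,
                               widths = c(7, 14, 21, 28), ...) {
  stopifnot(all(widths >= 1))
  rows <- lapply(widths, function(w) {
    sp <- spec
    sp$window_days <- as.integer(w)
    fit <- fit_ewa(bouts, roster, sp, ...)
    td <- tidy(fit)
    keys <- td[td$term %in% c("gamma", "f", paste0("beta_", CUE_NAMES)), ]
    wc <- waic(fit)
    out <- tibble::tibble(window_days = as.integer(w), waic = wc$waic,
                          se = wc$se, lppd = wc$lppd, p_waic = wc$p_waic)
    for (k in seq_len(nrow(keys))) out[[keys$term[k]]] <- keys$estimate[k]
    out
  })
  dplyr::bind_rows(rows)
}
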