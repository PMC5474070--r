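# Learning-strategy model specifications.

#' Define a learning-strategy model
#'
#' A model spec fixes which components of the full social-learning model are
#' estimated: whether a social term exists at all (`social_learning`),
#' whether its frequency dependence exponent f is estimated or fixed at 1
#' (`frequency_dependence`), which demonstrator/outcome cues enter the
#' log-linear bias term (`cues`), whether age slopes on the updating rate phi
#' and social weight gamma are estimated (`age_effects`), which parameters
#' get per-individual varying effects (`varying`), and the moving-window
#' width in days.
#'
#' @param label short model name.
#' @param social_learning if `FALSE`, gamma is fixed at 0 (individual
#'   learning only) and all other social flags are ignored.
#' @param frequency_dependence estimate f (`TRUE`) or fix f = 1.
#' @param cues character subset of `c("pay", "rank", "kin", "coho", "age")`.
#' @param age_effects estimate age slopes mu_phi (and mu_gamma when social
#'   learning is on).
#' @param varying parameters with per-individual varying effects
#'   (non-centered, independent); subset of `c("phi", "gam", "f", "beta")`.
#' @param window_days moving-window width (field default 14).
#' @return an `ewa_spec` object.
#' @export
ewa_spec <- function(label = "custom",
                     social_learning = TRUE,
                     frequency_dependence = FALSE,
                     cues = character(0),
                     age_effects = FALSE,
                     varying = c("phi", "gam"),
                     window_days = 14) {
  cues <- as.character(cues)
  bad <- setdiff(cues, CUE_NAMES)
  if (length(bad) > 0) stop("unknown cue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  varying <- intersect(as.character(varying), c("phi", "gam", "f", "beta"))
  if (!social_learning) {
    frequency_dependence <- FALSE
    cues <- character(0)
    varying <- intersect(varying, "phi")
  }
  stopifnot(window_days >= 1)
  structure(
    list(label = label,
         social_learning = isTRUE(social_learning),
         frequency_dependence = isTRUE(frequency_dependence),
         cues = cues,
         age_effects = isTRUE(age_effects),
         varying = varying,
         window_days = as.integer(window_days)),
    class = "ewa_spec"
  )
}

#' @export
print.ewa_spec <- function(x, ...) {
  cat("<ewa_spec> ", x$label, "\n",
      "  social learning: ", x$social_learning,
      " | frequency dependence (f free): ", x$frequency_dependence, "\n",
      "  cues: ", if (length(x$cues)) paste(x$cues, collapse = ", ") else "(none)", "\n",
      "  age effects: ", x$age_effects,
      " | varying: ", paste(x$varying, collapse = ", "),
      " | window: ", x$window_days, " days\n", sep = "")
  invisible(x)
}

#' The canonical set of learning-strategy models
#'
#' Nine strategies: individual learning only; unbiased social learning
#' (frequency-proportional, f = 1, no cues); frequency-dependent social
#' learning (f free); five single-cue models (pay-off, rank, kin,
#' age-similarity, age-bias; each with f = 1); and the global model with all
#' cues, f free, and age effects on phi and gamma.
#'
#' @param window_days moving-window width applied to every spec.
#' @param varying varying-effects setting applied to every spec.
#' @return named list of [ewa_spec()] objects.
#' @export
canonical_specs <- function(window_days = 14, varying = c("phi", "gam")) {
  cue_spec <- function(cue) {
    ewa_spec(label = paste0("cue_", cue), cues = cue,
             varying = varying, window_days = window_days)
  }
  specs <- c(
    list(
      individual = ewa_spec("individual", social_learning = FALSE,
                            varying = varying, window_days = window_days),
      freq_unbiased = ewa_spec("freq_unbiased", varying = varying,
                               window_days = window_days),
      freq_dependent = ewa_spec("freq_dependent", frequency_dependence = TRUE,
                                varying = varying, window_days = window_days)
    ),
    stats::setNames(lapply(CUE_NAMES, cue_spec), paste0("cue_", CUE_NAMES)),
    list(
      global = ewa_spec("global", frequency_dependence = TRUE,
                        cues = CUE_NAMES, age_effects = TRUE,
                        varying = varying, window_days = window_days)
    )
  )
  specs
}
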