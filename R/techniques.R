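# Technique profiles for the synthetic experiment.

#' Fruit-processing technique profiles
#'
#' Success probabilities and handling-time distributions for the seven
#' processing techniques used to open panama (*Sterculia apetala*) fruits,
#' matching the published per-technique summary statistics: success
#' proportions span 0.38-0.89 among ever-successful techniques, median
#' opening times span roughly 29-211 s, and two techniques (pound, scrub)
#' were never successful. The seam-strip median is approximate (the source
#' table is ambiguous for that row); never-successful techniques get a
#' nominal 60 s handling-time scale used only for failure durations.
#' Durations are modelled log-normal with median `duration_med_s` and
#' log-scale SD `duration_sigma`.
#'
#' @return tibble with columns `name`, `p_success`, `duration_med_s`,
#'   `duration_sigma`.
#' @export
capuchin_techniques <- function() {
  tibble::tibble(
    name = c("back_attack", "bite_and_pop", "canine_seam", "chew_hole",
             "pound", "scrub", "seam_strip"),
    p_success = c(0.511, 0.378, 0.885, 0.655, 0, 0, 0.650),
    duration_med_s = c(119, 29, 42, 211.5, 60, 60, 112),
    duration_sigma = 0.95
  )
}

#' Validate a technique-profile table
#'
#' @param techniques tibble with columns `name`, `p_success`,
#'   `duration_med_s` and optionally `duration_sigma` (default 0.95).
#' @return validated tibble.
#' @export
technique_profiles <- function(techniques) {
  stopifnot(is.data.frame(techniques))
  need <- c("name", "p_success", "duration_med_s")
  missing <- setdiff(need, names(techniques))
  if (length(missing) > 0) {
    stop("technique table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  techniques <- tibble::as_tibble(techniques)
  techniques$name <- as.character(techniques$name)
  if (anyDuplicated(techniques$name)) stop("technique names must be unique", call. = FALSE)
  if (any(techniques$p_success < 0 | techniques$p_success > 1)) {
    stop("p_success must lie in [0, 1]", call. = FALSE)
  }
  if (any(techniques$duration_med_s < 2)) {
    stop("duration_med_s must be at least 2 s", call. = FALSE)
  }
  if (is.null(techniques$duration_sigma)) techniques$duration_sigma <- 0.95
  stopifnot(all(techniques$duration_sigma > 0))
  techniques
}
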