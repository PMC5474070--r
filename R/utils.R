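# Small numeric helpers shared across modules.

#' Soft-max of a numeric vector
#'
#' Numerically stable soft-max: `exp(x - max(x)) / sum(exp(x - max(x)))`.
#' Adding a constant to all entries leaves the result unchanged.
#'
#' @param x numeric vector.
#' @return probability vector of the same length, summing to 1.
#' @keywords internal
#' @noRd
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

logistic <- function(x) stats::plogis(x)

#' Standardize ages for link functions and the age-bias cue
#'
#' Ages enter the logistic links and the age-bias cue centred on the group
#' mean and scaled by the group standard deviation, so slope priors are
#' scale-free. A single-individual (or zero-variance) roster gets all zeros.
#'
#' @param age_years numeric vector of ages in years.
#' @return numeric vector of standardized ages.
#' @export
standardize_age <- function(age_years) {
  stopifnot(is.numeric(age_years), all(is.finite(age_years)), all(age_years >= 0))
  s <- stats::sd(age_years)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(age_years)))
  }
  (age_years - mean(age_years)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a roster tibble; returns it with ids as character and a
# standardized-age column appended.
validate_roster <- function(roster) {
  stopifnot(is.data.frame(roster))
  need <- c("id", "age_years", "matriline", "alpha")
  missing <- setdiff(need, names(roster))
  if (length(missing) > 0) {
    stop("roster is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  roster <- tibble::as_tibble(roster)
  roster$id <- as.character(roster$id)
  if (anyDuplicated(roster$id)) stop("roster ids must be unique", call. = FALSE)
  if (any(!is.finite(roster$age_years)) || any(roster$age_years < 0)) {
    stop("roster ages must be finite and non-negative", call. = FALSE)
  }
  if (any(is.na(roster$matriline))) stop("roster matriline may not be NA", call. = FALSE)
  roster$alpha <- as.logical(roster$alpha)
  if (any(is.na(roster$alpha))) stop("roster alpha flag may not be NA", call. = FALSE)
  roster$age_std <- standardize_age(roster$age_years)
  roster
}

# Validate a bout tibble against a roster; normalizes the audience column to
# a list of character vectors and checks ordering/uniqueness invariants.
validate_bouts <- function(bouts, roster) {
  stopifnot(is.data.frame(bouts))
  need <- c("day", "seq", "actor", "technique", "success", "duration_s", "audience")
  missing <- setdiff(need, names(bouts))
  if (length(missing) > 0) {
    stop("bouts table is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bouts <- tibble::as_tibble(bouts)
  bouts$actor <- as.character(bouts$actor)
  bouts$audience <- as_audience_list(bouts$audience)
  if (any(bouts$day < 1)) stop("days are 1-based: found day < 1", call. = FALSE)
  if (anyDuplicated(bouts[, c("day", "seq")])) {
    stop("duplicate (day, seq) pairs in bout table", call. = FALSE)
  }
  ids <- roster$id
  bad_actor <- which(!bouts$actor %in% ids)
  if (length(bad_actor) > 0) {
    stop("bout row ", bad_actor[1], ": actor '", bouts$actor[bad_actor[1]],
         "' not in roster", call. = FALSE)
  }
  for (r in seq_len(nrow(bouts))) {
    aud <- bouts$audience[[r]]
    if (length(aud) > 0) {
      unknown <- setdiff(aud, ids)
      if (length(unknown) > 0) {
        stop("bout row ", r, ": audience id '", unknown[1], "' not in roster",
             call. = FALSE)
      }
      if (bouts$actor[r] %in% aud) {
        stop("bout row ", r, ": actor appears in own audience", call. = FALSE)
      }
    }
  }
  if (any(bouts$success & !(bouts$duration_s > 0))) {
    stop("successful bouts must have positive duration", call. = FALSE)
  }
  bouts
}

# Accepts a list column of character vectors or a semicolon-joined string
# column; returns a list of character vectors (possibly empty).
as_audience_list <- function(audience) {
  if (is.list(audience)) {
    return(lapply(audience, function(a) {
      if (length(a) == 0 || all(is.na(a))) character(0) else as.character(a)
    }))
  }
  audience <- as.character(audience)
  lapply(audience, function(a) {
    if (is.na(a) || !nzchar(a)) character(0) else strsplit(a, ";", fixed = TRUE)[[1]]
  })
}

# Check that bouts are sorted by (day, seq). Silent re-sorting would corrupt
# the attraction dynamics, so callers error instead.
assert_sorted_bouts <- function(bouts) {
  o <- order(bouts$day, bouts$seq)
  if (!identical(o, seq_len(nrow(bouts)))) {
    stop("bouts must be sorted by (day, seq); re-sort explicitly before calling",
         call. = FALSE)
  }
  invisible(bouts)
}
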