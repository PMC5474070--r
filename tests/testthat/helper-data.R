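# Small hand-built roster and bout tables used across unit tests.

toy_roster <- function() {
  tibble::tibble(
    id = c("ANA", "BOB", "CAT", "DAN"),
    age_years = c(4, 8, 8, 20),
    matriline = c("M1", "M1", "M2", "M2"),
    alpha = c(FALSE, FALSE, FALSE, TRUE)
  )
}

# audience normalization mirror used by round-trip checks
as_audience_list_for_test <- function(a) {
  lapply(a, function(x) if (length(x) == 0) character(0) else as.character(x))
}

# One bout row builder with a sane default audience.
bout_row <- function(day, seq, actor, technique, success, duration_s,
                     audience = character(0)) {
  tibble::tibble(day = day, seq = seq, actor = actor, technique = technique,
                 success = success, duration_s = duration_s,
                 audience = list(audience))
}
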