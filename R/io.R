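# Readers/writers for bout and roster tables and the pipeline runner.
#
# Bout CSV schema: day (1-based integer), seq (1-based within day), actor,
# technique, success (0/1), duration_s (decimal seconds), audience
# (semicolon-joined ids, empty allowed). Roster CSV schema: id, age_years,
# matriline, alpha (0/1). Days are experiment days, not calendar dates.

bout_cols <- c("day", "seq", "actor", "technique", "success", "duration_s",
               "audience")

#' Read a bout + roster dataset
#'
#' Parses and validates the two CSV files: every actor and audience member
#' must appear in the roster, `(day, seq)` pairs must be unique, successful
#' bouts must have positive durations. Validation errors name the offending
#' row and id.
#'
#' @param bouts_path,roster_path CSV file paths.
#' @return list with tibbles `bouts` (audience as a list-column) and
#'   `roster`, and `metadata` (file paths).
#' @export
read_dataset <- function(bouts_path, roster_path) {
  bouts <- readr::read_csv(bouts_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(bout_cols, names(bouts))
  if (length(missing) > 0) {
    stop("bout file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bouts$day <- as.integer(bouts$day)
  bouts$seq <- as.integer(bouts$seq)
  bouts$success <- parse_flag(bouts$success, "success")
  bouts$duration_s <- as.numeric(bouts$duration_s)
  if (anyNA(bouts$day) || anyNA(bouts$seq) || anyNA(bouts$duration_s)) {
    stop("non-numeric day/seq/duration_s value in bout file", call. = FALSE)
  }
  roster <- readr::read_csv(roster_path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
  need <- c("id", "age_years", "matriline", "alpha")
  miss_r <- setdiff(need, names(roster))
  if (length(miss_r) > 0) {
    stop("roster file missing column(s): ", paste(miss_r, collapse = ", "),
         call. = FALSE)
  }
  roster$age_years <- as.numeric(roster$age_years)
  roster$alpha <- parse_flag(roster$alpha, "alpha")
  roster <- validate_roster(roster)[, c("id", "age_years", "matriline", "alpha")]
  bouts <- validate_bouts(bouts, validate_roster(roster))
  bouts <- dplyr::arrange(bouts, .data$day, .data$seq)
  list(bouts = bouts, roster = roster,
       metadata = list(bouts_path = bouts_path, roster_path = roster_path))
}

# 0/1 and TRUE/FALSE are both accepted for flag columns.
parse_flag <- function(x, name) {
  out <- dplyr::case_when(
    x %in% c("1", "TRUE", "true", "T") ~ TRUE,
    x %in% c("0", "FALSE", "false", "F") ~ FALSE,
    .default = NA
  )
  if (anyNA(out)) stop("column '", name, "' must be 0/1 or TRUE/FALSE",
                       call. = FALSE)
  out
}

#' Write a bout + roster dataset
#'
#' Inverse of [read_dataset()]: audiences are serialized as semicolon-joined
#' id lists, logical flags as 0/1.
#'
#' @param bouts,roster tibbles in the package's in-memory form.
#' @param bouts_path,roster_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_dataset <- function(bouts, roster, bouts_path, roster_path) {
  aud <- vapply(as_audience_list(bouts$audience), paste, character(1),
                collapse = ";")
  out <- tibble::tibble(
    day = as.integer(bouts$day), seq = as.integer(bouts$seq),
    actor = bouts$actor, technique = bouts$technique,
    success = as.integer(bouts$success),
    duration_s = bouts$duration_s, audience = aud
  )
  readr::write_csv(out, bouts_path)
  ros <- tibble::tibble(id = roster$id, age_years = roster$age_years,
                        matriline = roster$matriline,
                        alpha = as.integer(roster$alpha))
  readr::write_csv(ros, roster_path)
  invisible(c(bouts = bouts_path, roster = roster_path))
}

#' Run a pipeline stage from a config file
#'
#' Thin orchestration over the package's functions. `command` is one of:
#' * `simulate`: forward-simulate a fixture (`fixture` key, optional
#'   `seed`); writes `bouts.csv`, `roster.csv`, `learner_params.csv`.
#' * `fit`: fit one spec (`bouts`, `roster` paths; `spec` block with the
#'   [ewa_spec()] fields; `mcmc` block with `chains`, `iter`, `seed`);
#'   writes `posterior.csv` (parameter, chain, iteration, value) and
#'   `summary.json`.
#' * `compare`: fit several specs by label (`specs`: labels from
#'   [canonical_specs()]) and write `model_table.csv` / `model_table.json`.
#' * `recover`: run [ewa_recovery()] on a fixture (`fixture`,
#'   `n_replicates`, `spec`, `mcmc`); writes `recovery.csv` / `.json`.
#' * `sensitivity`: run [window_sensitivity()] (`widths`); writes
#'   `sensitivity.csv`.
#'
#' The resolved config (including the seed actually used) is written to
#' `config_resolved.json` in the run directory, so deterministic stages can
#' be reproduced exactly.
#'
#' @param command pipeline stage.
#' @param config_path path to a JSON config.
#' @param out_dir run directory (created if needed); default
#'   `config$out_dir` or a `run-<command>` directory beside the config.
#' @param seed overrides the config seed.
#' @return invisibly, the run directory path.
#' @export
run_pipeline <- function(command = c("simulate", "fit", "compare", "recover",
                                     "sensitivity"),
                         config_path, out_dir = NULL, seed = NULL) {
  command <- match.arg(command)
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  out_dir <- out_dir %||% cfg$out_dir %||%
    file.path(dirname(config_path), paste0("run-", command))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$seed <- seed %||% cfg$seed %||% 1L
  cfg$command <- command

  spec_from_cfg <- function(s) {
    if (is.character(s) && length(s) == 1) {
      specs <- canonical_specs(window_days = cfg$window_days %||% 14)
      if (!s %in% names(specs)) {
        stop("unknown spec label '", s, "'; valid: ",
             paste(names(specs), collapse = ", "), call. = FALSE)
      }
      specs[[s]]
    } else {
      ewa_spec(label = s$label %||% "custom",
               social_learning = s$social_learning %||% TRUE,
               frequency_dependence = s$frequency_dependence %||% FALSE,
               cues = s$cues %||% character(0),
               age_effects = s$age_effects %||% FALSE,
               varying = s$varying %||% c("phi", "gam"),
               window_days = s$window_days %||% (cfg$window_days %||% 14))
    }
  }
  mcmc <- cfg$mcmc %||% list()
  fit_args <- list(chains = mcmc$chains %||% 2L, iter = mcmc$iter %||% 1500L,
                   seed = cfg$seed)

  if (command == "simulate") {
    if (is.null(cfg$fixture)) stop("config key 'fixture' is required", call. = FALSE)
    fx <- make_fixture(cfg$fixture, seed = cfg$seed)
    write_dataset(fx$bouts, fx$config$roster,
                  file.path(out_dir, "bouts.csv"),
                  file.path(out_dir, "roster.csv"))
    readr::write_csv(attr(fx$bouts, "learner_params"),
                     file.path(out_dir, "learner_params.csv"))
  } else if (command == "fit") {
    if (is.null(cfg$bouts) || is.null(cfg$roster)) {
      stop("config keys 'bouts' and 'roster' are required", call. = FALSE)
    }
    ds <- read_dataset(cfg$bouts, cfg$roster)
    spec <- spec_from_cfg(cfg$spec %||% "global")
    fit <- suppressWarnings(do.call(fit_ewa, c(list(ds$bouts, ds$roster, spec),
                                               fit_args)))
    nd <- dim(fit$draws_array)
    post <- tidyr::expand_grid(chain = seq_len(nd[2]),
                               iteration = seq_len(nd[1]),
                               parameter = fit$pack$names)
    post$value <- as.numeric(aperm(fit$draws_array, c(3, 1, 2)))
    readr::write_csv(post[, c("parameter", "chain", "iteration", "value")],
                     file.path(out_dir, "posterior.csv"))
    summ <- list(spec = spec$label, n_bouts = fit$data$n,
                 n_params = fit$n_params, converged = fit$converged,
                 estimates = tidy(fit), waic = unclass(waic(fit)))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command == "compare") {
    ds <- read_dataset(cfg$bouts, cfg$roster)
    labels <- cfg$specs %||% c("individual", "freq_dependent", "cue_pay", "global")
    fits <- lapply(labels, function(l) {
      suppressWarnings(do.call(fit_ewa, c(list(ds$bouts, ds$roster,
                                               spec_from_cfg(l)), fit_args)))
    })
    names(fits) <- labels
    tab <- compare_ewa_models(fits)
    readr::write_csv(tab, file.path(out_dir, "model_table.csv"))
    jsonlite::write_json(tab, file.path(out_dir, "model_table.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command == "recover") {
    fx <- make_fixture(cfg$fixture %||% "payoff-biased", simulate = FALSE)
    spec <- spec_from_cfg(cfg$spec %||% "global")
    n_rep <- cfg$n_replicates %||% 3L
    rec <- do.call(ewa_recovery,
                   c(list(fx$config, spec, n_replicates = n_rep,
                          seeds = cfg$seed + seq_len(n_rep)),
                     fit_args[setdiff(names(fit_args), "seed")]))
    readr::write_csv(rec$summary, file.path(out_dir, "recovery.csv"))
    jsonlite::write_json(rec$summary, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command == "sensitivity") {
    ds <- read_dataset(cfg$bouts, cfg$roster)
    spec <- spec_from_cfg(cfg$spec %||% "cue_pay")
    widths <- cfg$widths %||% c(7, 14, 21, 28)
    tab <- suppressWarnings(do.call(window_sensitivity,
                                    c(list(ds$bouts, ds$roster, spec,
                                           widths = widths), fit_args)))
    readr::write_csv(tab, file.path(out_dir, "sensitivity.csv"))
  }

  jsonlite::write_json(cfg, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
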