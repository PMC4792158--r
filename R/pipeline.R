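#' Read and validate a trial-level CSV
#'
#' The interchange format is a plain CSV with one row per trial and at least
#' the columns `subject_id`, `block`, `trial`, `location`, `correct`,
#' `rt_ms` (extra columns such as `group` or `session` pass through).
#' Validation flags rows whose RT exceeds the response deadline and blocks
#' whose trial count deviates from the design.
#'
#' @param path CSV path.
#' @param deadline_ms Response deadline; rows above it are flagged.
#' @param trials_per_block Expected per-block trial count; mismatches raise
#'   a warning. `NULL` skips the check.
#' @param drop_flagged Drop over-deadline rows instead of keeping them
#'   flagged.
#' @return A trial tibble with a logical `flagged` column.
#' @export
ingest_trials <- function(path, deadline_ms = 3000, trials_per_block = 49L,
                          drop_flagged = FALSE) {
  trials <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("subject_id", "block", "trial", "location", "correct",
                "rt_ms")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(trials$rt_ms)) {
    stop("`rt_ms` must be numeric", call. = FALSE)
  }
  trials$correct <- as.logical(trials$correct)
  trials$flagged <- trials$rt_ms > deadline_ms
  if (any(trials$flagged)) {
    warning(sum(trials$flagged), " trial(s) exceed the ", deadline_ms,
            " ms deadline (rows ",
            paste(utils::head(which(trials$flagged), 10L), collapse = ", "),
            ")", call. = FALSE)
  }
  if (!is.null(trials_per_block)) {
    counts <- trials |>
      dplyr::count(.data$subject_id, .data$block)
    bad <- counts[counts$n != trials_per_block, ]
    if (nrow(bad) > 0L) {
      warning("block trial-count mismatch (expected ", trials_per_block,
              "): ",
              paste(sprintf("%s/block %s has %d", bad$subject_id, bad$block,
                            bad$n)[seq_len(min(5L, nrow(bad)))],
                    collapse = "; "), call. = FALSE)
    }
  }
  if (drop_flagged) trials <- trials[!trials$flagged, ]
  trials
}

#' Pipeline configuration
#'
#' Bundles every knob of an end-to-end run. The resolved configuration is
#' snapshotted next to the outputs so any result file is regenerable from
#' the snapshot alone.
#'
#' @param experiment `"exp1"` (six groups, between subjects) or `"exp2"`
#'   (one subject, entropy-graded multi-session).
#' @param n_per_group Subjects per group (exp1).
#' @param n_sessions Sessions (exp2).
#' @param n_prev_range History lengths for predictor analyses.
#' @param entropy_n_prev History length for the block-wise entropy fits
#'   (default 3, where the slope-1 sigmoid is well covered).
#' @param window Analysis trial window.
#' @param seed RNG seed (mandatory: simulation is involved).
#' @param out_dir Output directory.
#' @param sigma,p_error Noise model settings.
#' @param rate Learning rate across blocks (exp1; exp2 runs flat).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = c("exp1", "exp2"),
                            n_per_group = 8L, n_sessions = 48L,
                            n_prev_range = 1:4, entropy_n_prev = 3L,
                            window = c(442, 1078),
                            seed = 1L, out_dir = tempfile("srtlearn_run_"),
                            sigma = 0.25, p_error = 0.03, rate = 0.15) {
  experiment <- match.arg(experiment)
  if (is.null(seed)) stop("`seed` is mandatory for simulation runs",
                          call. = FALSE)
  stopifnot(entropy_n_prev %in% n_prev_range)
  structure(list(experiment = experiment, n_per_group = n_per_group,
                 n_sessions = n_sessions, n_prev_range = n_prev_range,
                 entropy_n_prev = as.integer(entropy_n_prev),
                 window = window, seed = as.integer(seed),
                 out_dir = out_dir, sigma = sigma, p_error = p_error,
                 rate = rate),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulation (or ingest), predictor computation, model comparison and
#' block-wise trajectories, written as CSV/JSON files plus a markdown
#' report. Identical configuration and seed give byte-identical numeric
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param trials Optional pre-loaded trial tibble (e.g. from
#'   [ingest_trials()]); when `NULL` the experiment is simulated.
#' @return Invisibly, a list with the main tables and output paths.
#' @export
run_pipeline <- function(config, trials = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    stop("cannot create output directory ", config$out_dir, call. = FALSE)
  }
  out <- function(f) file.path(config$out_dir, f)
  yaml::write_yaml(unclass(config), out("config.yaml"))
  noise <- noise_model(sigma = config$sigma, p_error = config$p_error)

  if (config$experiment == "exp1") {
    specs <- sequence_presets()
    if (is.null(trials)) {
      trials <- simulate_experiment1(n_per_group = config$n_per_group,
                                     presets = specs, seed = config$seed,
                                     noise = noise, rate = config$rate)
    }
    spec_col <- "group"; unit_col <- "subject_id"
    family <- NULL
  } else {
    family <- gen_entropy_graded_family(n_sequences = config$n_sessions,
                                        je_range = c(1.5, 6.6),
                                        n_prev = config$entropy_n_prev)
    specs <- stats::setNames(family$spec,
                             vapply(family$spec, `[[`, "", "name"))
    if (is.null(trials)) {
      trials <- simulate_experiment2(n_sessions = config$n_sessions,
                                     family = family, seed = config$seed,
                                     noise = noise)
    }
    spec_col <- "label"; unit_col <- "session"
  }
  readr::write_csv(trials, out("trials.csv"))

  # predictor tables of every sequence, one CSV + JSON sidecar each
  for (nm in names(specs)) {
    pt <- nominal_predictor_table(specs[[nm]],
                                  n_prev = min(config$n_prev_range))
    write_predictor_table(pt, out(sprintf("predictors_%s.csv", nm)))
  }

  block_curve <- median_rt(trials, group_by = c(spec_col, unit_col, "block"),
                           mean_of_medians = FALSE)
  readr::write_csv(block_curve, out("block_medians.csv"))

  with_pred <- attach_predictors(trials, specs, spec_col = spec_col,
                                 unit_col = unit_col,
                                 n_prev_range = config$n_prev_range)
  trial_grid <- compare_predictors_trialwise(with_pred,
                                             n_prev_range = config$n_prev_range,
                                             window = config$window)
  readr::write_csv(trial_grid, out("grid_trialwise.csv"))

  units <- unit_entropy_table(trials, specs, spec_col = spec_col,
                              unit_col = unit_col,
                              n_prev_range = config$n_prev_range,
                              window = config$window)
  session_grid <- compare_predictors_sessionwise(units,
                                                 n_prev_range = config$n_prev_range)
  readr::write_csv(session_grid, out("grid_sessionwise.csv"))

  je_per_unit <- units |>
    dplyr::select(dplyr::all_of(unit_col),
                  je = dplyr::all_of(paste0("je_", config$entropy_n_prev)))
  trajectory <- blockwise_sigmoid(trials, je_per_unit, unit_col = unit_col)
  readr::write_csv(trajectory, out("blockwise_trajectory.csv"))

  report <- c(
    "# srtlearn pipeline report", "",
    sprintf("experiment: %s; seed: %d; trials: %d", config$experiment,
            config$seed, nrow(trials)),
    "",
    "## Best comparison-grid cells",
    sprintf("- trial-wise: %s + %s (n_prev = %d), R^2 = %.3f",
            best_cell(trial_grid)$predictor, best_cell(trial_grid)$fn,
            best_cell(trial_grid)$n_prev, best_cell(trial_grid)$r_squared),
    sprintf("- session-wise: %s + %s (n_prev = %d), R^2 = %.3f",
            best_cell(session_grid)$predictor, best_cell(session_grid)$fn,
            best_cell(session_grid)$n_prev,
            best_cell(session_grid)$r_squared),
    "",
    "## Block-wise sigmoid trajectory (slope fixed at 1)",
    sprintf("- Xhalf: %.3f -> %.3f bits across fitted blocks",
            utils::head(stats::na.omit(trajectory$xhalf), 1),
            utils::tail(stats::na.omit(trajectory$xhalf), 1)),
    sprintf("- Ymin: %.1f -> %.1f ms",
            utils::head(stats::na.omit(trajectory$ymin), 1),
            utils::tail(stats::na.omit(trajectory$ymin), 1)),
    sprintf("- Ymax: %.1f -> %.1f ms",
            utils::head(stats::na.omit(trajectory$ymax), 1),
            utils::tail(stats::na.omit(trajectory$ymax), 1)))
  writeLines(report, out("report.md"))

  invisible(list(trials = trials, trial_grid = trial_grid,
                 session_grid = session_grid, trajectory = trajectory,
                 units = units, family = family,
                 out_dir = config$out_dir))
}
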