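# CSV and configuration I/O.

trial_col_types <- readr::cols(
  participant = readr::col_character(),
  group = readr::col_character(),
  block = readr::col_integer(),
  trial = readr::col_integer(),
  stimulus = readr::col_integer(),
  transition_prob = readr::col_double(),
  rt = readr::col_double(),
  correct = readr::col_logical(),
  valid = readr::col_logical(),
  .default = readr::col_guess()
)

#' Read a trial-level CSV
#'
#' Header-validated reader for the trial table format (`participant`,
#' `group`, `block`, `trial`, `stimulus`, `transition_prob`, `rt`,
#' `correct`, `valid`; only the first five are required). Unknown columns
#' are kept with a warning.
#'
#' @param path File path.
#' @return A trial-level tibble.
#' @export
read_trial_csv <- function(path) {
  header <- names(readr::read_csv(path,
    n_max = 0, show_col_types = FALSE, progress = FALSE
  ))
  spec <- readr::cols(.default = readr::col_guess())
  spec$cols <- trial_col_types$cols[intersect(names(trial_col_types$cols), header)]
  tbl <- readr::read_csv(path, col_types = spec, progress = FALSE)
  missing_cols <- setdiff(trial_required_cols, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Trial CSV is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  known <- c(
    "participant", "group", "block", "trial", "stimulus",
    "transition_prob", "rt", "correct", "valid", "trial_rank"
  )
  extra <- setdiff(names(tbl), known)
  if (length(extra) > 0) {
    warn(paste("Unknown column(s) kept as-is:", paste(extra, collapse = ", ")))
  }
  tbl
}

#' Write a trial-level CSV
#'
#' RTs are serialized in ms with at most 3 decimals; the round trip through
#' [read_trial_csv()] is lossless at that precision.
#'
#' @param table A trial-level tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(table, path) {
  tbl <- dplyr::mutate(table, rt = round(.data$rt, 3))
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param design An [srt_design()] (used when `groups` is `NULL` and for
#'   single-design runs), or `NULL`.
#' @param simulation An [sim_config()] to simulate a cohort, or `NULL` to
#'   analyse `input_trials`.
#' @param groups Optional named list of group specifications as produced by
#'   [cohort_presets()]; defaults to the presets when simulating.
#' @param input_trials Optional path to a trial CSV (used when `simulation`
#'   is `NULL`).
#' @param input_posttest Optional path to a posttest CSV.
#' @param trim_k SD multiplier for [trim_rts()] (default 2.5).
#' @param window Offline window size (default 12).
#' @param online_blocks,offline_from_blocks Aggregation switches of
#'   [learning_summary()].
#' @param alpha Significance level for the inference stage (default 0.05).
#' @param seed Master seed.
#' @return A list of class `srt_pipeline_config`.
#' @export
srt_config <- function(design = NULL, simulation = sim_config(),
                       groups = NULL, input_trials = NULL,
                       input_posttest = NULL, trim_k = 2.5, window = 12L,
                       online_blocks = 1:4, offline_from_blocks = 1:3,
                       alpha = 0.05, seed = 1L) {
  structure(
    list(
      design = design, simulation = simulation, groups = groups,
      input_trials = input_trials, input_posttest = input_posttest,
      trim_k = trim_k, window = as.integer(window),
      online_blocks = online_blocks,
      offline_from_blocks = offline_from_blocks,
      alpha = alpha, seed = as.integer(seed)
    ),
    class = "srt_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `design` (fields of [srt_design()]; `matrix`
#' may be a 16-number row-major vector), `simulation` (fields of
#' [sim_config()]), `trim_k`, `window`, `online_blocks`,
#' `offline_from_blocks`, `alpha`, `seed`, `input_trials`,
#' `input_posttest`.
#'
#' @param path YAML file path.
#' @return An `srt_pipeline_config`.
#' @export
read_srt_config <- function(path) {
  raw <- yaml::read_yaml(path)
  design <- NULL
  if (!is.null(raw$design)) {
    dargs <- raw$design
    if (!is.null(dargs$matrix)) {
      dargs$matrix <- as_transition_matrix(
        matrix(as.numeric(unlist(dargs$matrix)), 4, 4, byrow = TRUE)
      )
    }
    if (!is.null(dargs$fixed_sequence) &&
      !identical(dargs$fixed_sequence, "auto")) {
      dargs$fixed_sequence <- as.integer(unlist(dargs$fixed_sequence))
    }
    design <- do.call(srt_design, dargs)
  }
  simulation <- NULL
  if (!is.null(raw$simulation)) {
    sargs <- raw$simulation
    if (!is.null(sargs$prob_sensitivity)) {
      sargs$prob_sensitivity <- unlist(sargs$prob_sensitivity)
    }
    simulation <- do.call(sim_config, sargs)
  }
  srt_config(
    design = design, simulation = simulation,
    input_trials = raw$input_trials, input_posttest = raw$input_posttest,
    trim_k = raw$trim_k %||% 2.5, window = raw$window %||% 12L,
    online_blocks = raw$online_blocks %||% 1:4,
    offline_from_blocks = raw$offline_from_blocks %||% 1:3,
    alpha = raw$alpha %||% 0.05, seed = raw$seed %||% 1L
  )
}
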