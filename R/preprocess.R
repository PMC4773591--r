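# Trial-table validation and the standard-deviation outlier trimming rule.

trial_required_cols <- c("participant", "block", "trial", "stimulus", "rt")

#' Validate a trial table
#'
#' Checks structural integrity of a trial-level table: required columns,
#' duplicate `(participant, block, trial)` keys, trial indices contiguous
#' from 1 within each block, stimulus range, and finite positive RTs.
#'
#' @param table A trial-level data frame.
#' @param n_stimuli Expected number of distinct stimuli (default 4).
#' @return A tibble of issues with columns `issue`, `detail`, `n`; zero rows
#'   means the table is clean.
#' @export
validate_trial_table <- function(table, n_stimuli = 4L) {
  missing_cols <- setdiff(trial_required_cols, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Trial table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  issues <- list()
  add <- function(issue, detail, n) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      issue = issue, detail = detail, n = as.integer(n)
    )
  }
  dup <- dplyr::count(
    table, .data$participant, .data$block, .data$trial
  )
  dup <- dplyr::filter(dup, .data$n > 1)
  if (nrow(dup) > 0) {
    add(
      "duplicate_key",
      paste0(
        "e.g. (", dup$participant[1], ", block ", dup$block[1],
        ", trial ", dup$trial[1], ")"
      ),
      nrow(dup)
    )
  }
  gaps <- table |>
    dplyr::group_by(.data$participant, .data$block) |>
    dplyr::summarise(
      contiguous = identical(as.integer(sort(.data$trial)), seq_len(dplyr::n())),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$contiguous)
  if (nrow(gaps) > 0) {
    add(
      "noncontiguous_trials",
      paste0("e.g. ", gaps$participant[1], " block ", gaps$block[1]),
      nrow(gaps)
    )
  }
  bad_stim <- !(table$stimulus %in% seq_len(n_stimuli))
  if (any(bad_stim)) {
    add(
      "stimulus_out_of_range",
      paste0("values outside 1..", n_stimuli), sum(bad_stim)
    )
  }
  bad_rt <- !is.finite(table$rt) | table$rt <= 0
  if (any(bad_rt)) {
    add("nonpositive_rt", "RTs must be finite and > 0", sum(bad_rt))
  }
  if (length(issues) == 0) {
    tibble::tibble(issue = character(), detail = character(), n = integer())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Trim outlying RTs by the k-standard-deviation rule
#'
#' Within each `(participant, block)` cell, computes the mean and standard
#' deviation of all RTs once (single pass, non-iterative) and marks invalid
#' any RT strictly outside `mean +/- k * SD`; boundary values are retained.
#' Cells with fewer than two trials are left untrimmed with a warning. A
#' removal fraction above 10% in any cell triggers a data-quality warning.
#' The function refuses to run on a table that already carries a `valid`
#' column, so the pipeline never re-trims.
#'
#' @param table A trial-level data frame (see [validate_trial_table()]).
#' @param k Positive SD multiplier (default 2.5).
#' @param exclude_errors If `TRUE` and the table has a `correct` column,
#'   incorrect-response trials are marked invalid before the trimming
#'   statistics are computed. Default `FALSE`.
#' @return `table` with a logical `valid` column added, and the per-cell
#'   trimming report attached as attribute `"trim_report"` (see
#'   [trim_report()]).
#' @examples
#' tt <- tibble::tibble(
#'   participant = "p1", block = 1L, trial = 1:100, stimulus = 1L,
#'   rt = c(rnorm(99, 500, 50), 5000)
#' )
#' trimmed <- trim_rts(tt)
#' trim_report(trimmed)
#' @export
trim_rts <- function(table, k = 2.5, exclude_errors = FALSE) {
  if (k <= 0) abort("`k` must be > 0.")
  if ("valid" %in% names(table)) {
    abort(paste0(
      "Table already has a `valid` column: trimming is single-pass ",
      "and must not be applied twice."
    ))
  }
  tbl <- dplyr::as_tibble(table)
  considered <- rep(TRUE, nrow(tbl))
  if (exclude_errors && "correct" %in% names(tbl)) {
    considered <- considered & (tbl$correct %in% TRUE)
  }
  tbl$.considered <- considered
  tbl <- tbl |>
    dplyr::group_by(.data$participant, .data$block) |>
    dplyr::mutate(
      .m = mean(.data$rt[.data$.considered]),
      .s = sd(.data$rt[.data$.considered]),
      .n_cell = sum(.data$.considered)
    ) |>
    dplyr::ungroup()
  small <- tbl$.n_cell < 2
  if (any(small)) {
    warn("Some (participant, block) cells have < 2 trials; left untrimmed.")
  }
  within_bounds <- small |
    (tbl$rt >= tbl$.m - k * tbl$.s & tbl$rt <= tbl$.m + k * tbl$.s)
  tbl$valid <- tbl$.considered & within_bounds
  report <- tbl |>
    dplyr::group_by(.data$participant, .data$block) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_removed = sum(!.data$valid),
      frac_removed = .data$n_removed / .data$n_trials,
      .groups = "drop"
    )
  if (any(report$frac_removed > 0.10)) {
    warn(sprintf(
      "Data quality: %d cell(s) lost more than 10%% of trials to trimming.",
      sum(report$frac_removed > 0.10)
    ))
  }
  tbl <- dplyr::select(tbl, -".m", -".s", -".n_cell", -".considered")
  attr(tbl, "trim_report") <- report
  tbl
}

#' Retrieve the trimming report of a trimmed table
#'
#' @param table A table returned by [trim_rts()].
#' @return The per-cell report tibble (`participant`, `block`, `n_trials`,
#'   `n_removed`, `frac_removed`).
#' @export
trim_report <- function(table) {
  rep <- attr(table, "trim_report")
  if (is.null(rep)) abort("No trimming report: was the table trimmed with `trim_rts()`?")
  rep
}
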