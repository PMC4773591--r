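# The learning decomposition: block means, overall learning contrasts,
# online (within-block regression), offline (break windows), corrected
# offline, and probability-stratified variants.

valid_col <- function(table) {
  if ("valid" %in% names(table)) table$valid %in% TRUE else rep(TRUE, nrow(table))
}

index_col <- function(table) {
  if ("trial_rank" %in% names(table)) table$trial_rank else table$trial
}

#' Per-block mean reaction times
#'
#' Arithmetic mean of valid RTs per `(participant, block)`. Group-level
#' means, where needed, are unweighted means of these participant means.
#'
#' @param table A trial-level table, normally trimmed with [trim_rts()]
#'   (rows with `valid == FALSE` are excluded; a table without a `valid`
#'   column is used in full).
#' @return A tibble with `participant` (`group` if present), `block`,
#'   `mean_rt`, `n_valid`. Cells with no valid trials get `NA` means.
#' @export
block_means <- function(table) {
  grp <- intersect(c("participant", "group", "block"), names(table))
  table$`.valid` <- valid_col(table)
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean_rt = ifelse(any(.data$.valid),
        mean(.data$rt[.data$.valid]), NA_real_
      ),
      n_valid = sum(.data$.valid),
      .groups = "drop"
    )
  if (any(is.na(out$mean_rt))) {
    inform("Some (participant, block) cells have no valid trials; means are NA.")
  }
  out
}

#' Overall learning contrasts from block means
#'
#' `learning_b1_b4 = mean(B1) - mean(B4)` (positive = improvement over the
#' learning blocks) and `interference_b5_b4 = mean(B5) - mean(B4)` (positive
#' = slowing when the random block is introduced).
#'
#' @param bm A block-means tibble from [block_means()].
#' @return A tibble with one row per participant: `learning_b1_b4`,
#'   `interference_b5_b4` (`NA` when a needed block mean is missing).
#' @export
overall_learning <- function(bm) {
  grp <- intersect(c("participant", "group"), names(bm))
  bm |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      learning_b1_b4 = pick_block(.data$block, .data$mean_rt, 1L) -
        pick_block(.data$block, .data$mean_rt, 4L),
      interference_b5_b4 = pick_block(.data$block, .data$mean_rt, 5L) -
        pick_block(.data$block, .data$mean_rt, 4L),
      .groups = "drop"
    )
}

pick_block <- function(block, value, which) {
  v <- value[block == which]
  if (length(v) == 1) v else NA_real_
}

#' Online learning within one block
#'
#' Ordinary least-squares regression of RT on the within-block trial index
#' over the valid trials; online learning is the fitted RT change over the
#' whole block, sign-flipped so that improvement is positive:
#' `-slope * (n_trials - 1)`. Negative values indicate within-block slowing.
#'
#' @param rt Numeric RTs (valid trials only).
#' @param index Within-block trial indices for those RTs.
#' @param n_trials Total span of the block in trials (default
#'   `max(index)`); the fitted change is evaluated over `n_trials - 1`
#'   index steps.
#' @return Online learning in ms, or `NA` if fewer than 3 trials.
#' @examples
#' online_learning(600 - 0.5 * (0:119), 1:120) # 59.5
#' @export
online_learning <- function(rt, index, n_trials = max(index)) {
  if (length(rt) < 3) {
    inform("Fewer than 3 valid trials: online learning is NA.")
    return(NA_real_)
  }
  slope <- coef(lm(rt ~ index))[["index"]]
  -slope * (n_trials - 1)
}

#' Online learning for every (participant, block) cell
#'
#' @param table A (trimmed) trial table. If the table carries a
#'   `trial_rank` column (see [stratify_by_probability()]) the regression
#'   uses the ranks and the per-cell rank span; otherwise it uses `trial`
#'   and `n_trials`.
#' @param n_trials Block length in trials (default: the maximum trial index
#'   observed in the table).
#' @return A tibble `participant` (`group`), `block`, `online`.
#' @export
online_by_block <- function(table, n_trials = NULL) {
  stratified <- "trial_rank" %in% names(table)
  if (is.null(n_trials)) n_trials <- max(table$trial)
  grp <- intersect(c("participant", "group", "block"), names(table))
  table$.valid <- valid_col(table)
  table$.idx <- index_col(table)
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      online = online_learning(
        .data$rt[.data$.valid], .data$.idx[.data$.valid],
        n_trials = if (stratified) max(.data$.idx) else n_trials
      ),
      .groups = "drop"
    )
}

#' Offline learning across one break
#'
#' Mean of the last `window` valid trials of the earlier block minus the
#' mean of the first `window` valid trials of the later block; positive
#' values are post-break improvement.
#'
#' @param rt_before,rt_after Valid RTs of the two blocks, in trial order.
#' @param window Window size in trials (default 12, one repetition of the
#'   fixed sequence).
#' @return Offline learning in ms, or `NA` if either block has fewer than
#'   `window` valid trials.
#' @export
offline_learning <- function(rt_before, rt_after, window = 12L) {
  if (length(rt_before) < window || length(rt_after) < window) {
    inform("Fewer valid trials than the window size: offline learning is NA.")
    return(NA_real_)
  }
  mean(tail(rt_before, window)) - mean(head(rt_after, window))
}

#' Offline learning for every between-block break
#'
#' @param table A (trimmed) trial table; windows are taken over valid trials
#'   in trial order (rank order if stratified).
#' @param window Window size (default 12).
#' @return A tibble `participant` (`group`), `from_block`, `to_block`,
#'   `offline` with one row per consecutive block pair.
#' @export
offline_by_break <- function(table, window = 12L) {
  grp <- intersect(c("participant", "group"), names(table))
  table$.valid <- valid_col(table)
  table$.idx <- index_col(table)
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(~ {
      blocks <- sort(unique(.x$block))
      pairs <- blocks[-length(blocks)]
      purrr::map_dfr(pairs, function(b) {
        nb <- blocks[which(blocks == b) + 1L]
        before <- .x[.x$block == b & .x$.valid, ]
        after <- .x[.x$block == nb & .x$.valid, ]
        tibble::tibble(
          from_block = b, to_block = nb,
          offline = offline_learning(
            before$rt[order(before$.idx)],
            after$rt[order(after$.idx)],
            window = window
          )
        )
      })
    }) |>
    dplyr::ungroup()
}

#' Corrected offline learning
#'
#' Offline learning minus any within-block RT deterioration of the previous
#' block: if `online_prev < 0` (the block ended slower than it began),
#' `corrected = offline - |online_prev|`; otherwise the offline value is
#' unchanged. The corrected value measures post-break improvement over the
#' pre-break best level, separating offline learning from dissipating
#' fatigue.
#'
#' @param offline Offline learning value(s), ms.
#' @param online_prev Online learning of the preceding block, ms
#'   (improvement positive).
#' @return Corrected offline learning (vectorized).
#' @examples
#' corrected_offline_learning(30, -20) # 10
#' corrected_offline_learning(30, 15) # 30
#' @export
corrected_offline_learning <- function(offline, online_prev) {
  offline + pmin(online_prev, 0)
}

#' Restrict a probabilistic-design table to given transition probabilities
#'
#' Keeps trials whose annotated transition probability is in `probs`
#' (block-initial trials, which have no predecessor, are always dropped) and
#' re-expresses the within-block trial index as the rank among retained
#' trials (column `trial_rank`), so that downstream regressions and
#' last/first windows operate on the retained trials.
#'
#' @param table A trial table with a `transition_prob` column carrying
#'   Markov annotations (probabilistic designs only).
#' @param probs Probabilities to retain (default `c(0.3, 0.6)`, the
#'   learnable transitions).
#' @return The filtered table with an added `trial_rank` column.
#' @export
stratify_by_probability <- function(table, probs = c(0.3, 0.6)) {
  if (!"transition_prob" %in% names(table) ||
    all(is.na(table$transition_prob))) {
    abort(paste0(
      "Probability stratification needs Markov-annotated transition ",
      "probabilities; fixed-design tables cannot be stratified."
    ))
  }
  if (length(probs) == 0) {
    warn("Empty probability set: returning an empty table.")
    out <- dplyr::filter(table, FALSE)
    out$trial_rank <- integer(0)
    return(out)
  }
  table |>
    dplyr::filter(.data$transition_prob %in% probs) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      intersect(c("participant", "block"), names(table))
    ))) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(trial_rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Per-participant learning summary
#'
#' Assembles the full learning decomposition for each participant: block
#' means and overall contrasts, aggregate online learning (mean over
#' `online_blocks`), aggregate offline and corrected offline learning (mean
#' over the breaks leaving `offline_from_blocks`), and their difference.
#' Breaks and blocks touching the random block are excluded from the
#' aggregates by default but remain available from [online_by_block()] and
#' [offline_by_break()].
#'
#' @param table A trimmed trial table (one or many participants).
#' @param window Offline window size (default 12).
#' @param n_trials Block length (default max observed trial index).
#' @param online_blocks Blocks entering the online aggregate (default 1:4).
#' @param offline_from_blocks Earlier blocks of the breaks entering the
#'   offline aggregates (default 1:3, i.e. breaks 1-2, 2-3, 3-4).
#' @return A tibble with one row per participant: `learning_b1_b4`,
#'   `interference_b5_b4`, `online`, `offline`, `corrected_offline`,
#'   `offline_minus_online`.
#' @export
learning_summary <- function(table, window = 12L, n_trials = NULL,
                             online_blocks = 1:4,
                             offline_from_blocks = 1:3) {
  grp <- intersect(c("participant", "group"), names(table))
  ov <- overall_learning(block_means(table))
  onl <- online_by_block(table, n_trials = n_trials)
  off <- offline_by_break(table, window = window)
  onl_prev <- dplyr::select(onl,
    dplyr::all_of(grp),
    from_block = "block", online_prev = "online"
  )
  off <- off |>
    dplyr::left_join(onl_prev, by = c(grp, "from_block")) |>
    dplyr::mutate(
      corrected = corrected_offline_learning(.data$offline, .data$online_prev)
    )
  onl_agg <- onl |>
    dplyr::filter(.data$block %in% online_blocks) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(online = mean(.data$online), .groups = "drop")
  off_agg <- off |>
    dplyr::filter(.data$from_block %in% offline_from_blocks) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      offline = mean(.data$offline),
      corrected_offline = mean(.data$corrected),
      .groups = "drop"
    )
  ov |>
    dplyr::left_join(onl_agg, by = grp) |>
    dplyr::left_join(off_agg, by = grp) |>
    dplyr::mutate(offline_minus_online = .data$offline - .data$online)
}
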