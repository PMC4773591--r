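# Scoring of the declarative posttests: recognition endorsement and free
# recall of three-element chunks, with chance correction.

#' Score the recognition task
#'
#' The recognition score is the number of correct chunks the participant
#' endorsed, normalized by the number of correct chunks in the answer key
#' (four in the standard design).
#'
#' @param endorsed Character vector of endorsed chunks.
#' @param key A [recognition_key()] tibble (`chunk`, `correct`).
#' @return The recognition score in `[0, 1]`.
#' @examples
#' d <- srt_design("fixed", seed = 7)
#' key <- recognition_key(d, seed = 1)
#' score_recognition(key$chunk[key$correct], key) # 1
#' @export
score_recognition <- function(endorsed, key) {
  endorsed <- unique(as.character(endorsed))
  if (!all(endorsed %in% key$chunk)) {
    abort("Endorsed chunk(s) not among the presented chunks.")
  }
  length(intersect(endorsed, key$chunk[key$correct])) / sum(key$correct)
}

#' Score free recall of the sequence
#'
#' Tokenizes the recalled material, extracts all overlapping
#' `chunk_length`-element windows, and counts the distinct windows that
#' belong to the design's true chunk set ([enumerate_chunks()]; internal
#' transition probability >= 0.3 for probabilistic designs). The count is
#' normalized by the size of the true chunk set: 12 for the standard fixed
#' design and 16 for the probabilistic design.
#'
#' A chunk recalled twice counts once. Note that a linearly written 12-item
#' recall exposes at most 10 of the 12 cyclic windows of a fixed sequence,
#' so perfect linear recall scores 10/12; recall supplied as a chunk list is
#' not subject to this ceiling.
#'
#' @param recalled Either an integer stimulus vector (a linearly written
#'   sequence) or a character vector of chunk strings.
#' @param design An [srt_design()].
#' @param chunk_length Chunk length (default 3).
#' @return A list with `recall_count` and `recall_percent`.
#' @export
score_recall <- function(recalled, design, chunk_length = 3L) {
  true <- suppressWarnings(enumerate_chunks(design, chunk_length))
  if (is.character(recalled)) {
    windows <- unique(unlist(lapply(recalled, function(ch) {
      chunk_windows(chunk_tokens(ch), chunk_length)
    })))
  } else {
    windows <- unique(chunk_windows(as.integer(recalled), chunk_length))
  }
  if (length(windows) == 0) {
    warn("Recalled material shorter than the chunk length: count is 0.")
  }
  count <- length(intersect(windows, true))
  list(recall_count = count, recall_percent = count / length(true))
}

#' Chance-correct a recall percentage
#'
#' Subtracts the design-specific analytic chance level
#' ([recall_chance_level()]) from the recall percentage; the corrected value
#' may be negative.
#'
#' @param recall_percent Recall fraction(s) in `[0, 1]`.
#' @param design An [srt_design()] or `"fixed"`/`"probabilistic"`.
#' @param chunk_length Chunk length (default 3).
#' @return Corrected recall fraction(s).
#' @examples
#' correct_for_chance(0.1875, "fixed") # 0
#' @export
correct_for_chance <- function(recall_percent, design, chunk_length = 3L) {
  recall_percent - recall_chance_level(design, chunk_length)
}

#' Score a long posttest response table
#'
#' Applies [score_recognition()], [score_recall()] and
#' [correct_for_chance()] to each participant of a long posttest table in
#' the format produced by [simulate_posttest()] / [simulate_cohort()]:
#' one row per response with columns `participant`, `task`
#' (`"recall"`/`"recognition"`), `chunk`, `endorsed`, `correct`.
#'
#' @param posttest The long posttest tibble.
#' @param design The [srt_design()] the participants performed.
#' @return A tibble with one row per participant: `recognition_score`,
#'   `recall_count`, `recall_percent`, `recall_percent_corrected`.
#' @export
score_posttest <- function(posttest, design) {
  grp <- intersect(c("participant", "group"), names(posttest))
  posttest |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(~ {
      rec <- .x[.x$task == "recognition", ]
      rcl <- .x[.x$task == "recall", ]
      recog <- if (nrow(rec) > 0) {
        sum(rec$endorsed & rec$correct) / sum(rec$correct)
      } else {
        NA_real_
      }
      recall <- score_recall(rcl$chunk, design)
      tibble::tibble(
        recognition_score = recog,
        recall_count = recall$recall_count,
        recall_percent = recall$recall_percent,
        recall_percent_corrected =
          correct_for_chance(recall$recall_percent, design)
      )
    }) |>
    dplyr::ungroup()
}
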