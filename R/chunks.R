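# Chunk enumeration and analytic chance levels for the declarative posttests.

chunk_str <- function(x) paste(as.integer(x), collapse = "")

chunk_tokens <- function(chunk) as.integer(strsplit(chunk, "")[[1]])

# Overlapping k-windows of a stimulus vector, as chunk strings.
chunk_windows <- function(stimuli, k, cyclic = FALSE) {
  stimuli <- as.integer(stimuli)
  n <- length(stimuli)
  if (cyclic) {
    ext <- c(stimuli, stimuli[seq_len(k - 1)])
    starts <- seq_len(n)
  } else {
    if (n < k) return(character(0))
    ext <- stimuli
    starts <- seq_len(n - k + 1)
  }
  vapply(starts, function(i) chunk_str(ext[i:(i + k - 1)]), character(1))
}

all_tuples <- function(k, n_stimuli = 4L) {
  grids <- rev(replicate(k, seq_len(n_stimuli), simplify = FALSE))
  g <- do.call(expand.grid, grids)[, k:1, drop = FALSE]
  apply(g, 1, chunk_str)
}

#' Enumerate the learnable chunks of a design
#'
#' For a fixed design, the distinct overlapping `chunk_length`-windows of the
#' cyclic sequence (12 three-element chunks for the standard 12-item
#' sequence). For a probabilistic design, all stimulus tuples whose every
#' internal transition has probability at least `min_prob` under the design's
#' matrix (16 three-element chunks at `min_prob = 0.3` under the default
#' matrix, where each stimulus has two learnable successors).
#'
#' @param design An [srt_design()].
#' @param chunk_length Chunk length (default 3).
#' @param min_prob Minimum internal transition probability for probabilistic
#'   designs (default 0.3, the smaller of the two probabilities participants
#'   learn). Ignored, with a warning, for fixed designs.
#' @return Character vector of chunks, each a string of stimulus digits.
#' @examples
#' length(enumerate_chunks(srt_design("fixed", seed = 7), 3)) # 12
#' length(enumerate_chunks(srt_design("probabilistic"), 3)) # 16
#' @export
enumerate_chunks <- function(design, chunk_length = 3L, min_prob = 0.3) {
  stopifnot(inherits(design, "srt_design"))
  chunk_length <- as.integer(chunk_length)
  if (chunk_length < 1) abort("`chunk_length` must be >= 1.")
  if (chunk_length == 1L) {
    return(as.character(seq_len(design$n_stimuli)))
  }
  if (design$sequence_type == "fixed") {
    if (!missing(min_prob)) {
      warn("`min_prob` is ignored for fixed designs.")
    }
    return(unique(chunk_windows(design$fixed_sequence, chunk_length,
      cyclic = TRUE
    )))
  }
  m <- design$matrix
  tuples <- all_tuples(chunk_length, design$n_stimuli)
  keep <- vapply(tuples, function(ch) {
    s <- chunk_tokens(ch)
    all(m[cbind(s[-length(s)], s[-1])] >= min_prob)
  }, logical(1))
  unname(tuples[keep])
}

#' Analytic chance level for chunk recall
#'
#' The probability of producing a correct `chunk_length`-element chunk by
#' guessing, under the conditional-guessing model: the first element is
#' given; for a fixed sequence the second element is guessed correctly with
#' probability 0.75 (each stimulus has three distinct successors among the
#' four possible guesses) and each later element with probability 0.25 (each
#' longer context has a unique continuation); for a probabilistic sequence
#' each subsequent element is guessed correctly with probability 0.5 (two
#' learnable successors per stimulus, guessed among... see Details).
#'
#' @details For the standard three-element chunk this gives
#' `0.75 * 0.25 = 18.75%` (fixed) and `0.5 * 0.5 = 25%` (probabilistic).
#' Equivalently, these are the fractions of learnable chunks among all
#' `4^3 = 64` stimulus triples: 12/64 and 16/64.
#'
#' @param design An [srt_design()], or the strings `"fixed"` /
#'   `"probabilistic"`.
#' @param chunk_length Chunk length (default 3; must be >= 2).
#' @return A probability.
#' @examples
#' recall_chance_level("fixed") # 0.1875
#' recall_chance_level("probabilistic") # 0.25
#' @export
recall_chance_level <- function(design, chunk_length = 3L) {
  type <- if (inherits(design, "srt_design")) design$sequence_type else design
  if (!type %in% c("fixed", "probabilistic")) {
    abort("`design` must be fixed or probabilistic.")
  }
  chunk_length <- as.integer(chunk_length)
  if (chunk_length < 2) abort("`chunk_length` must be >= 2.")
  if (type == "fixed") {
    0.75 * 0.25^(chunk_length - 2L)
  } else {
    0.5^(chunk_length - 1L)
  }
}

#' Analytic chance level for the recognition score
#'
#' Expected recognition score when each presented chunk is endorsed
#' independently with probability 1/2: the expected number of endorsed
#' correct chunks is `n_correct / 2`, and dividing by `n_correct` gives 0.5
#' regardless of the counts.
#'
#' @param n_presented Number of presented chunks (default 8).
#' @param n_correct Number of correct chunks among them (default 4; the
#'   normalizing denominator of the score).
#' @return The expected score, 0.5.
#' @export
recognition_chance_level <- function(n_presented = 8L, n_correct = 4L) {
  if (n_correct <= 0 || n_correct > n_presented) {
    abort("Require 0 < n_correct <= n_presented.")
  }
  (n_correct * 0.5) / n_correct
}

#' Construct a recognition answer key for a design
#'
#' Samples the eight-item recognition set of the posttest: four three-element
#' and four four-element chunks, two of each drawn from the design's true
#' chunk set and two of each foils (tuples outside it).
#'
#' @param design An [srt_design()].
#' @param seed Integer seed.
#' @return A tibble with columns `chunk`, `length`, `correct`.
#' @export
recognition_key <- function(design, seed = 1L) {
  with_local_seed(seed, {
    rows <- lapply(c(3L, 4L), function(k) {
      true <- suppressWarnings(enumerate_chunks(design, k))
      foils <- setdiff(all_tuples(k, design$n_stimuli), true)
      tibble::tibble(
        chunk = c(sample(true, 2L), sample(foils, 2L)),
        length = k,
        correct = c(TRUE, TRUE, FALSE, FALSE)
      )
    })
    dplyr::bind_rows(rows)
  })
}
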