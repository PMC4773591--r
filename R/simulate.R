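# Synthetic cohort generation: trial-level RTs with known online/offline
# learning parameters, plus simulated posttests.

#' Simulation configuration
#'
#' Parameters of the phenomenological RT generator. The trial-level model is
#'
#' `RT = baseline_rt - general_practice_rate * (block - 1) - K(block, trial)
#'       + prob_sensitivity[p(trial)] + ex-Gaussian noise`,
#'
#' where `K` is the sequence-knowledge term (in ms of RT reduction). Within a
#' sequence block `K` changes linearly so that the trend RT change across the
#' whole block equals `online_rate` (negative = within-block improvement,
#' positive = within-block slowing/fatigue). At a rest break between two
#' sequence blocks `K` jumps so that the trend-level difference between the
#' mean of the last `offline_window` trials before the break and the mean of
#' the first `offline_window` trials after it equals exactly `offline_gain`:
#' the configured gain is the quantity the standard window-based offline
#' metric measures. On random-role blocks `K` is withheld from RT but not
#' destroyed; the next sequence block resumes from the last sequence block's
#' level plus one `offline_gain`.
#'
#' @param baseline_rt Baseline RT (ms) at the start of block 1.
#' @param online_rate Signed trend RT change (ms) across one full sequence
#'   block; negative values are within-block improvement.
#' @param offline_gain RT improvement (ms) measured between the last/first
#'   `offline_window` trials across each sequence-to-sequence break.
#' @param general_practice_rate Sequence-independent speeding (ms per block).
#' @param prob_sensitivity Named numeric map from transition probability
#'   (`"0.1"`, `"0.3"`, `"0.6"`, `"undefined"`) to an RT offset in ms; used
#'   for probabilistic designs only.
#' @param random_block_reset Logical; if `TRUE` (default) the knowledge term
#'   is withheld on random-role blocks.
#' @param noise_sigma Gaussian noise SD (ms), > 0.
#' @param noise_tau Exponential tail parameter of the ex-Gaussian noise (ms),
#'   >= 0. The noise is centred so its mean is 0.
#' @param outlier_rate Per-trial probability of an attentional-lapse outlier,
#'   in `[0, 0.1)`.
#' @param outlier_scale Outlier RTs are set to `baseline_rt + outlier_scale`.
#' @param declarative_knowledge Probability in `[0, 1]` that a true chunk is
#'   reproduced in the posttest (drives recall and recognition).
#' @param n_participants_per_group Cohort cell size (default 12).
#' @param offline_window Window (trials) defining the offline gain (default
#'   12, matching the offline-learning metric).
#' @param seed Master integer seed.
#' @return A list of class `srt_sim_config`.
#' @export
sim_config <- function(baseline_rt = 500,
                       online_rate = -25,
                       offline_gain = 6,
                       general_practice_rate = 2,
                       prob_sensitivity = c(
                         "0.1" = 22, "0.3" = 12, "0.6" = -12, "undefined" = 0
                       ),
                       random_block_reset = TRUE,
                       noise_sigma = 45,
                       noise_tau = 65,
                       outlier_rate = 0.02,
                       outlier_scale = 1500,
                       declarative_knowledge = 0.2,
                       n_participants_per_group = 12L,
                       offline_window = 12L,
                       seed = 1L) {
  if (noise_sigma <= 0) abort("`noise_sigma` must be > 0.")
  if (noise_tau < 0) abort("`noise_tau` must be >= 0.")
  if (outlier_rate < 0 || outlier_rate >= 0.1) {
    abort("`outlier_rate` must lie in [0, 0.1).")
  }
  if (declarative_knowledge < 0 || declarative_knowledge > 1) {
    abort("`declarative_knowledge` must lie in [0, 1].")
  }
  structure(
    list(
      baseline_rt = baseline_rt, online_rate = online_rate,
      offline_gain = offline_gain,
      general_practice_rate = general_practice_rate,
      prob_sensitivity = prob_sensitivity,
      random_block_reset = isTRUE(random_block_reset),
      noise_sigma = noise_sigma, noise_tau = noise_tau,
      outlier_rate = outlier_rate, outlier_scale = outlier_scale,
      declarative_knowledge = declarative_knowledge,
      n_participants_per_group = as.integer(n_participants_per_group),
      offline_window = as.integer(offline_window),
      seed = as.integer(seed)
    ),
    class = "srt_sim_config"
  )
}

# Knowledge-term trend for one session: returns, per block, the block-start
# level K1 (ms of RT reduction) and whether K is applied to RT in that block.
knowledge_trend <- function(roles, sim, n_pb = 120L) {
  n_blocks <- length(roles)
  treat_as_sequence <- roles == "sequence" | !sim$random_block_reset
  k1 <- numeric(n_blocks)
  applied <- treat_as_sequence
  level <- 0 # block-start K of the current block
  last_seq_end <- 0
  seen_seq <- FALSE
  for (b in seq_len(n_blocks)) {
    if (treat_as_sequence[b]) {
      if (!seen_seq) {
        level <- 0
        seen_seq <- TRUE
      } else {
        level <- last_seq_end + sim$offline_gain
        if (b > 1 && treat_as_sequence[b - 1]) {
          # calibrated jump: the last/first window means differ by offline_gain
          level <- level + window_slope_correction(sim, n_pb)
        }
      }
      k1[b] <- level
      last_seq_end <- level - sim$online_rate # K at end of block
    } else {
      k1[b] <- NA_real_
    }
  }
  list(k1 = k1, applied = applied)
}

# Trend correction r * (w - 1) / (n - 1) added to the end-of-block jump so
# the last/first window means straddle the break by exactly offline_gain.
window_slope_correction <- function(sim, n = 120L) {
  w <- sim$offline_window
  sim$online_rate * (w - 1) / (n - 1)
}

#' Simulate one participant's trial table
#'
#' Generates the stimulus session for `design` and applies the generative RT
#' model of [sim_config()], ex-Gaussian noise, outliers and the 150 ms
#' physiological floor.
#'
#' @param design An [srt_design()].
#' @param sim An [sim_config()].
#' @param participant_id Identifier stored in the `participant` column.
#' @param seed Integer seed (per participant).
#' @return A tibble with columns `participant`, `block`, `trial`, `stimulus`,
#'   `transition_prob`, `rt`, `correct`.
#' @export
simulate_participant <- function(design, sim, participant_id = "p1",
                                 seed = sim$seed) {
  stopifnot(inherits(design, "srt_design"), inherits(sim, "srt_sim_config"))
  session <- generate_session(design, seed = derive_seed(seed, 1))
  n_pb <- design$trials_per_block
  kt <- knowledge_trend(design$block_roles, sim, n_pb)

  rt_trend <- numeric(nrow(session))
  for (b in seq_along(design$block_roles)) {
    idx <- which(session$block == b)
    t_rel <- (session$trial[idx] - 1) / (n_pb - 1)
    level <- sim$baseline_rt - sim$general_practice_rate * (b - 1)
    if (kt$applied[b]) {
      K <- kt$k1[b] - sim$online_rate * t_rel
      rt_trend[idx] <- level - K
    } else {
      rt_trend[idx] <- level
    }
  }

  offset <- numeric(nrow(session))
  if (design$sequence_type == "probabilistic") {
    key <- ifelse(is.na(session$transition_prob), "undefined",
      format(session$transition_prob, trim = TRUE)
    )
    ps <- sim$prob_sensitivity
    offset <- ifelse(key %in% names(ps), ps[key], 0)
  }

  with_local_seed(derive_seed(seed, 2), {
    n <- nrow(session)
    noise <- rnorm(n, 0, sim$noise_sigma)
    if (sim$noise_tau > 0) {
      noise <- noise + rexp(n, rate = 1 / sim$noise_tau) - sim$noise_tau
    }
    rt <- rt_trend + offset + noise
    if (sim$outlier_rate > 0) {
      lapse <- runif(n) < sim$outlier_rate
      rt[lapse] <- sim$baseline_rt + sim$outlier_scale
    }
    rt <- pmax(rt, 150)
    tibble::tibble(
      participant = participant_id,
      block = session$block,
      trial = session$trial,
      stimulus = session$stimulus,
      transition_prob = session$transition_prob,
      rt = rt,
      correct = TRUE
    )
  })
}

#' Per-group presets for the four-group study design
#'
#' Returns the default 2 x 2 cohort specification (preliminary knowledge x
#' sequence type). Fixed-sequence groups improve within blocks (negative
#' `online_rate`) with small between-block gains; probabilistic groups slow
#' down within blocks and gain substantially across breaks; declarative
#' knowledge is highest with a fixed sequence and preliminary knowledge.
#'
#' @param base An [sim_config()] supplying shared parameters.
#' @return A named list (one element per group) of lists with fields
#'   `design` and `sim`.
#' @export
cohort_presets <- function(base = sim_config()) {
  groups <- list(
    PK_Fixed = list(
      type = "fixed", pk = TRUE,
      online_rate = -25, offline_gain = 6, declarative_knowledge = 0.6
    ),
    NPK_Fixed = list(
      type = "fixed", pk = FALSE,
      online_rate = -18, offline_gain = 6, declarative_knowledge = 0.35
    ),
    PK_Prob = list(
      type = "probabilistic", pk = TRUE,
      online_rate = 12, offline_gain = 30, declarative_knowledge = 0.10
    ),
    NPK_Prob = list(
      type = "probabilistic", pk = FALSE,
      online_rate = 12, offline_gain = 30, declarative_knowledge = 0.05
    )
  )
  lapply(groups, function(g) {
    s <- base
    s$online_rate <- g$online_rate
    s$offline_gain <- g$offline_gain
    s$declarative_knowledge <- g$declarative_knowledge
    list(
      design = srt_design(g$type, pk = g$pk, seed = base$seed),
      sim = s
    )
  })
}

#' Simulate a full four-group cohort
#'
#' Simulates `n_participants_per_group` participants in each group of
#' `groups` (default: the 2 x 2 [cohort_presets()]), with per-participant
#' seeds derived deterministically from `seed`, and simulates each
#' participant's posttest.
#'
#' @param groups Named list of `list(design =, sim =)` group specifications.
#' @param seed Master integer seed.
#' @param n_participants_per_group Cell size; defaults to each group's
#'   `sim$n_participants_per_group`.
#' @return A list of class `srt_cohort` with elements `trials` (trial-level
#'   tibble including `group`) and `posttest` (long posttest response tibble,
#'   see [score_posttest()]).
#' @export
simulate_cohort <- function(groups = cohort_presets(), seed = 1L,
                            n_participants_per_group = NULL) {
  trials <- list()
  posttest <- list()
  ids_seen <- character(0)
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    g <- groups[[gi]]
    n_pp <- n_participants_per_group %||% g$sim$n_participants_per_group
    for (pi in seq_len(n_pp)) {
      pid <- sprintf("%s_%02d", gname, pi)
      if (pid %in% ids_seen) abort(sprintf("Duplicate participant id: %s", pid))
      ids_seen <- c(ids_seen, pid)
      pseed <- derive_seed(seed, gi, pi)
      tt <- simulate_participant(g$design, g$sim, pid, seed = pseed)
      tt$group <- gname
      trials[[pid]] <- tt
      pt <- simulate_posttest(g$design, g$sim$declarative_knowledge,
        seed = derive_seed(pseed, 3)
      )
      pt$participant <- pid
      pt$group <- gname
      posttest[[pid]] <- pt
    }
  }
  out <- list(
    trials = dplyr::relocate(
      dplyr::bind_rows(trials), "participant", "group"
    ),
    posttest = dplyr::relocate(
      dplyr::bind_rows(posttest), "participant", "group"
    )
  )
  class(out) <- "srt_cohort"
  out
}

#' @export
print.srt_cohort <- function(x, ...) {
  cat("<srt_cohort> ", dplyr::n_distinct(x$trials$participant),
    " participants, ", nrow(x$trials), " trials\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate a posttest (recall + recognition)
#'
#' Recall: each true chunk of the design is reproduced with probability
#' `declarative_knowledge`; every remaining response slot is filled with a
#' stimulus triple drawn uniformly without replacement from all `4^3`
#' triples not already emitted, so that with zero knowledge the expected
#' recall fraction equals the analytic chance level (12/64 fixed, 16/64
#' probabilistic). Recognition: each item of the design's
#' [recognition_key()] is answered correctly (endorsed if correct, rejected
#' if a foil) with probability `0.5 + declarative_knowledge / 2`.
#'
#' @param design An [srt_design()].
#' @param declarative_knowledge Probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A long tibble with columns `task` (`"recall"`/`"recognition"`),
#'   `chunk`, `endorsed` (recognition only), `correct` (recognition key),
#'   `confidence` (ordinal 1-5).
#' @export
simulate_posttest <- function(design, declarative_knowledge, seed = 1L) {
  stopifnot(inherits(design, "srt_design"))
  dk <- declarative_knowledge
  if (dk < 0 || dk > 1) abort("`declarative_knowledge` must be in [0, 1].")
  true <- suppressWarnings(enumerate_chunks(design, 3L))
  key <- recognition_key(design, seed = derive_seed(seed, 7))
  with_local_seed(seed, {
    known <- runif(length(true)) < dk
    recalled <- true[known]
    n_fill <- sum(!known)
    if (n_fill > 0) {
      pool <- setdiff(all_tuples(3L, design$n_stimuli), recalled)
      recalled <- c(recalled, sample(pool, n_fill))
    }
    recalled <- recalled[sample.int(length(recalled))] # response order is arbitrary
    correct_answer <- runif(nrow(key)) < 0.5 + dk / 2
    endorsed <- ifelse(key$correct, correct_answer, !correct_answer)
    confidence <- 1L + rbinom(1, 4, dk)
    dplyr::bind_rows(
      tibble::tibble(
        task = "recall", chunk = recalled, endorsed = NA,
        correct = NA, confidence = confidence
      ),
      tibble::tibble(
        task = "recognition", chunk = key$chunk, endorsed = endorsed,
        correct = key$correct, confidence = confidence
      )
    )
  })
}
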