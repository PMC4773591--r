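# Stimulus sequence design: transition matrices, constrained block generators,
# and the experiment design configuration.

#' Build a first-order Markov transition matrix for stimulus sequences
#'
#' Constructs the row-stochastic 4 x 4 matrix of next-stimulus probabilities
#' used to generate probabilistic sequences. The default is a circulant
#' pattern in which every stimulus has exactly one successor with probability
#' 0.6, one with 0.3 and one with 0.1 (the diagonal is zero: a stimulus is
#' never followed by itself). Row 2 of the default reads
#' `P(1 | 2) = 0.6, P(3 | 2) = 0.3, P(4 | 2) = 0.1`.
#'
#' @param probs Length-3 numeric vector giving the probabilities assigned, in
#'   order, to the successors at offsets -1, +1 and +2 (mod 4) from the
#'   current stimulus. Must be positive and sum to 1.
#' @return A 4 x 4 numeric matrix of class `srt_tmatrix`: rows index the
#'   current stimulus, columns the next stimulus; each row sums to 1 and the
#'   diagonal is exactly zero.
#' @examples
#' T <- transition_matrix()
#' T[2, ] # 0.6 -> stimulus 1, 0.3 -> stimulus 3, 0.1 -> stimulus 4
#' @export
transition_matrix <- function(probs = c(0.6, 0.3, 0.1)) {
  if (length(probs) != 3 || any(probs <= 0) || abs(sum(probs) - 1) > 1e-12) {
    abort("`probs` must be 3 positive probabilities summing to 1.")
  }
  m <- matrix(0, 4, 4)
  offsets <- c(-1L, 1L, 2L)
  for (i in 1:4) {
    for (k in 1:3) {
      j <- ((i - 1L + offsets[k]) %% 4L) + 1L
      m[i, j] <- probs[k]
    }
  }
  dimnames(m) <- list(from = 1:4, to = 1:4)
  as_transition_matrix(m)
}

#' Validate and classify a transition matrix
#'
#' @param m A 4 x 4 numeric matrix of next-stimulus probabilities.
#' @return `m` with class `srt_tmatrix`, after validation: rows must sum to 1
#'   (within 1e-12), all entries must lie in \[0, 1\] and the diagonal must be
#'   exactly zero (no immediate repeats).
#' @export
as_transition_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) != ncol(m)) {
    abort("A transition matrix must be a square numeric matrix.")
  }
  if (any(m < 0 | m > 1)) abort("Transition probabilities must lie in [0, 1].")
  if (any(diag(m) != 0)) abort("The diagonal must be exactly 0 (no immediate repeats).")
  if (any(abs(rowSums(m) - 1) > 1e-12)) abort("Each row must sum to 1 (within 1e-12).")
  structure(m, class = c("srt_tmatrix", "matrix", "array"))
}

uniform_offdiag_matrix <- function(n_stimuli = 4L) {
  m <- matrix(1 / (n_stimuli - 1), n_stimuli, n_stimuli)
  diag(m) <- 0
  dimnames(m) <- list(from = seq_len(n_stimuli), to = seq_len(n_stimuli))
  as_transition_matrix(m)
}

#' Experiment design configuration
#'
#' Bundles the structural constants of an SRT session: four spatial stimuli,
#' six blocks of 120 trials, blocks 1-4 and 6 carrying the assigned (fixed or
#' probabilistic) sequence and block 5 random.
#'
#' @param sequence_type `"fixed"` (a 12-item sequence repeated 10 times per
#'   block) or `"probabilistic"` (first-order Markov sampling from `matrix`).
#' @param n_stimuli Number of distinct stimuli (default 4).
#' @param trials_per_block Trials per block (default 120).
#' @param block_roles Character vector of `"sequence"`/`"random"` roles, one
#'   per block; default `c(rep("sequence", 4), "random", "sequence")`.
#' @param pk Logical: does the (simulated) group receive preliminary knowledge
#'   that a sequence is present? Structural metadata only.
#' @param fixed_sequence For fixed designs, a 12-item stimulus vector or
#'   `"auto"` to generate one from `seed` (see [make_fixed_sequence()]).
#' @param repetitions Repetitions of the fixed sequence per block (default 10;
#'   `repetitions * length(fixed_sequence)` must equal `trials_per_block`).
#' @param matrix An `srt_tmatrix` used for probabilistic designs and for
#'   annotating transition probabilities. Defaults to [transition_matrix()].
#' @param seed Integer seed used when `fixed_sequence = "auto"`.
#' @return An object of class `srt_design` (a named list of the above, with
#'   `fixed_sequence` resolved to an explicit vector for fixed designs).
#' @examples
#' d <- srt_design("fixed", seed = 7)
#' d$fixed_sequence
#' @export
srt_design <- function(sequence_type = c("fixed", "probabilistic"),
                       n_stimuli = 4L,
                       trials_per_block = 120L,
                       block_roles = c(rep("sequence", 4), "random", "sequence"),
                       pk = FALSE,
                       fixed_sequence = "auto",
                       repetitions = 10L,
                       matrix = transition_matrix(),
                       seed = 1L) {
  sequence_type <- match.arg(sequence_type)
  n_stimuli <- as.integer(n_stimuli)
  trials_per_block <- as.integer(trials_per_block)
  if (!all(block_roles %in% c("sequence", "random"))) {
    abort("`block_roles` must contain only \"sequence\" and \"random\".")
  }
  if (trials_per_block %% n_stimuli != 0) {
    abort("`trials_per_block` must be divisible by `n_stimuli` (balanced blocks).")
  }
  matrix <- as_transition_matrix(matrix)
  if (sequence_type == "fixed") {
    if (identical(fixed_sequence, "auto")) {
      n_items <- trials_per_block %/% as.integer(repetitions)
      fixed_sequence <- make_fixed_sequence(n_items, n_stimuli, seed = seed)
    }
    fixed_sequence <- as.integer(fixed_sequence)
    if (length(fixed_sequence) * repetitions != trials_per_block) {
      abort("`repetitions * length(fixed_sequence)` must equal `trials_per_block`.")
    }
    check_cyclic_norepeat(fixed_sequence)
  } else {
    fixed_sequence <- NULL
  }
  structure(
    list(
      sequence_type = sequence_type, n_stimuli = n_stimuli,
      trials_per_block = trials_per_block, block_roles = block_roles,
      pk = isTRUE(pk), fixed_sequence = fixed_sequence,
      repetitions = as.integer(repetitions), matrix = matrix,
      seed = as.integer(seed)
    ),
    class = "srt_design"
  )
}

#' @export
print.srt_design <- function(x, ...) {
  cat("<srt_design> ", x$sequence_type, ", ", length(x$block_roles),
    " blocks x ", x$trials_per_block, " trials (block roles: ",
    paste(substr(x$block_roles, 1, 1), collapse = ""), ")\n",
    sep = ""
  )
  if (x$sequence_type == "fixed") {
    cat("  sequence: ", paste(x$fixed_sequence, collapse = " "), " x ",
      x$repetitions, "\n",
      sep = ""
    )
  }
  invisible(x)
}

check_cyclic_norepeat <- function(sequence) {
  if (any(sequence != as.integer(sequence))) abort("Stimuli must be integers.")
  n <- length(sequence)
  if (n > 1 && any(sequence[-1] == sequence[-n])) {
    abort("Sequence has an immediate repeat.")
  }
  if (n > 1 && sequence[1] == sequence[n]) {
    abort("Sequence repeats across the cyclic wrap (last == first).")
  }
  invisible(sequence)
}

#' Generate a balanced cyclic fixed sequence
#'
#' Produces the deterministic n-item sequence repeated within each fixed-design
#' block. Each stimulus appears `n_items / n_stimuli` times, no stimulus is
#' immediately repeated, and the constraint holds across the cyclic wrap so
#' that repetitions concatenate legally. When `n_items == n_stimuli *
#' (n_stimuli - 1)` (the default 12-item, 4-stimulus case) the sequence is a
#' random Eulerian circuit of the complete digraph on the stimuli: every
#' ordered stimulus pair occurs exactly once, so each stimulus has three
#' distinct successors and every two-element context determines its successor
#' uniquely -- the structure presupposed by the recall chance-level model.
#'
#' @param n_items Sequence length; must be divisible by `n_stimuli`.
#' @param n_stimuli Number of distinct stimuli.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return Integer vector of length `n_items`.
#' @examples
#' make_fixed_sequence(12, 4, seed = 7)
#' @export
make_fixed_sequence <- function(n_items, n_stimuli = 4L, seed = 1L) {
  n_items <- as.integer(n_items)
  n_stimuli <- as.integer(n_stimuli)
  if (n_items %% n_stimuli != 0) {
    abort("`n_items` must be divisible by `n_stimuli`.")
  }
  quota <- n_items %/% n_stimuli
  if (n_stimuli < 2 && n_items > 1) {
    abort("Cannot avoid immediate repeats with fewer than 2 stimuli.")
  }
  if (n_items == n_stimuli) { # quota 1: a random permutation suffices
    return(with_local_seed(seed, sample(seq_len(n_stimuli))))
  }
  if (quota == n_stimuli - 1L) {
    return(with_local_seed(seed, eulerian_sequence(n_stimuli)))
  }
  # General case: randomized backtracking over per-stimulus quotas.
  with_local_seed(seed, {
    for (attempt in 1:1000) {
      s <- quota_sequence_attempt(n_items, n_stimuli, quota)
      if (!is.null(s)) return(s)
    }
    abort("Could not construct a balanced cyclic sequence in 1000 attempts.")
  })
}

# Random Eulerian circuit on the complete digraph over n stimuli
# (each ordered pair used exactly once), via randomized Hierholzer/backtracking.
eulerian_sequence <- function(n_stimuli) {
  edges <- matrix(TRUE, n_stimuli, n_stimuli)
  diag(edges) <- FALSE
  n_edges <- sum(edges)
  start <- sample.int(n_stimuli, 1)
  path <- integer(n_edges + 1L)
  path[1] <- start
  walk <- function(pos) {
    if (pos == n_edges + 1L) {
      return(path[n_edges + 1L] == start) # must close the circuit
    }
    cur <- path[pos]
    nxt <- which(edges[cur, ])
    for (j in nxt[sample.int(length(nxt))]) {
      edges[cur, j] <<- FALSE
      path[pos + 1L] <<- j
      if (walk(pos + 1L)) return(TRUE)
      edges[cur, j] <<- TRUE
    }
    FALSE
  }
  if (!walk(1L)) abort("Eulerian circuit construction failed.") # unreachable for n >= 3
  path[seq_len(n_edges)]
}

quota_sequence_attempt <- function(n_items, n_stimuli, quota) {
  remaining <- rep(quota, n_stimuli)
  s <- integer(n_items)
  s[1] <- sample.int(n_stimuli, 1)
  remaining[s[1]] <- remaining[s[1]] - 1L
  for (t in 2:n_items) {
    avoid <- s[t - 1L]
    if (t == n_items) avoid <- c(avoid, s[1]) # cyclic wrap
    ok <- which(remaining > 0L)
    ok <- setdiff(ok, avoid)
    if (length(ok) == 0L) return(NULL)
    nxt <- if (length(ok) == 1L) ok else sample(ok, 1L)
    s[t] <- nxt
    remaining[nxt] <- remaining[nxt] - 1L
  }
  s
}

#' Build a fixed-sequence block by repetition
#'
#' Concatenates `repetitions` copies of a cyclically valid sequence into one
#' block (default: 10 x 12 items = 120 trials).
#'
#' @param sequence Integer stimulus vector satisfying the cyclic no-repeat
#'   property (checked).
#' @param repetitions Number of concatenated repetitions.
#' @return Integer stimulus vector of length `length(sequence) * repetitions`.
#' @export
make_fixed_block <- function(sequence, repetitions = 10L) {
  sequence <- as.integer(sequence)
  check_cyclic_norepeat(sequence)
  rep(sequence, times = as.integer(repetitions))
}

#' Sample a balanced no-repeat block from a Markov chain
#'
#' Draws a block of stimuli from the first-order transition matrix subject to
#' the design constraints: no stimulus immediately repeats and each stimulus
#' occurs exactly `n_trials / nrow(matrix)` times. Sampling is sequential:
#' at each step the current row of the matrix is restricted to stimuli with
#' remaining quota and renormalized; if the chain dead-ends (only the current
#' stimulus has quota left) the whole block is restarted, up to `max_restarts`
#' times.
#'
#' @param matrix An `srt_tmatrix`.
#' @param n_trials Block length; must be divisible by the number of stimuli.
#' @param seed Integer seed (same seed, same block).
#' @param max_restarts Restart budget before failing (default 1000).
#' @return Integer stimulus vector of length `n_trials`.
#' @examples
#' b <- make_markov_block(transition_matrix(), 120, seed = 1)
#' table(b) # 30 of each stimulus
#' @export
make_markov_block <- function(matrix, n_trials = 120L, seed = 1L,
                              max_restarts = 1000L) {
  matrix <- as_transition_matrix(matrix)
  n_stimuli <- nrow(matrix)
  n_trials <- as.integer(n_trials)
  if (n_trials %% n_stimuli != 0) {
    abort("`n_trials` must be divisible by the number of stimuli.")
  }
  quota <- n_trials %/% n_stimuli
  with_local_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      s <- markov_block_attempt(matrix, n_trials, n_stimuli, quota)
      if (!is.null(s)) {
        attr(s, "attempts") <- attempt
        return(s)
      }
    }
    abort(sprintf(
      "Markov block generation failed to satisfy the quota after %d restarts.",
      max_restarts
    ))
  })
}

markov_block_attempt <- function(matrix, n_trials, n_stimuli, quota) {
  remaining <- rep(quota, n_stimuli)
  s <- integer(n_trials)
  s[1] <- sample.int(n_stimuli, 1)
  remaining[s[1]] <- remaining[s[1]] - 1L
  for (t in 2:n_trials) {
    w <- matrix[s[t - 1L], ]
    w[remaining <= 0L] <- 0
    tot <- sum(w)
    if (tot <= 0) return(NULL) # dead end: only the current stimulus remains
    s[t] <- sample.int(n_stimuli, 1, prob = w / tot)
    remaining[s[t]] <- remaining[s[t]] - 1L
  }
  s
}

#' Sample a balanced random block
#'
#' A random-order block with uniform off-diagonal transition probabilities:
#' the special case of [make_markov_block()] with `P(j | i) = 1/(n-1)` for
#' `j != i`. Used for block 5 of the standard session.
#'
#' @inheritParams make_markov_block
#' @param n_stimuli Number of distinct stimuli.
#' @return Integer stimulus vector of length `n_trials`.
#' @export
make_random_block <- function(n_trials = 120L, n_stimuli = 4L, seed = 1L,
                              max_restarts = 1000L) {
  make_markov_block(uniform_offdiag_matrix(n_stimuli), n_trials,
    seed = seed, max_restarts = max_restarts
  )
}

#' Annotate each trial with its transition probability
#'
#' Trial `t >= 2` receives `matrix[stimulus(t-1), stimulus(t)]`; trial 1 has
#' no predecessor and receives `NA`.
#'
#' @param stimuli Integer stimulus vector (one block).
#' @param matrix An `srt_tmatrix`.
#' @return Numeric vector of per-trial transition probabilities (`NA` first).
#' @examples
#' annotate_transition_probs(c(2, 1, 3), transition_matrix()) # NA, 0.6, 0.1
#' @export
annotate_transition_probs <- function(stimuli, matrix) {
  matrix <- as_transition_matrix(matrix)
  stimuli <- as.integer(stimuli)
  n <- length(stimuli)
  p <- rep(NA_real_, n)
  if (n >= 2) {
    p[-1] <- matrix[cbind(stimuli[-n], stimuli[-1])]
  }
  p
}

#' Generate the full stimulus session for a design
#'
#' Builds all blocks of the session in their design roles: sequence blocks
#' carry the fixed sequence or fresh Markov samples, random blocks are
#' uniformly sampled, and every trial is annotated with its transition
#' probability under the design matrix (`NA` for block-initial trials, and
#' for every trial of fixed designs, where the Markov annotation does not
#' apply).
#'
#' @param design An [srt_design()].
#' @param seed Integer seed controlling all block sampling.
#' @return A tibble with columns `block`, `role`, `trial`, `stimulus`,
#'   `transition_prob`.
#' @export
generate_session <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "srt_design"))
  n_blocks <- length(design$block_roles)
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    block_seed <- derive_seed(seed, b)
    role <- design$block_roles[b]
    stimuli <- if (role == "random") {
      make_random_block(design$trials_per_block, design$n_stimuli,
        seed = block_seed
      )
    } else if (design$sequence_type == "fixed") {
      make_fixed_block(design$fixed_sequence, design$repetitions)
    } else {
      make_markov_block(design$matrix, design$trials_per_block,
        seed = block_seed
      )
    }
    prob <- if (design$sequence_type == "probabilistic") {
      annotate_transition_probs(stimuli, design$matrix)
    } else {
      rep(NA_real_, length(stimuli))
    }
    blocks[[b]] <- tibble::tibble(
      block = b, role = role,
      trial = seq_along(stimuli),
      stimulus = as.integer(stimuli),
      transition_prob = prob
    )
  }
  dplyr::bind_rows(blocks)
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed))
  force(code)
}
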