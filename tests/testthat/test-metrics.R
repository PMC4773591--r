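linear_block <- function(intercept = 600, slope = -0.5, n = 120,
                         participant = "p1", block = 1L) {
  tibble::tibble(
    participant = participant, block = block, trial = 1:n,
    stimulus = rep_len(1:4, n), rt = intercept + slope * (0:(n - 1))
  )
}

test_that("block means average valid trials only", {
  tt <- tibble::tibble(
    participant = "p1", block = 1L, trial = 1:4, stimulus = 1:4,
    rt = c(400, 600, 1000, 2000), valid = c(TRUE, TRUE, FALSE, FALSE)
  )
  bm <- block_means(tt)
  expect_equal(bm$mean_rt, 500)
  expect_equal(bm$n_valid, 2L)
  none <- dplyr::mutate(tt, valid = FALSE)
  expect_message(bm0 <- block_means(none), "no valid")
  expect_true(is.na(bm0$mean_rt))
})

test_that("overall learning contrasts are plain block-mean differences", {
  bm <- tibble::tibble(
    participant = "p1", block = 1:6,
    mean_rt = c(550, 520, 500, 480, 530, 470), n_valid = 120L
  )
  ov <- overall_learning(bm)
  expect_equal(ov$learning_b1_b4, 70)
  expect_equal(ov$interference_b5_b4, 50)
  flat <- dplyr::mutate(bm, mean_rt = 500)
  ovf <- overall_learning(flat)
  expect_equal(ovf$learning_b1_b4, 0)
  expect_equal(ovf$interference_b5_b4, 0)
  missing4 <- bm[-4, ]
  ovm <- overall_learning(missing4)
  expect_true(is.na(ovm$learning_b1_b4))
})

test_that("online learning equals the fitted change over the block", {
  expect_equal(online_learning(600 - 0.5 * (0:119), 1:120), 59.5)
  expect_equal(online_learning(rep(500, 120), 1:120), 0)
  expect_message(expect_true(is.na(online_learning(c(1, 2), 1:2))), "Fewer")
  # noisy data against the normal-equations oracle
  set.seed(31)
  rt <- 550 - 0.8 * (0:119) + rnorm(120, 0, 40)
  expect_equal(
    online_learning(rt, 1:120),
    -ols_slope_oracle(1:120, rt) * 119,
    tolerance = 1e-9
  )
})

test_that("offline learning is the last/first window mean difference", {
  expect_equal(offline_learning(rep(550, 20), rep(520, 20)), 30)
  expect_equal(offline_learning(rep(500, 12), rep(500, 12)), 0)
  expect_message(
    expect_true(is.na(offline_learning(rep(500, 11), rep(500, 12)))),
    "window"
  )
  before <- c(rep(999, 108), rep(550, 12))
  after <- c(rep(520, 12), rep(111, 108))
  expect_equal(offline_learning(before, after), 30)
})

test_that("corrected offline learning subtracts only deterioration", {
  expect_equal(corrected_offline_learning(30, -20), 10)
  expect_equal(corrected_offline_learning(30, 15), 30)
  expect_equal(corrected_offline_learning(c(30, 30), c(-20, 15)), c(10, 30))
})

test_that("learning metrics are shift-invariant and scale-equivariant", {
  d <- srt_design("probabilistic", seed = 5)
  sim <- sim_config(outlier_rate = 0)
  tt <- simulate_participant(d, sim, "p1", seed = 9)
  tt$valid <- TRUE
  base <- quiet_summary(tt)
  shifted <- dplyr::mutate(tt, rt = rt + 250)
  scaled <- dplyr::mutate(tt, rt = rt * 3)
  metrics <- c(
    "learning_b1_b4", "interference_b5_b4", "online", "offline",
    "corrected_offline", "offline_minus_online"
  )
  for (m in metrics) {
    expect_equal(quiet_summary(shifted)[[m]], base[[m]], tolerance = 1e-9)
    expect_equal(quiet_summary(scaled)[[m]], 3 * base[[m]], tolerance = 1e-9)
  }
})

test_that("window metrics ignore trimming outside the windows", {
  b1 <- linear_block(600, 0, block = 1L)
  b2 <- linear_block(570, 0, block = 2L)
  tt <- dplyr::bind_rows(b1, b2)
  tt$valid <- TRUE
  full <- suppressMessages(offline_by_break(tt))
  # invalidate mid-block trials far from both windows
  tt2 <- dplyr::mutate(tt, valid = !(trial %in% 40:60))
  part <- suppressMessages(offline_by_break(tt2))
  expect_equal(part$offline, full$offline)
  expect_equal(full$offline, 30)
})

test_that("probability stratification filters, ranks and guards", {
  d <- srt_design("probabilistic", seed = 5)
  ses <- generate_session(d, seed = 2)
  tt <- dplyr::mutate(ses, participant = "p1", rt = 500, valid = TRUE)
  st <- stratify_by_probability(tt, probs = c(0.3, 0.6))
  # direct count oracle on the annotated session
  expect_equal(nrow(st), sum(tt$transition_prob %in% c(0.3, 0.6)))
  expect_true(all(st$transition_prob %in% c(0.3, 0.6)))
  ranks <- st |>
    dplyr::group_by(block) |>
    dplyr::summarise(ok = all(trial_rank == seq_len(dplyr::n())))
  expect_true(all(ranks$ok))
  # full probability set = all annotated trials (trial 1 has no predecessor)
  full <- stratify_by_probability(tt, probs = c(0.1, 0.3, 0.6))
  expect_equal(nrow(full), sum(!is.na(tt$transition_prob)))
  expect_warning(empty <- stratify_by_probability(tt, probs = numeric(0)), "Empty")
  expect_equal(nrow(empty), 0)
  fixed_tt <- dplyr::mutate(tt, transition_prob = NA_real_)
  expect_error(stratify_by_probability(fixed_tt), "stratif")
})

test_that("stratified noiseless metrics still recover generative values", {
  d <- srt_design("probabilistic", seed = 5)
  sim <- noiseless_sim(
    online_rate = 24, offline_gain = 18,
    prob_sensitivity = c("0.1" = 0, "0.3" = 0, "0.6" = 0, "undefined" = 0)
  )
  tt <- simulate_participant(d, sim, "p1", seed = 9)
  tt$valid <- TRUE
  st <- stratify_by_probability(tt, probs = c(0.3, 0.6))
  sm <- quiet_summary(st)
  # the within-block trend is linear in the original trial index, so the
  # regression on ranks still measures the same per-block change up to the
  # span of retained trials; with ~90% retained the distortion is < 15%
  expect_lt(abs(sm$online - (-24)), 0.15 * 24)
  expect_lt(abs(sm$offline - 18), 0.15 * 18)
})

test_that("participant summaries satisfy the definitional identity", {
  co <- simulate_cohort(seed = 8)
  tr <- quiet_trim(co$trials)
  sm <- quiet_summary(tr)
  expect_equal(sm$offline_minus_online, sm$offline - sm$online)
  expect_equal(nrow(sm), 48)
  expect_false(any(is.na(sm$online)))
})
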