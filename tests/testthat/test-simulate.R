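test_that("noiseless within-block trend equals the configured online rate", {
  d <- srt_design("fixed", seed = 7)
  sim <- noiseless_sim(online_rate = -60, offline_gain = 0)
  tt <- simulate_participant(d, sim, "p1", seed = 1)
  for (b in c(1:4, 6)) {
    rt <- tt$rt[tt$block == b]
    expect_equal(rt[1] - rt[120], 60, tolerance = 1e-9)
    # exactly linear
    expect_equal(rt, rt[1] - 60 * (0:119) / 119, tolerance = 1e-9)
  }
  # random block: flat (knowledge withheld, no practice term here)
  expect_equal(sd(tt$rt[tt$block == 5]), 0, tolerance = 1e-9)
})

test_that("noiseless break gains equal the configured offline gain", {
  d <- srt_design("fixed", seed = 7)
  sim <- noiseless_sim(online_rate = 0, offline_gain = 30)
  tt <- simulate_participant(d, sim, "p1", seed = 1)
  off <- suppressMessages(offline_by_break(tt))
  expect_equal(off$offline[off$from_block %in% 1:3], rep(30, 3), tolerance = 1e-9)
  # knowledge is withheld in block 5 and resumes in block 6 one gain above
  # block 4's level
  b4 <- mean(tt$rt[tt$block == 4])
  b5 <- mean(tt$rt[tt$block == 5])
  b6 <- mean(tt$rt[tt$block == 6])
  expect_equal(b5 - b4, 90, tolerance = 1e-9) # three accumulated gains
  expect_equal(b4 - b6, 30, tolerance = 1e-9) # one further gain
})

test_that("noiseless metrics recover the generative parameters exactly", {
  d <- srt_design("fixed", seed = 7)
  cases <- list(
    improvement = list(rate = -50, gain = 10),
    fatigue = list(rate = 20, gain = 30),
    none = list(rate = 0, gain = 0)
  )
  for (cs in cases) {
    sim <- noiseless_sim(online_rate = cs$rate, offline_gain = cs$gain)
    tt <- simulate_participant(d, sim, "p1", seed = 1)
    sm <- quiet_summary(tt)
    expect_equal(sm$online, -cs$rate, tolerance = 1e-9)
    expect_equal(sm$offline, cs$gain, tolerance = 1e-9)
    expected_corrected <- if (cs$rate > 0) cs$gain - cs$rate else cs$gain
    expect_equal(sm$corrected_offline, expected_corrected, tolerance = 1e-9)
    expect_equal(sm$offline_minus_online, sm$offline - sm$online)
  }
})

test_that("window-based B1-to-B4 decomposition identity holds noiselessly", {
  d <- srt_design("fixed", seed = 7)
  n <- 120
  w <- 12
  for (cs in list(c(-40, 15), c(25, 30), c(0, 20), c(-60, 0))) {
    sim <- noiseless_sim(online_rate = cs[1], offline_gain = cs[2])
    tt <- simulate_participant(d, sim, "p1", seed = 1)
    first_w_b1 <- mean(tt$rt[tt$block == 1][1:w])
    last_w_b4 <- mean(tt$rt[tt$block == 4][(n - w + 1):n])
    total <- first_w_b1 - last_w_b4
    sm <- quiet_summary(tt)
    # each block contributes its fitted change over the (n-w) steps spanned
    # by the window midpoints; each break contributes one offline gain
    expect_equal(total, 4 * sm$online * (n - w) / (n - 1) + 3 * sm$offline,
      tolerance = 1e-9
    )
  }
  # with no within-block trend this reduces to: B1-B4 improvement = 3 gains
  sim0 <- noiseless_sim(online_rate = 0, offline_gain = 25)
  sm0 <- quiet_summary(simulate_participant(d, sim0, "p1", seed = 1))
  expect_equal(sm0$learning_b1_b4, 3 * 25, tolerance = 1e-9)
})

test_that("cohort simulation is deterministic with the expected dimensions", {
  co1 <- simulate_cohort(seed = 5)
  co2 <- simulate_cohort(seed = 5)
  expect_identical(co1$trials, co2$trials)
  expect_identical(co1$posttest, co2$posttest)
  expect_equal(nrow(co1$trials), 4 * 12 * 6 * 120) # 34,560
  expect_equal(dplyr::n_distinct(co1$trials$participant), 48)
  expect_setequal(
    unique(co1$trials$group),
    c("PK_Fixed", "NPK_Fixed", "PK_Prob", "NPK_Prob")
  )
  co3 <- simulate_cohort(seed = 6)
  expect_false(identical(co1$trials$rt, co3$trials$rt))
})

test_that("the preset cohort shows the qualitative group signature", {
  # pool three cohorts: per-sequence-type means over 72 participants
  sm <- purrr::map_dfr(2:4, function(s) {
    quiet_summary(quiet_trim(simulate_cohort(seed = s)$trials))
  })
  gs <- sm |>
    dplyr::mutate(seqtype = ifelse(grepl("Prob", .data$group), "prob", "fixed")) |>
    dplyr::group_by(.data$seqtype) |>
    dplyr::summarise(
      online = mean(.data$online), offline = mean(.data$offline)
    )
  prob <- gs[gs$seqtype == "prob", ]
  fixed <- gs[gs$seqtype == "fixed", ]
  expect_lt(prob$online, 0) # within-block slowing
  expect_gt(prob$offline, 0) # between-block gains
  expect_gt(prob$offline, prob$online)
  expect_gt(fixed$online, 0)
  expect_gte(fixed$online, fixed$offline)
})

test_that("probability sensitivity orders stratified RTs 0.6 < 0.3 < 0.1", {
  co <- simulate_cohort(seed = 3)
  tr <- quiet_trim(co$trials)
  ord <- tr |>
    dplyr::filter(
      grepl("Prob", .data$group), .data$valid, !is.na(.data$transition_prob)
    ) |>
    dplyr::group_by(.data$transition_prob) |>
    dplyr::summarise(rt = mean(.data$rt))
  rts <- setNames(ord$rt, ord$transition_prob)
  expect_lt(rts[["0.6"]], rts[["0.3"]])
  expect_lt(rts[["0.3"]], rts[["0.1"]])
})

test_that("posttest simulation respects the declarative knowledge boundary", {
  d <- srt_design("fixed", seed = 7)
  pt1 <- simulate_posttest(d, declarative_knowledge = 1, seed = 4)
  recall <- pt1$chunk[pt1$task == "recall"]
  expect_setequal(recall, enumerate_chunks(d, 3))
  sc <- score_posttest(
    dplyr::mutate(pt1, participant = "p1"), d
  )
  expect_equal(sc$recall_percent, 1)
  expect_equal(sc$recognition_score, 1)
})

test_that("zero-knowledge posttests sit at the analytic chance levels", {
  d <- srt_design("fixed", seed = 7)
  dp <- srt_design("probabilistic")
  set.seed(77)
  seeds <- sample.int(1e6, 400)
  stats <- vapply(seeds, function(s) {
    ptf <- simulate_posttest(d, 0, seed = s)
    ptp <- simulate_posttest(dp, 0, seed = s + 1)
    scf <- score_posttest(dplyr::mutate(ptf, participant = "x"), d)
    scp <- score_posttest(dplyr::mutate(ptp, participant = "x"), dp)
    c(scf$recall_percent, scp$recall_percent, scf$recognition_score)
  }, numeric(3))
  # recall at 18.75% (fixed) and 25% (probabilistic); recognition at 50%
  expect_lt(abs(mean(stats[1, ]) - 0.1875), 0.015)
  expect_lt(abs(mean(stats[2, ]) - 0.25), 0.015)
  expect_lt(abs(mean(stats[3, ]) - 0.5), 0.03)
})

test_that("simulation config validation rejects out-of-range parameters", {
  expect_error(sim_config(noise_sigma = 0), "noise_sigma")
  expect_error(sim_config(noise_tau = -1), "noise_tau")
  expect_error(sim_config(outlier_rate = 0.2), "outlier_rate")
  expect_error(sim_config(declarative_knowledge = 1.5), "declarative_knowledge")
})
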