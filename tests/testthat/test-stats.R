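srh_fixture <- function() {
  d <- expand.grid(a = c("l", "h"), b = c("x", "y"), rep = 1:3)
  d$y <- c(12, 5, 9, 14, 3, 8, 11, 7, 6, 13, 2, 10)
  d
}

test_that("Scheirer-Ray-Hare matches the hand-ranked worked computation", {
  # Oracle (computed by hand before implementation): the 12 distinct values
  # rank to r = (10,3,7,12,2,6,9,5,4,11,1,8). Rank sums: a=l 33, a=h 45;
  # b=x 36, b=y 42; cells (l,x)=16, (h,x)=20, (l,y)=17, (h,y)=25.
  # SS_total = 650 - 12*6.5^2 = 143, MS_total = 13.
  # SS_a = (33^2+45^2)/6 - 507 = 12        -> H_a  = 12/13
  # SS_b = (36^2+42^2)/6 - 507 = 3         -> H_b  = 3/13
  # SS_cells = 523.333... - 507 = 16.333..., SS_ab = 4/3 -> H_ab = (4/3)/13
  out <- tidy(scheirer_ray_hare(srh_fixture(), "y", c("a", "b")))
  expect_equal(out$statistic, c(12 / 13, 3 / 13, (4 / 3) / 13), tolerance = 1e-12)
  expect_equal(out$df, c(1L, 1L, 1L))
  expect_equal(out$p.value, pchisq(out$statistic, 1, lower.tail = FALSE))
})

test_that("Scheirer-Ray-Hare handles total ties and is rank-invariant", {
  d <- srh_fixture()
  tied <- dplyr::mutate(d, y = 7)
  out <- tidy(scheirer_ray_hare(tied, "y", c("a", "b")))
  expect_equal(out$statistic, rep(0, 3))
  expect_equal(out$p.value, rep(1, 3))
  # invariance under strictly monotone transforms
  base <- tidy(scheirer_ray_hare(d, "y", c("a", "b")))
  logt <- tidy(scheirer_ray_hare(dplyr::mutate(d, y = log(y)), "y", c("a", "b")))
  expt <- tidy(scheirer_ray_hare(dplyr::mutate(d, y = exp(y / 3)), "y", c("a", "b")))
  expect_equal(base$statistic, logt$statistic, tolerance = 1e-12)
  expect_equal(base$statistic, expt$statistic, tolerance = 1e-12)
  expect_error(scheirer_ray_hare(d[1:5, ], "y", c("a", "b")), "at least 2")
})

test_that("two-way ANOVA reproduces hand-computed sums of squares", {
  # balanced 2x2 with n = 2 per cell; cell means 10, 20, 30, 60
  d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"))[rep(1:4, each = 2), ]
  d$y <- c(9, 11, 19, 21, 29, 31, 58, 62)
  out <- tidy(two_way_anova(d, "y", c("a", "b")))
  # oracle by hand: grand mean 30; A means 20 vs 40 -> SS_A = 8*10^2 = 800
  # B means 15 vs 45 -> SS_B = 8*15^2 = 1800; interaction SS = 8*5^2 = 200
  # SS_err = sum within-cell squares = 4*2 + 2*2 = ... each cell contributes
  # 2*(1)^2 except the last with 2*(2)^2: SS_err = 6 + 8 = 14, df = 4
  mse <- 14 / 4
  expect_equal(out$statistic[out$term == "a"], 800 / mse, tolerance = 1e-10)
  expect_equal(out$statistic[out$term == "b"], 1800 / mse, tolerance = 1e-10)
  expect_equal(out$statistic[out$term == "a:b"], 200 / mse, tolerance = 1e-10)
  expect_equal(out$df2, rep(4L, 3))

  flat <- dplyr::mutate(d, y = 5)
  outf <- tidy(two_way_anova(flat, "y", c("a", "b")))
  expect_true(all(is.na(outf$statistic) | outf$statistic == 0))
  expect_error(
    two_way_anova(d[d$a == "a1" | d$b == "b1", ], "y", c("a", "b")),
    "Empty"
  )
})

test_that("repeated-measures ANOVA with CS reproduces the paired t-test", {
  set.seed(42)
  n <- 10
  d <- tibble::tibble(
    participant = rep(sprintf("p%02d", 1:n), each = 2),
    cond = rep(c("a", "b"), n),
    y = rnorm(2 * n, 500, 40) + rep(c(0, 25), n) +
      rep(rnorm(n, 0, 30), each = 2)
  )
  fit <- rm_anova(d, "y", "participant", within = "cond", structures = "cs")
  tt <- t.test(d$y[d$cond == "b"] - d$y[d$cond == "a"])
  out <- tidy(fit)
  expect_equal(out$statistic, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(out$df2, n - 1L) # between-within denominator df
})

test_that("rm_anova selects a structure by AIC and reports all terms", {
  set.seed(43)
  d <- tidyr::expand_grid(
    participant = sprintf("p%02d", 1:16), block = factor(1:4)
  )
  d$grp <- rep(c("PK", "NPK"), each = 32)
  d$y <- rnorm(64, 500, 30) + rep(rnorm(16, 0, 25), each = 4)
  fit <- rm_anova(d, "y", "participant", within = "block", between = "grp")
  out <- tidy(fit)
  expect_setequal(out$term, c("block", "grp", "block:grp"))
  expect_true(fit$structure %in% c("cs", "ar1", "un"))
  expect_true(all(out$p.value >= 0 & out$p.value <= 1))
  expect_true(all(out$statistic >= 0))
  g <- glance(fit)
  expect_equal(g$structure, fit$structure)
  expect_true(g$n_converged >= 1)
  # between-within denominators: 14 between, within stratum for the rest
  expect_equal(out$df2[out$term == "grp"], 14L)
})

test_that("injected effects are detected at the configured sizes", {
  set.seed(48)
  # within-participant block effect, compound-symmetric noise
  dm <- tidyr::expand_grid(
    participant = sprintf("p%02d", 1:24), block = factor(1:6)
  )
  hits_block <- vapply(1:15, function(r) {
    dm$y <- 500 - 12 * as.integer(dm$block) +
      rep(rnorm(24, 0, 30), each = 6) + rnorm(144, 0, 25)
    fit <- rm_anova(dm, "y", "participant",
      within = "block", structures = "cs"
    )
    tidy(fit)$p.value[tidy(fit)$term == "block"] < 0.001
  }, logical(1))
  expect_gte(mean(hits_block), 0.95)
  # between-subjects sequence effect on offline learning, n = 12 per cell
  d2 <- expand.grid(
    knowledge = c("PK", "NPK"), sequence = c("Fixed", "Prob"), rep = 1:12
  )
  hits_seq <- vapply(1:50, function(r) {
    d2$y <- ifelse(d2$sequence == "Prob", 32, 8) + rnorm(48, 0, 20)
    out <- tidy(two_way_anova(d2, "y", c("knowledge", "sequence")))
    out$p.value[out$term == "sequence"] < 0.05
  }, logical(1))
  expect_gte(mean(hits_seq), 0.9)
})

test_that("Tukey-Kramer reduces to Tukey HSD under equal n", {
  means <- c(a = 500, b = 520, c = 560)
  out <- tukey_kramer(means, n = 12, s2 = 900, df = 33)
  # direct studentized-range oracle
  q_ab <- abs(500 - 520) / sqrt(900 / 12)
  expect_equal(
    out$p.adj[out$pair == "a-b"],
    ptukey(q_ab, 3, 33, lower.tail = FALSE),
    tolerance = 1e-12
  )
  # equal means: p ~ 1
  out2 <- tukey_kramer(c(a = 500, b = 500), n = 10, s2 = 400, df = 18)
  expect_equal(out2$p.adj, 1, tolerance = 1e-9)
  # degenerate zero variance is flagged
  expect_warning(
    out3 <- tukey_kramer(c(a = 1, b = 2), n = 5, s2 = 0, df = 8),
    "degenerate|Zero"
  )
  expect_equal(out3$p.adj, 0)
})

test_that("Tukey-Kramer isolates a single displaced cell at large n", {
  set.seed(44)
  n <- 200
  d <- data.frame(
    g = rep(c("a", "b", "c", "d"), each = n),
    y = c(rnorm(n), rnorm(n), rnorm(n), rnorm(n, 0.6))
  )
  means <- tapply(d$y, d$g, mean)
  s2 <- mean(tapply(d$y, d$g, var))
  out <- tukey_kramer(means, n = n, s2 = s2, df = 4 * (n - 1))
  sig <- out$pair[out$p.adj < 0.05]
  expect_setequal(sig, c("a-d", "b-d", "c-d"))
})

test_that("tests against chance use the Bonferroni-adjusted threshold", {
  set.seed(45)
  d <- data.frame(
    group = rep(c("g1", "g2", "g3", "g4"), each = 12),
    score = c(
      rnorm(12, 0.5, 0.1), rnorm(12, 0.19, 0.05),
      rep(0.25, 12), rnorm(12, 0.25, 0.08)
    )
  )
  out <- test_against_chance(d, "score", "group",
    chance = c(g1 = 0.5, g2 = 0.1875, g3 = 0.25, g4 = 0.25)
  )
  expect_equal(unique(out$alpha_adj), 0.0125)
  # identically-at-chance scores are non-significant with p = 1
  expect_equal(out$p.value[out$group == "g3"], 1)
  expect_false(out$significant[out$group == "g3"])
  wil <- test_against_chance(d, "score", "group", chance = 0.25,
    method = "wilcoxon"
  )
  expect_true(all(wil$p.value >= 0 & wil$p.value <= 1))
  expect_equal(unique(wil$alpha_adj), 0.0125)
})

test_that("a knowledgeable fixed group is detected as above chance", {
  d <- srt_design("fixed", seed = 7)
  set.seed(46)
  detected <- vapply(1:40, function(r) {
    scores <- vapply(1:12, function(p) {
      pt <- simulate_posttest(d, 0.5, seed = sample.int(1e8, 1))
      score_posttest(dplyr::mutate(pt, participant = "x"), d)$recall_percent
    }, numeric(1))
    out <- test_against_chance(
      data.frame(group = "g", score = scores), "score", "group",
      chance = 0.1875, k = 4
    )
    out$significant
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("fuzzed inputs keep statistics non-negative and p in [0, 1]", {
  set.seed(47)
  for (r in 1:20) {
    d <- data.frame(
      a = sample(c("x", "y"), 24, replace = TRUE),
      b = rep(c("u", "v"), each = 12),
      y = sample(c(rnorm(20), rep(1.5, 4)))
    )
    cells <- table(d$a, d$b)
    if (any(cells < 2)) next
    srh <- tidy(scheirer_ray_hare(d, "y", c("a", "b")))
    expect_true(all(srh$statistic >= 0))
    expect_true(all(srh$p.value >= 0 & srh$p.value <= 1))
    aov2 <- tidy(two_way_anova(d, "y", c("a", "b")))
    expect_true(all(aov2$p.value >= 0 & aov2$p.value <= 1, na.rm = TRUE))
  }
})
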