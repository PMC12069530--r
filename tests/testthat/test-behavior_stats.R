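# binomial / chi-square / KS statistics against hand-computed oracles

test_that("binomial performance test matches the exact tail sum", {
  t <- make_hand_block()
  # 18 correct of 20 in a stratum, chance 0.5
  t20 <- t[t$scene_index %in% 1:2 & t$run_index <= 2, ]  # 8 rows: resize
  t20 <- t[1:20, ]
  t20$run_index <- 1L
  t20$stay_switch <- NA_character_
  t20$reward_size <- "small"
  t20$scene_index <- rep(1:5, 4)
  t20$correct <- c(rep(TRUE, 18), FALSE, FALSE)
  res <- performance_by_run_and_size(t20)
  row <- res[res$run_index == 1L & res$reward_size == "small", ]
  oracle <- sum(choose(20, 18:20)) / 2^20
  expect_equal(row$p_value, oracle, tolerance = 1e-12)
  expect_equal(row$k, 18)
  expect_equal(row$proportion, 0.9)

  # all 30 correct -> p = 2^-30
  t30 <- t
  t30$reward_size <- "medium"
  t30$run_index <- 1L
  t30$stay_switch <- NA_character_
  t30$trial_index_in_block <- 1:30
  res30 <- performance_by_run_and_size(t30)
  expect_equal(res30$p_value[res30$reward_size == "medium"], 2^-30,
               tolerance = 1e-12)

  # k = n/2 exactly -> p > 0.05; empty stratum -> NA, n = 0
  t20$correct <- rep(c(TRUE, FALSE), 10)
  res_half <- performance_by_run_and_size(t20)
  half <- res_half[res_half$reward_size == "small", ]
  expect_gt(half$p_value, 0.05)
  empty <- res_half[res_half$reward_size == "large", ]
  expect_identical(empty$n, 0L)
  expect_true(is.na(empty$p_value))
})

test_that("binomial p decreases in k at fixed n", {
  p <- vapply(10:20, function(k) {
    stats::binom.test(k, 20, 0.5, alternative = "greater")$p.value
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("chi-square comparison matches brute-force expected counts", {
  # (30/40) vs (15/40)
  obs <- rbind(c(30, 10), c(15, 25))
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  oracle <- sum((obs - expd)^2 / expd)
  res <- compare_proportions(30, 40, 15, 40)
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(oracle, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_false(res$zero_expected_cell)

  # identical proportions -> statistic 0, p 1; duplicated table likewise
  same <- compare_proportions(10, 20, 10, 20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # swapping groups leaves the statistic unchanged
  swap <- compare_proportions(15, 40, 30, 40)
  expect_equal(swap$statistic, res$statistic)

  # zero expected cell flagged, statistic still returned
  degen <- compare_proportions(0, 10, 0, 10)
  expect_true(degen$zero_expected_cell)
  expect_true(is.finite(degen$statistic))
})

test_that("switch proportions respect the outcome-filter partition", {
  s <- make_session(n_blocks = 40L, with_spikes = FALSE, seed = 12L)
  all_ <- switch_proportions(s$trials, "all")$proportions
  ac <- switch_proportions(s$trials, "after_correct")$proportions
  ai <- switch_proportions(s$trials, "after_incorrect")$proportions
  # after_correct + after_incorrect partition the all-trials counts
  expect_equal(ac$k + ai$k, all_$k)
  expect_equal(ac$n + ai$n, all_$n)
  # run-1 rows are excluded, not an error
  expect_true(all(all_$run_index >= 2))
  # a never-switching agent has switch proportion 0 everywhere
  sticky <- agent_params(stay_after_correct = c(small = 1, medium = 1,
                                                large = 1),
                         stay_after_incorrect = c(small = 1, medium = 1,
                                                  large = 1))
  d <- generate_block_design(task_design_params(n_blocks = 5L), seed = 1L)
  t2 <- simulate_behavior(d, sticky, seed = 2L)
  sw0 <- switch_proportions(t2)$proportions
  expect_true(all(sw0$proportion[sw0$n > 0] == 0))
})

test_that("switch proportion tracks a configured stay probability", {
  agent <- agent_params(stay_after_correct = c(small = 0.6, medium = 0.95,
                                               large = 0.95),
                        stay_after_incorrect = c(small = 0.6, medium = 0.15,
                                                 large = 0.15))
  d <- generate_block_design(task_design_params(n_blocks = 300L), seed = 8L)
  t <- simulate_behavior(d, agent, seed = 9L)
  sw <- switch_proportions(t)$proportions
  small <- sw[sw$reward_size == "small", ]
  pooled <- sum(small$k) / sum(small$n)
  se <- sqrt(0.4 * 0.6 / sum(small$n))
  expect_lt(abs(pooled - 0.4), 2.5 * se)
})

test_that("KS comparisons behave on trivial and analytic cases", {
  t <- make_hand_block()
  # identical samples -> statistic 0
  res <- compare_reaction_times(t)
  expect_true(all(res$statistic == 0))
  # disjoint supports -> statistic 1
  t2 <- t
  t2$reaction_time[t2$reward_size == "small"] <- 1:12
  t2$reaction_time[t2$reward_size != "small"] <- 100 + 1:18
  res2 <- compare_reaction_times(t2)
  sm <- res2[res2$group_a == "small" | res2$group_b == "small", ]
  expect_true(all(sm$statistic == 1))
  # two shifted log-normals: statistic near the analytic sup-CDF difference
  withr::with_seed(99, {
    n <- 500
    a <- stats::rlnorm(n, log(450), 0.2)
    b <- stats::rlnorm(n, log(380), 0.2)
    grid <- seq(200, 900, by = 0.5)
    analytic <- max(abs(stats::plnorm(grid, log(450), 0.2) -
                          stats::plnorm(grid, log(380), 0.2)))
    t3 <- t[rep(1, 2 * n), ]
    t3$reward_size <- rep(c("small", "medium"), each = n)
    t3$reaction_time <- c(a, b)
    res3 <- compare_reaction_times(t3)
    stat <- res3$statistic[res3$group_a == "medium" &
                             res3$group_b == "small"]
    se <- sqrt(1 / n)   # ~2 SE band for the two-sample KS statistic
    expect_lt(abs(stat - analytic), 2 * se)
  })
  # groups with < 2 observations are skipped with a warning
  t4 <- t
  t4$reaction_time[t4$reward_size == "large"] <- NA
  warns <- capture_warnings(compare_reaction_times(t4))
  expect_true(length(warns) > 0 && all(grepl("skipping", warns)))
})

test_that("per-day aggregation averages days without weighting", {
  prop_correct <- function(x) mean(x$correct)
  # single session: day mean equals pooled value
  s1 <- make_hand_block()
  s1$correct <- rep(c(TRUE, FALSE, TRUE), 10)
  agg1 <- aggregate_by_day(s1, prop_correct)
  expect_equal(agg1$mean, mean(s1$correct))
  # equal-n sessions with 0.4 and 0.6 -> day mean 0.5 = pooled
  a <- make_hand_block("day1")
  a$correct <- rep(c(TRUE, FALSE, FALSE, TRUE, FALSE), 6)  # 0.4
  b <- make_hand_block("day2")
  b$correct <- rep(c(TRUE, FALSE, TRUE, TRUE, FALSE), 6)   # 0.6
  agg2 <- aggregate_by_day(rbind(a, b), prop_correct)
  expect_equal(agg2$mean, 0.5)
  # unequal n: unweighted day mean differs from the pooled proportion
  big <- do.call(rbind, lapply(1:3, function(i) {
    x <- make_hand_block("day2", block = i)
    x$correct <- rep(c(TRUE, TRUE, TRUE, FALSE, TRUE), 6)  # 0.8, n = 90
    x
  }))
  small_day <- make_hand_block("day1")
  small_day$correct <- rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 6)  # 0.2
  both <- rbind(small_day, big)
  agg3 <- aggregate_by_day(both, prop_correct)
  expect_equal(agg3$mean, 0.5)
  pooled <- mean(both$correct)
  expect_equal(pooled, 0.65)
  expect_false(isTRUE(all.equal(agg3$mean, pooled)))
})

test_that("behavior_report emits every table with significance stars", {
  s <- make_session(n_blocks = 20L, with_spikes = FALSE, seed = 31L)
  rep_ <- behavior_report(s$trials)
  expect_named(rep_, c("performance", "performance_comparisons",
                       "switch_all", "switch_all_comparisons",
                       "switch_after_correct", "switch_after_incorrect",
                       "reaction_times"))
  expect_true(all(rep_$performance$stars %in%
                    c("", "ns", "*", "**", "***")))
  # small-reward RTs stochastically dominate: KS must flag small pairs
  rt <- rep_$reaction_times
  expect_true(all(rt$p_value[rt$group_a == "small" |
                               rt$group_b == "small"] < 0.05))
})
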