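# Behavioral analyses: learning curves vs chance, proportion comparisons,
# stay/switch proportions, reaction-time distribution tests, per-day
# aggregation.

#' Proportion of correct trials per run and reward size
#'
#' For each (run, reward size) stratum, the proportion of correct trials
#' with a one-sided exact binomial test against chance (0.5: two objects
#' per scene).
#'
#' @param trials a validated trial table (completed trials).
#' @param chance chance level of a single choice.
#' @return data.frame with one row per (run, reward size): `k`, `n`,
#'   `proportion`, `p_value` (one-sided exact binomial; `NA` when `n = 0`),
#'   `test`.
#' @export
performance_by_run_and_size <- function(trials, chance = 0.5) {
  grid <- expand.grid(run_index = sort(unique(trials$run_index)),
                      reward_size = reward_levels(),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- trials[trials$run_index == grid$run_index[i] &
                    trials$reward_size == grid$reward_size[i], , drop = FALSE]
    k <- sum(sub$correct)
    n <- nrow(sub)
    p <- if (n == 0L) NA_real_ else
      stats::binom.test(k, n, p = chance,
                        alternative = "greater")$p.value
    data.frame(run_index = grid$run_index[i],
               reward_size = grid$reward_size[i],
               k = k, n = n,
               proportion = if (n == 0L) NA_real_ else k / n,
               p_value = p, test = "binomial_one_sided",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Chi-square comparison of two proportions
#'
#' 2x2 chi-square test (without Yates continuity correction by default) of
#' `kA/nA` against `kB/nB`, the test used for all pairwise comparisons of
#' correct- and switch-trial proportions.
#'
#' @param kA,nA,kB,nB successes and totals of the two groups (`n > 0`).
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df`, `expected`, and
#'   `zero_expected_cell` (flag; the statistic is still computed over the
#'   non-degenerate cells).
#' @export
compare_proportions <- function(kA, nA, kB, nB, correct = FALSE) {
  stopifnot(nA > 0, nB > 0, kA >= 0, kB >= 0, kA <= nA, kB <= nB)
  obs <- rbind(c(kA, nA - kA), c(kB, nB - kB))
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  zero <- any(expd == 0)
  if (!zero) {
    ct <- suppressWarnings(stats::chisq.test(obs, correct = correct))
    stat <- unname(ct$statistic)
    p <- ct$p.value
  } else {
    ok <- expd > 0
    adj <- if (correct) pmax(abs(obs - expd) - 0.5, 0) else abs(obs - expd)
    stat <- sum(adj[ok]^2 / expd[ok])
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, df = 1L, expected = expd,
       zero_expected_cell = zero)
}

# previous-run correctness of the same scene, aligned to rows of `trials`
previous_run_correct_ <- function(trials) {
  key <- paste(trials$session_id, trials$block_index, trials$scene_index,
               trials$run_index)
  prev_key <- paste(trials$session_id, trials$block_index,
                    trials$scene_index, trials$run_index - 1L)
  trials$correct[match(prev_key, key)]
}

#' Switch proportions per run and reward size
#'
#' Proportion of switch trials (chosen object differs from the choice for
#' the same scene in the previous run) per (run 2-6, reward size), with all
#' pairwise chi-square comparisons between reward sizes within each run.
#' The outcome filter conditions on whether the same scene's previous-run
#' choice was correct.
#'
#' @param trials a validated trial table; run-1 rows are excluded (not an
#'   error).
#' @param outcome_filter `"all"`, `"after_correct"` or `"after_incorrect"`.
#' @return list with `proportions` (data.frame per run x size: `k` switch
#'   trials, `n`, `proportion`) and `comparisons` (pairwise chi-square per
#'   run).
#' @export
switch_proportions <- function(trials,
                               outcome_filter = c("all", "after_correct",
                                                  "after_incorrect")) {
  outcome_filter <- match.arg(outcome_filter)
  prev_all <- previous_run_correct_(trials)  # needs run-1 rows present
  keep <- trials$run_index >= 2L & !is.na(trials$stay_switch)
  sub <- trials[keep, , drop = FALSE]
  prev_ok <- prev_all[keep]
  if (outcome_filter == "after_correct") {
    sub <- sub[!is.na(prev_ok) & prev_ok, , drop = FALSE]
  } else if (outcome_filter == "after_incorrect") {
    sub <- sub[!is.na(prev_ok) & !prev_ok, , drop = FALSE]
  }
  grid <- expand.grid(run_index = 2:6, reward_size = reward_levels(),
                      stringsAsFactors = FALSE)
  props <- lapply(seq_len(nrow(grid)), function(i) {
    s <- sub[sub$run_index == grid$run_index[i] &
               sub$reward_size == grid$reward_size[i], , drop = FALSE]
    k <- sum(s$stay_switch == "switch")
    n <- nrow(s)
    data.frame(run_index = grid$run_index[i],
               reward_size = grid$reward_size[i], k = k, n = n,
               proportion = if (n == 0L) NA_real_ else k / n,
               outcome_filter = outcome_filter, stringsAsFactors = FALSE)
  })
  props <- do.call(rbind, props)
  pairs <- utils::combn(reward_levels(), 2L)
  comps <- list()
  for (run in 2:6) {
    for (j in seq_len(ncol(pairs))) {
      a <- props[props$run_index == run & props$reward_size == pairs[1, j], ]
      b <- props[props$run_index == run & props$reward_size == pairs[2, j], ]
      if (a$n == 0L || b$n == 0L) next
      cmp <- compare_proportions(a$k, a$n, b$k, b$n)
      comps[[length(comps) + 1L]] <-
        data.frame(run_index = run, size_a = pairs[1, j],
                   size_b = pairs[2, j], statistic = cmp$statistic,
                   p_value = cmp$p_value, stringsAsFactors = FALSE)
    }
  }
  list(proportions = props,
       comparisons = if (length(comps)) do.call(rbind, comps) else NULL)
}

#' Pairwise Kolmogorov-Smirnov comparison of reaction times
#'
#' Two-sided two-sample KS tests of the reaction-time distributions for
#' each pair of reward sizes (asymptotic p by default).
#'
#' @param trials a validated trial table.
#' @param grouping column to group by (default `reward_size`).
#' @param exact use the exact KS p-value (small samples).
#' @return data.frame with one row per group pair: `statistic`, `p_value`,
#'   group sizes; pairs with fewer than 2 observations in a group are
#'   skipped with a warning.
#' @export
compare_reaction_times <- function(trials, grouping = "reward_size",
                                   exact = FALSE) {
  groups <- split(trials$reaction_time, trials[[grouping]])
  groups <- lapply(groups, function(x) x[!is.na(x)])
  nms <- names(groups)
  pairs <- utils::combn(nms, 2L)
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- groups[[pairs[1, j]]]
    b <- groups[[pairs[2, j]]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("group with < 2 observations: skipping ",
              pairs[1, j], " vs ", pairs[2, j], call. = FALSE)
      next
    }
    ks <- suppressWarnings(stats::ks.test(a, b, exact = exact))
    out[[length(out) + 1L]] <-
      data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                 n_a = length(a), n_b = length(b),
                 statistic = unname(ks$statistic), p_value = ks$p.value,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-day aggregation of a behavioral statistic
#'
#' Evaluates a statistic separately for each recording day (session) and
#' averages the per-day values without weighting, the robustness variant of
#' the pooled analyses.
#'
#' @param trials a validated trial table.
#' @param statistic function taking a trial-table subset and returning a
#'   single numeric value.
#' @return list with `per_day` (data.frame session_id, value) and `mean`
#'   (unweighted mean over days).
#' @export
aggregate_by_day <- function(trials, statistic) {
  stopifnot(is.function(statistic))
  sessions <- split(trials, trials$session_id)
  vals <- vapply(sessions, statistic, numeric(1))
  list(per_day = data.frame(session_id = names(vals), value = unname(vals),
                            stringsAsFactors = FALSE),
       mean = mean(vals))
}

#' Run the full set of behavioral statistics
#'
#' Convenience bundle: performance vs chance, pairwise performance
#' comparisons, switch proportions (all / after-correct / after-incorrect)
#' and reaction-time KS tests, in tidy data.frames with significance stars.
#'
#' @param trials a validated trial table.
#' @return named list of data.frames.
#' @export
behavior_report <- function(trials) {
  perf <- performance_by_run_and_size(trials)
  perf$stars <- p_stars_(perf$p_value)
  perf_cmp <- list()
  pairs <- utils::combn(reward_levels(), 2L)
  for (run in sort(unique(trials$run_index))) {
    for (j in seq_len(ncol(pairs))) {
      a <- perf[perf$run_index == run & perf$reward_size == pairs[1, j], ]
      b <- perf[perf$run_index == run & perf$reward_size == pairs[2, j], ]
      if (a$n == 0L || b$n == 0L) next
      cmp <- compare_proportions(a$k, a$n, b$k, b$n)
      perf_cmp[[length(perf_cmp) + 1L]] <-
        data.frame(run_index = run, size_a = pairs[1, j],
                   size_b = pairs[2, j], statistic = cmp$statistic,
                   p_value = cmp$p_value, stars = p_stars_(cmp$p_value),
                   stringsAsFactors = FALSE)
    }
  }
  sw <- switch_proportions(trials, "all")
  sw_c <- switch_proportions(trials, "after_correct")
  sw_i <- switch_proportions(trials, "after_incorrect")
  rt <- compare_reaction_times(trials)
  rt$stars <- p_stars_(rt$p_value)
  list(performance = perf,
       performance_comparisons = do.call(rbind, perf_cmp),
       switch_all = sw$proportions, switch_all_comparisons = sw$comparisons,
       switch_after_correct = sw_c$proportions,
       switch_after_incorrect = sw_i$proportions,
       reaction_times = rt)
}

p_stars_ <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}
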