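# Per-neuron confound controls: OLS variance partitioning between the
# reaction-movement time and reward size, and the feedback shape/color
# selectivity ANOVA.

#' Variance partition between motor and reward regressors
#'
#' Ordinary-least-squares fit of
#' `rate ~ rt_movement + reward_size + rt_movement:reward_size` for one
#' neuron and epoch, followed by an ANOVA converting sums of squares to the
#' percentage of total variance explained by each term, plus the
#' full-model-vs-null F test. Sequential (Type I) sums of squares with the
#' reaction-movement time entered first are the default — conservative for
#' the claim that reward size dominates; Type II is available.
#'
#' @param rate per-trial firing rate of the neuron in the epoch window.
#' @param rt_movement per-trial reaction-movement time (go signal to
#'   peripheral-target touch, ms).
#' @param reward_size per-trial reward size (all three levels present).
#' @param type `"I"` (sequential) or `"II"` (requires the car package).
#' @param min_trials minimum trials required for the fit.
#' @param neuron_id,epoch labels carried into the result.
#' @return one-row data.frame: percent variance explained by
#'   `rt_movement`, `reward_size` and their interaction, per-term p-values,
#'   full-model p-value and significance flag, and a `rank_deficient` flag
#'   (terms `NA` when set).
#' @export
variance_partition <- function(rate, rt_movement, reward_size, type = "I",
                               min_trials = 10L,
                               neuron_id = NA_character_,
                               epoch = NA_character_) {
  stopifnot(length(rate) == length(rt_movement),
            length(rate) == length(reward_size))
  if (length(rate) < min_trials) {
    stop("need >= ", min_trials, " trials for the per-neuron linear model",
         call. = FALSE)
  }
  reward_size <- factor(reward_size, levels = reward_levels())
  if (any(table(reward_size) == 0L)) {
    stop("all three reward sizes must be present", call. = FALSE)
  }
  df <- data.frame(rate = rate, rt = rt_movement, size = reward_size)
  fit <- stats::lm(rate ~ rt + size + rt:size, data = df)
  rank_def <- any(is.na(stats::coef(fit)))
  if (rank_def) {
    return(data.frame(neuron_id = neuron_id, epoch = epoch,
                      pct_rt = NA_real_, pct_size = NA_real_,
                      pct_interaction = NA_real_, p_rt = NA_real_,
                      p_size = NA_real_, p_interaction = NA_real_,
                      p_full = NA_real_, full_significant = NA,
                      rank_deficient = TRUE, stringsAsFactors = FALSE))
  }
  an <- if (type == "II") {
    if (!requireNamespace("car", quietly = TRUE)) {
      stop("type II requires the car package", call. = FALSE)
    }
    car::Anova(fit, type = 2)
  } else {
    stats::anova(fit)
  }
  ss <- an[["Sum Sq"]]
  terms <- rownames(an)
  total_ss <- sum((rate - mean(rate))^2)
  pct <- 100 * ss / total_ss
  pval <- an[["Pr(>F)"]]
  pick <- function(pat) {
    i <- grep(pat, terms)
    c(pct = if (length(i)) pct[i[1]] else NA_real_,
      p = if (length(i)) pval[i[1]] else NA_real_)
  }
  rt_row <- pick("^rt$")
  size_row <- pick("^size$")
  int_row <- pick(":")
  fstat <- summary(fit)$fstatistic
  p_full <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  data.frame(neuron_id = neuron_id, epoch = epoch,
             pct_rt = unname(rt_row["pct"]),
             pct_size = unname(size_row["pct"]),
             pct_interaction = unname(int_row["pct"]),
             p_rt = unname(rt_row["p"]), p_size = unname(size_row["p"]),
             p_interaction = unname(int_row["p"]),
             p_full = unname(p_full),
             full_significant = unname(p_full < 0.05),
             rank_deficient = FALSE, stringsAsFactors = FALSE)
}

#' Variance partition for a whole population
#'
#' Applies [variance_partition()] neuron by neuron on an epoch rate matrix.
#'
#' @param rates matrix `n_neurons x n_trials` (e.g. from [epoch_rates()]).
#' @param rt_movement,reward_size per-trial regressors.
#' @param epoch epoch label.
#' @param type sum-of-squares type.
#' @return data.frame with one row per neuron plus summary attributes.
#' @export
population_variance_partition <- function(rates, rt_movement, reward_size,
                                          epoch = "epoch", type = "I") {
  out <- do.call(rbind, lapply(seq_len(nrow(rates)), function(i) {
    variance_partition(rates[i, ], rt_movement, reward_size, type = type,
                       neuron_id = as.character(i), epoch = epoch)
  }))
  out
}

#' Feedback visual-property selectivity (one-way ANOVA)
#'
#' Tests, neuron by neuron, whether firing in the feedback window
#' (feedback onset to +400 ms) depends on a visual property of the feedback
#' stimulus (shape or color), separately within correct and incorrect
#' trials. Reports the fraction of selective neurons (p < 0.05), which on a
#' property-blind population should sit at the nominal 5% false-positive
#' rate.
#'
#' @param rates matrix `n_neurons x n_trials` of feedback-window rates.
#' @param property per-trial property labels.
#' @param split optional logical per-trial filter (e.g. `trials$correct`);
#'   `NULL` uses all trials.
#' @param alpha selectivity threshold.
#' @return list: `per_neuron` (data.frame neuron, p, selective; `NA` for
#'   skipped neurons), `n_tested`, `n_selective`, `fraction_selective`.
#' @export
feedback_property_anova <- function(rates, property, split = NULL,
                                    alpha = 0.05) {
  stopifnot(is.matrix(rates), length(property) == ncol(rates))
  keep <- if (is.null(split)) rep(TRUE, ncol(rates)) else split
  keep <- keep & !is.na(property)
  prop <- factor(property[keep])
  p <- vapply(seq_len(nrow(rates)), function(i) {
    y <- rates[i, keep]
    if (any(table(prop) < 2L)) return(NA_real_)
    ss_total <- sum((y - mean(y))^2)
    if (ss_total == 0) return(1)          # identical rates: F = 0, p = 1
    an <- stats::anova(stats::lm(y ~ prop))
    an[["Pr(>F)"]][1]
  }, numeric(1))
  tested <- !is.na(p)
  sel <- tested & p < alpha
  list(per_neuron = data.frame(neuron = seq_len(nrow(rates)), p_value = p,
                               selective = ifelse(tested, sel, NA)),
       n_tested = sum(tested), n_selective = sum(sel),
       fraction_selective = if (any(tested)) sum(sel) / sum(tested)
                            else NA_real_)
}
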