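# Time-resolved pseudo-population decoding with linear SVMs, label-shuffle
# null distributions, sliding trial-window decoding, and balanced-sampling
# decoding that decorrelates confounded task variables.

#' Linear-SVM decoder specification
#'
#' @param cost SVM regularization constant C (> 0).
#' @param k cross-validation folds (>= 2).
#' @param n_resamples pseudo-population resamples averaged per time bin.
#' @param scheme multi-class scheme: `"ovr"` (one-vs-rest, default) or
#'   `"ovo"` (one-vs-one, libsvm's native scheme).
#' @return list of class `decoder_spec`.
#' @export
decoder_spec <- function(cost = 1, k = 10L, n_resamples = 50L,
                         scheme = c("ovr", "ovo")) {
  scheme <- match.arg(scheme)
  stopifnot(cost > 0, k >= 2L, n_resamples >= 1L)
  structure(list(cost = cost, k = as.integer(k),
                 n_resamples = as.integer(n_resamples), scheme = scheme),
            class = "decoder_spec")
}

# train a linear SVM on columns of Xtr and predict labels of Xte columns
svm_train_predict_ <- function(Xtr, ytr, Xte, scheme, cost) {
  ytr <- factor(ytr)
  lv <- levels(ytr)
  if (length(lv) == 2L || scheme == "ovo") {
    m <- e1071::svm(t(Xtr), ytr, kernel = "linear", cost = cost,
                    scale = FALSE)
    as.character(stats::predict(m, t(Xte)))
  } else {
    dv <- vapply(lv, function(l) {
      y2 <- factor(ifelse(ytr == l, "pos", "neg"),
                   levels = c("pos", "neg"))
      m <- e1071::svm(t(Xtr), y2, kernel = "linear", cost = cost,
                      scale = FALSE)
      p <- stats::predict(m, t(Xte), decision.values = TRUE)
      d <- attr(p, "decision.values")
      # libsvm signs the decision value by order of appearance in the
      # training data, not by factor level: flip when "neg" came first
      if (colnames(d)[1] == "neg/pos") -drop(d) else drop(d)
    }, numeric(ncol(Xte)))
    if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1L)
    lv[max.col(dv)]
  }
}

# k-fold cross-validated accuracy on one population matrix
cv_accuracy_ <- function(x, col_labels, fold, k, scheme, cost) {
  acc <- numeric(k)
  for (f in seq_len(k)) {
    z <- zscore_by_train(x, col_labels, fold, f, mode = "all")
    pred <- svm_train_predict_(z$train, col_labels[z$train_cols], z$test,
                               scheme, cost)
    acc[f] <- mean(pred == col_labels[z$test_cols])
  }
  mean(acc)
}

#' Time-resolved pseudo-population decoding
#'
#' For each time bin, the mean over `n_resamples` pseudo-population
#' resamples of the k-fold cross-validated linear-SVM accuracy. One trial
#' sample is drawn per resample and shared across bins; z-scoring uses
#' training-fold statistics only.
#'
#' @param binned a `binned_activity`.
#' @param labels per-trial condition labels (`NA` trials are never sampled).
#' @param spec a [decoder_spec()].
#' @param n_per_condition trials sampled per condition per neuron (60 for
#'   the three-class reward decoding, 25 for stay/switch).
#' @param neurons,available see [select_eligible_neurons()].
#' @param bins bin indices to decode (default all).
#' @param seed integer seed.
#' @return object of class `decoding_result`: `mean_accuracy` and
#'   `sd_accuracy` per bin, `accuracy` (resamples x bins), `chance`,
#'   `bin_centers`, `conditions`, `spec`.
#' @export
decode_timecourse <- function(binned, labels, spec = decoder_spec(),
                              n_per_condition = 60L, neurons = NULL,
                              available = NULL, bins = NULL, seed = NULL) {
  stopifnot(inherits(binned, "binned_activity"),
            inherits(spec, "decoder_spec"))
  if (is.null(bins)) bins <- seq_along(binned$bin_centers)
  conds <- sort(unique(labels[!is.na(labels)]))
  if (length(conds) < 2L) stop("need >= 2 labels", call. = FALSE)
  with_seed_(seed, {
    acc <- matrix(NA_real_, nrow = spec$n_resamples, ncol = length(bins))
    for (r in seq_len(spec$n_resamples)) {
      smp <- assemble_sample(binned, labels, n_per_condition,
                             neurons = neurons, available = available)
      smp <- assign_folds(smp, spec$k)
      for (bi in seq_along(bins)) {
        x <- sample_matrix(binned, smp, bins[bi])
        acc[r, bi] <- cv_accuracy_(x, smp$col_labels, smp$fold, spec$k,
                                   spec$scheme, spec$cost)
      }
    }
    structure(list(mean_accuracy = colMeans(acc),
                   sd_accuracy = apply(acc, 2, stats::sd),
                   accuracy = acc,
                   chance = 1 / length(conds),
                   bin_centers = binned$bin_centers[bins],
                   conditions = conds, spec = spec),
              class = "decoding_result")
  })
}

#' Label-shuffle null model for time-resolved decoding
#'
#' Repeats the full decoding procedure with trial labels randomly permuted
#' (`n_shuffles` times); for each shuffle and bin the across-resample
#' average accuracy is kept, and all `n_shuffles x n_bins` values are
#' pooled into one null distribution. The Bonferroni-corrected alpha is
#' `0.05 / (n_bins * n_shuffles)` (with the reference 63 bins and 20
#' shuffles: 1260 values, alpha ~ 3.96e-5).
#'
#' @inheritParams decode_timecourse
#' @param n_shuffles label shuffles (>= 2).
#' @return object of class `null_model`: `values` (pooled), `n_shuffles`,
#'   `n_bins`, `alpha`, `mean`, `sd`.
#' @export
build_null <- function(binned, labels, spec = decoder_spec(),
                       n_per_condition = 60L, neurons = NULL,
                       available = NULL, bins = NULL, n_shuffles = 20L,
                       seed = NULL) {
  if (n_shuffles < 2L) {
    stop("parameter error: n_shuffles must be >= 2", call. = FALSE)
  }
  if (is.null(bins)) bins <- seq_along(binned$bin_centers)
  labeled <- which(!is.na(labels))
  with_seed_(seed, {
    vals <- matrix(NA_real_, nrow = n_shuffles, ncol = length(bins))
    for (s in seq_len(n_shuffles)) {
      shuf <- labels
      shuf[labeled] <- sample(labels[labeled])
      res <- decode_timecourse(binned, shuf, spec, n_per_condition,
                               neurons = neurons, available = available,
                               bins = bins)
      vals[s, ] <- res$mean_accuracy
    }
    pooled <- as.vector(vals)
    structure(list(values = pooled, n_shuffles = n_shuffles,
                   n_bins = length(bins),
                   alpha = 0.05 / (length(bins) * n_shuffles),
                   mean = mean(pooled), sd = stats::sd(pooled)),
              class = "null_model")
  })
}

#' Assess decoding significance against a shuffle null
#'
#' Each bin's observed accuracy is z-scored against the pooled null;
#' one-sided p-values come either from the Gaussian tail of the z-score
#' (`p_method = "gaussian"`, default — the only definition able to reach
#' the Bonferroni-corrected alpha with a finite null) or from the
#' +1-corrected empirical exceedance proportion
#' `(1 + #\{null >= observed\}) / (1 + N)`. Bins with `p <= alpha` pass;
#' the final mask keeps only runs of at least `min_consecutive` passing
#' bins.
#'
#' @param result a `decoding_result`.
#' @param null a `null_model` built from matching inputs.
#' @param min_consecutive run-length rule (reference analyses use 5).
#' @param alpha significance threshold; defaults to the null's
#'   Bonferroni-corrected alpha.
#' @param p_method `"gaussian"` or `"empirical"`.
#' @return data.frame per bin: `bin_center`, `accuracy`, `z`, `p_value`,
#'   `pass`, `significant` (after the consecutive-bin rule); the `alpha`
#'   used is attached as an attribute.
#' @export
assess_significance <- function(result, null, min_consecutive = 5L,
                                alpha = NULL,
                                p_method = c("gaussian", "empirical")) {
  stopifnot(inherits(result, "decoding_result"),
            inherits(null, "null_model"))
  p_method <- match.arg(p_method)
  if (length(null$values) == 0L) stop("empty null", call. = FALSE)
  if (is.null(alpha)) alpha <- null$alpha
  obs <- result$mean_accuracy
  z <- (obs - null$mean) / null$sd
  p <- if (p_method == "gaussian") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    vapply(obs, function(a) {
      (1 + sum(null$values >= a)) / (1 + length(null$values))
    }, numeric(1))
  }
  pass <- p <= alpha
  out <- data.frame(bin_center = result$bin_centers, accuracy = obs,
                    z = z, p_value = p, pass = pass,
                    significant = consecutive_mask_(pass, min_consecutive))
  attr(out, "alpha") <- alpha
  attr(out, "p_method") <- p_method
  out
}

#' Sliding trial-window decoding within blocks
#'
#' Decodes within a moving window of `window` trials per block (window w
#' pools trials w..w+window-1 of every complete block), moved in steps of
#' `step` trials — 21 windows for the 30-trial block with the defaults.
#' Each window gets its own shuffle null and consecutive-bin significance,
#' visualizable as a windows x bins heatmap.
#'
#' @inheritParams decode_timecourse
#' @param trials the trial table matching `binned` (rows parallel to the
#'   trial dimension); incomplete blocks are dropped.
#' @param window,step window length and step in trials.
#' @param n_per_condition trials per condition sampled within each window
#'   (the reference uses 20, requiring >= 20 per condition in every
#'   window).
#' @param n_shuffles shuffles per window for the null.
#' @param min_consecutive consecutive-bin rule within a window.
#' @return object of class `sliding_window_result`: `accuracy` and
#'   `significant` matrices (`n_windows x n_bins`), `window_start`,
#'   `bin_centers`, per-window null summaries.
#' @export
sliding_window_decode <- function(binned, trials, labels, window = 10L,
                                  step = 1L, spec = decoder_spec(),
                                  n_per_condition = 20L, neurons = NULL,
                                  available = NULL, bins = NULL,
                                  n_shuffles = 20L, min_consecutive = 5L,
                                  seed = NULL) {
  stopifnot(nrow(trials) == dim(binned$counts)[2])
  bkey <- paste(trials$session_id, trials$block_index)
  bn <- table(bkey)
  keep <- bkey %in% names(bn)[bn == 30L]
  if (!any(keep)) stop("no complete blocks", call. = FALSE)
  if (is.null(bins)) bins <- seq_along(binned$bin_centers)
  n_block_trials <- 30L
  starts <- seq(1L, n_block_trials - window + 1L, by = step)
  with_seed_(seed, {
    acc <- matrix(NA_real_, nrow = length(starts), ncol = length(bins))
    sig <- matrix(FALSE, nrow = length(starts), ncol = length(bins))
    nulls <- vector("list", length(starts))
    for (wi in seq_along(starts)) {
      w <- starts[wi]
      in_win <- keep & trials$trial_index_in_block %in% (w:(w + window - 1L))
      idx <- which(in_win)
      sub <- subset_binned_(binned, idx)
      sub_labels <- labels[idx]
      sub_avail <- if (is.null(available)) NULL else
        available[, idx, drop = FALSE]
      counts <- table(sub_labels[!is.na(sub_labels)])
      if (any(counts < n_per_condition)) {
        stop("eligibility error: window ", w, " has only ",
             min(counts), " trials for condition '",
             names(counts)[which.min(counts)], "' (need ",
             n_per_condition, ")", call. = FALSE)
      }
      res <- decode_timecourse(sub, sub_labels, spec, n_per_condition,
                               neurons = neurons, available = sub_avail,
                               bins = bins)
      null <- build_null(sub, sub_labels, spec, n_per_condition,
                         neurons = neurons, available = sub_avail,
                         bins = bins, n_shuffles = n_shuffles)
      sg <- assess_significance(res, null, min_consecutive)
      acc[wi, ] <- res$mean_accuracy
      sig[wi, ] <- sg$significant
      nulls[[wi]] <- list(mean = null$mean, sd = null$sd,
                          alpha = null$alpha)
    }
    structure(list(accuracy = acc, significant = sig,
                   window_start = starts,
                   bin_centers = binned$bin_centers[bins],
                   window = window, step = step, nulls = nulls),
              class = "sliding_window_result")
  })
}

# restrict a binned_activity to a subset of trials
subset_binned_ <- function(binned, trial_idx) {
  out <- binned
  out$counts <- binned$counts[, trial_idx, , drop = FALSE]
  out
}

#' Balanced-sampling decoding of two correlated variables
#'
#' Decodes each of two binary task variables (reward grouped as small vs
#' medium+large; action stay vs switch) from activity in a single time bin,
#' with training and test sets containing equal counts of every (A x B)
#' cell. The balancing breaks the behavioral correlation between the
#' variables, so each variable is decoded free of the other's contribution;
#' chance is exactly 50% for both. Significance comes from a label-shuffle
#' null (`p = (1 + #\{shuffled >= observed\}) / (1 + n_shuffles)`).
#'
#' @param x matrix `n_neurons x n_trials` of activity in the decoded bin
#'   (the reference bin is 800-1000 ms after scene onset; see
#'   [epoch_rates()]).
#' @param labels_a,labels_b per-trial binary labels (`NA` trials dropped).
#' @param split training fraction of each cell (70/30 by default).
#' @param folds repetitions of the random split (tenfold by default).
#' @param min_per_cell eligibility: trials required in every (A x B) cell.
#' @param n_shuffles label shuffles for the null (25 by default).
#' @param cost SVM cost.
#' @param available optional per-neuron availability matrix.
#' @param seed integer seed.
#' @return object of class `balanced_decoding_result`: for each variable,
#'   `accuracy`, `null` values, `p_value`, `stars`; plus `chance = 0.5`,
#'   `n_per_cell`, `neurons` used.
#' @export
balanced_decode <- function(x, labels_a, labels_b, split = 0.7,
                            folds = 10L, min_per_cell = 10L,
                            n_shuffles = 25L, cost = 1,
                            available = NULL, seed = NULL) {
  stopifnot(is.matrix(x), length(labels_a) == ncol(x),
            length(labels_b) == ncol(x), split > 0, split < 1)
  ok <- !is.na(labels_a) & !is.na(labels_b)
  x <- x[, ok, drop = FALSE]
  a <- as.character(labels_a[ok])
  b <- as.character(labels_b[ok])
  if (length(unique(a)) != 2L || length(unique(b)) != 2L) {
    stop("both variables must be binary", call. = FALSE)
  }
  if (is.null(available)) {
    available <- matrix(TRUE, nrow(x), ncol(x))
  } else {
    available <- available[, ok, drop = FALSE]
  }
  cell <- paste(a, b, sep = "|")
  cells <- sort(unique(cell))
  if (length(cells) < 4L) {
    stop("empty (A x B) cell: balancing impossible", call. = FALSE)
  }
  # eligibility per neuron: >= min_per_cell available trials in every cell
  elig <- vapply(seq_len(nrow(x)), function(i) {
    all(vapply(cells, function(cc) sum(available[i, ] & cell == cc),
               numeric(1)) >= min_per_cell)
  }, logical(1))
  if (!any(elig)) stop("no eligible neurons", call. = FALSE)
  neurons <- which(elig)
  m <- min(vapply(neurons, function(i) {
    min(vapply(cells, function(cc) sum(available[i, ] & cell == cc),
               numeric(1)))
  }, numeric(1)))
  with_seed_(seed, {
    # pseudo-population: m columns per cell, sampled per neuron
    col_cell <- rep(cells, each = m)
    pop <- matrix(0, nrow = length(neurons), ncol = length(col_cell))
    for (r in seq_along(neurons)) {
      i <- neurons[r]
      for (ci in seq_along(cells)) {
        pool <- which(available[i, ] & cell == cells[ci])
        cols <- (ci - 1L) * m + seq_len(m)
        pop[r, cols] <- x[i, sample(pool, m)]
      }
    }
    col_a <- sub("\\|.*$", "", col_cell)
    col_b <- sub("^.*\\|", "", col_cell)
    n_tr <- max(1L, min(m - 1L, round(split * m)))
    run_once <- function(lab_a, lab_b) {
      acc <- matrix(NA_real_, folds, 2L)
      for (f in seq_len(folds)) {
        tr <- unlist(lapply(seq_along(cells), function(ci) {
          (ci - 1L) * m + sample(m, n_tr)
        }))
        te <- setdiff(seq_along(col_cell), tr)
        mu <- rowMeans(pop[, tr, drop = FALSE])
        sdv <- row_sds_(pop[, tr, drop = FALSE])
        sdv[sdv == 0 | !is.finite(sdv)] <- Inf
        ztr <- (pop[, tr, drop = FALSE] - mu) / sdv
        zte <- (pop[, te, drop = FALSE] - mu) / sdv
        pa <- svm_train_predict_(ztr, lab_a[tr], zte, "ovo", cost)
        pb <- svm_train_predict_(ztr, lab_b[tr], zte, "ovo", cost)
        acc[f, ] <- c(mean(pa == lab_a[te]), mean(pb == lab_b[te]))
      }
      colMeans(acc)
    }
    obs <- run_once(col_a, col_b)
    null <- matrix(NA_real_, n_shuffles, 2L)
    for (s in seq_len(n_shuffles)) {
      null[s, ] <- run_once(sample(col_a), sample(col_b))
    }
    p <- vapply(1:2, function(v) {
      (1 + sum(null[, v] >= obs[v])) / (1 + n_shuffles)
    }, numeric(1))
    structure(list(
      variable_a = list(accuracy = obs[1], null = null[, 1],
                        p_value = p[1], stars = p_stars_(p[1])),
      variable_b = list(accuracy = obs[2], null = null[, 2],
                        p_value = p[2], stars = p_stars_(p[2])),
      chance = 0.5, n_per_cell = m, n_train_per_cell = n_tr,
      neurons = neurons),
      class = "balanced_decoding_result")
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result>", length(x$bin_centers), "bins,",
      nrow(x$accuracy), "resamples; chance", signif(x$chance, 3),
      "; peak accuracy", signif(max(x$mean_accuracy), 3), "\n")
  invisible(x)
}

#' @export
print.balanced_decoding_result <- function(x, ...) {
  cat("<balanced_decoding_result> chance 50%\n",
      " variable A: accuracy", signif(100 * x$variable_a$accuracy, 4),
      "% , p =", signif(x$variable_a$p_value, 3), x$variable_a$stars, "\n",
      " variable B: accuracy", signif(100 * x$variable_b$accuracy, 4),
      "% , p =", signif(x$variable_b$p_value, 3), x$variable_b$stars, "\n")
  invisible(x)
}
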