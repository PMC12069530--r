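# Pseudo-population assembly: label-balanced trial resampling per neuron,
# stratified folds, and leakage-free z-scoring. Substrate of all decoding
# and geometry stages.

#' Select neurons eligible for pseudo-population analyses
#'
#' A neuron is eligible when it has at least `min_trials_per_condition`
#' labeled trials for every condition. Per-neuron availability (neurons
#' recorded for different subsets of trials) is expressed with a logical
#' `available` matrix.
#'
#' @param binned a `binned_activity`.
#' @param labels per-trial condition labels (`NA` = trial unlabeled, e.g.
#'   run-1 trials for stay/switch).
#' @param min_trials_per_condition eligibility threshold (the reference
#'   analyses use 60 trials per reward condition, 25 per action condition,
#'   20 per condition within sliding trial windows).
#' @param available optional logical matrix `n_neurons x n_trials`; default
#'   all `TRUE`.
#' @return integer indices of eligible neurons (named by neuron id).
#' @export
select_eligible_neurons <- function(binned, labels,
                                    min_trials_per_condition,
                                    available = NULL) {
  stopifnot(inherits(binned, "binned_activity"))
  n_neurons <- dim(binned$counts)[1]
  n_trials <- dim(binned$counts)[2]
  stopifnot(length(labels) == n_trials)
  if (is.null(available)) {
    available <- matrix(TRUE, n_neurons, n_trials)
  }
  stopifnot(dim(available)[1] == n_neurons, dim(available)[2] == n_trials)
  conds <- sort(unique(labels[!is.na(labels)]))
  ok <- vapply(seq_len(n_neurons), function(i) {
    counts <- vapply(conds, function(cc) {
      sum(available[i, ] & !is.na(labels) & labels == cc)
    }, numeric(1))
    all(counts >= min_trials_per_condition)
  }, logical(1))
  idx <- which(ok)
  names(idx) <- binned$neuron_ids[idx]
  idx
}

#' Assemble one pseudo-population sample
#'
#' For each neuron and condition, samples `n_per_condition` of its labeled
#' trials uniformly without replacement, independently across neurons
#' (pseudo-simultaneity: column j of condition c pairs the j-th draw of
#' every neuron). A fresh sample is drawn per resample; across resamples
#' trials are re-drawn with replacement of the pool.
#'
#' @inheritParams select_eligible_neurons
#' @param n_per_condition trials sampled per condition per neuron.
#' @param neurons indices of (eligible) neurons; default all.
#' @param seed integer seed (optional).
#' @return an object of class `pseudo_sample`: `index` (matrix
#'   `n_neurons x (n_conditions * n_per_condition)` of trial indices),
#'   `col_labels`, `conditions`, `neurons`, `fold` (`NULL` until
#'   [assign_folds()]).
#' @export
assemble_sample <- function(binned, labels, n_per_condition, neurons = NULL,
                            available = NULL, seed = NULL) {
  stopifnot(inherits(binned, "binned_activity"))
  n_neurons_all <- dim(binned$counts)[1]
  n_trials <- dim(binned$counts)[2]
  if (is.null(neurons)) neurons <- seq_len(n_neurons_all)
  if (is.null(available)) available <- matrix(TRUE, n_neurons_all, n_trials)
  conds <- sort(unique(labels[!is.na(labels)]))
  if (length(conds) < 2L) {
    stop("need at least 2 condition labels", call. = FALSE)
  }
  with_seed_(seed, {
    index <- matrix(0L, nrow = length(neurons),
                    ncol = length(conds) * n_per_condition)
    col_labels <- rep(conds, each = n_per_condition)
    for (r in seq_along(neurons)) {
      i <- neurons[r]
      for (ci in seq_along(conds)) {
        pool <- which(available[i, ] & !is.na(labels) &
                        labels == conds[ci])
        if (length(pool) < n_per_condition) {
          stop("eligibility error: neuron ", binned$neuron_ids[i],
               " has only ", length(pool), " trials for condition '",
               conds[ci], "' (need ", n_per_condition, ")", call. = FALSE)
        }
        cols <- (ci - 1L) * n_per_condition + seq_len(n_per_condition)
        index[r, cols] <- sample(pool, n_per_condition)
      }
    }
    structure(list(index = index, col_labels = col_labels,
                   conditions = conds, neurons = neurons, fold = NULL),
              class = "pseudo_sample")
  })
}

#' Assign condition-balanced cross-validation folds
#'
#' Folds are stratified by condition: within each condition the columns are
#' randomly partitioned into `k` near-equal parts, so every fold carries
#' (almost) equal label counts and the chance level is unbiased.
#'
#' @param sample a `pseudo_sample`.
#' @param k number of folds (`k >= 2`); `k = n_per_condition` gives
#'   leave-one-trial-per-condition-out.
#' @param seed integer seed (optional).
#' @return the sample with a `fold` vector (one integer in `1..k` per
#'   column).
#' @export
assign_folds <- function(sample, k, seed = NULL) {
  stopifnot(inherits(sample, "pseudo_sample"), k >= 2L)
  n_per <- sum(sample$col_labels == sample$conditions[1])
  if (k > n_per) {
    stop("parameter error: k exceeds trials per condition", call. = FALSE)
  }
  with_seed_(seed, {
    fold <- integer(length(sample$col_labels))
    for (cc in sample$conditions) {
      cols <- which(sample$col_labels == cc)
      fold[cols] <- sample(rep_len(seq_len(k), length(cols)))
    }
    sample$fold <- fold
    sample
  })
}

#' Extract the population matrix of a sample at one time bin
#'
#' @param binned a `binned_activity`.
#' @param sample a `pseudo_sample` assembled from it.
#' @param bin time-bin index.
#' @return matrix `n_neurons x n_columns` of counts.
#' @export
sample_matrix <- function(binned, sample, bin) {
  m <- binned$counts[, , bin, drop = FALSE]
  dim(m) <- dim(binned$counts)[1:2]
  x <- matrix(0, nrow = nrow(sample$index), ncol = ncol(sample$index))
  for (r in seq_len(nrow(sample$index))) {
    x[r, ] <- m[sample$neurons[r], sample$index[r, ]]
  }
  x
}

#' Z-score a population matrix with training-fold statistics
#'
#' Per-neuron `(x - mu) / sigma` applied to both splits, with `mu`, `sigma`
#' computed from training columns only (no leakage). `mode = "all"` uses
#' all training columns (decoding); `mode = "small_large"` uses only the
#' training columns of the two extreme conditions (geometry: the
#' discriminant normalization). A neuron with zero training variance is
#' mapped to 0 rather than dropped, keeping the population size fixed.
#'
#' @param x matrix `n_neurons x n_columns`.
#' @param col_labels,fold per-column labels and fold assignment.
#' @param test_fold fold held out for testing.
#' @param mode `"all"` or `"small_large"`.
#' @param extremes the two conditions defining the normalization pool in
#'   `"small_large"` mode.
#' @param warn_constant warn when a constant neuron is zeroed.
#' @return list with `train`, `test` (z-scored matrices), `train_cols`,
#'   `test_cols`, `mu`, `sigma`.
#' @export
zscore_by_train <- function(x, col_labels, fold, test_fold, mode = "all",
                            extremes = c("small", "large"),
                            warn_constant = FALSE) {
  train_cols <- which(fold != test_fold)
  test_cols <- which(fold == test_fold)
  norm_cols <- if (mode == "small_large") {
    intersect(train_cols, which(col_labels %in% extremes))
  } else train_cols
  mu <- rowMeans(x[, norm_cols, drop = FALSE])
  sigma <- row_sds_(x[, norm_cols, drop = FALSE])
  zero <- sigma == 0 | !is.finite(sigma)
  if (any(zero) && warn_constant) {
    warning(sum(zero), " neuron(s) with zero training variance mapped to 0",
            call. = FALSE)
  }
  sigma[zero] <- Inf   # (x - mu)/Inf -> 0
  z <- (x - mu) / sigma
  list(train = z[, train_cols, drop = FALSE],
       test = z[, test_cols, drop = FALSE],
       train_cols = train_cols, test_cols = test_cols,
       mu = mu, sigma = sigma)
}
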