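# Discriminant-projection geometry: the small-large coding direction,
# cross-validated projections of all three reward conditions, and the
# overlap-index significance criterion.

#' Compute the small-large discriminant (coding direction)
#'
#' The unnormalized direction `mean(large) - mean(small)` of training-trial
#' population activity, one entry per neuron.
#'
#' @param train_means matrix `n_neurons x n_conditions` of per-condition
#'   mean training activity (columns named by condition).
#' @param small,large the two extreme conditions.
#' @return numeric direction vector of length `n_neurons`.
#' @export
compute_discriminant <- function(train_means, small = "small",
                                 large = "large") {
  if (!all(c(small, large) %in% colnames(train_means))) {
    stop("missing condition column: need '", small, "' and '", large, "'",
         call. = FALSE)
  }
  train_means[, large] - train_means[, small]
}

#' Project condition vectors onto a direction
#'
#' Dot product between the discriminant and each condition's population
#' vector of test activity.
#'
#' @param direction numeric vector (length `n_neurons`).
#' @param test_matrix matrix `n_neurons x n_conditions`.
#' @return named numeric vector, one projection per condition.
#' @export
project_conditions <- function(direction, test_matrix) {
  if (length(direction) != nrow(test_matrix)) {
    stop("dimension mismatch: direction length ", length(direction),
         " vs ", nrow(test_matrix), " neurons", call. = FALSE)
  }
  drop(crossprod(test_matrix, direction))
}

#' Overlap index of two sample distributions
#'
#' Proportion of shared area between the kernel density estimates of two
#' samples: the integral of `min(f_A, f_B)` over a shared grid (Gaussian
#' kernel, Silverman's bandwidth, 512 grid points). Values near 1 mean
#' indistinguishable distributions; an overlap below 5% is the criterion
#' for a significant difference.
#'
#' @param a,b numeric samples (>= 10 values each recommended).
#' @param n_grid shared grid size.
#' @return overlap proportion in `[0, 1]`, symmetric in its arguments.
#' @export
overlap_index <- function(a, b, n_grid = 512L) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L || stats::sd(a) == 0 ||
      stats::sd(b) == 0) {
    # point-mass rule for degenerate samples
    return(if (isTRUE(all.equal(unique(a), unique(b))) &&
               length(unique(a)) == 1L && length(unique(b)) == 1L) 1 else 0)
  }
  bw_a <- stats::bw.nrd0(a)
  bw_b <- stats::bw.nrd0(b)
  lo <- min(a, b) - 3 * max(bw_a, bw_b)
  hi <- max(a, b) + 3 * max(bw_a, bw_b)
  da <- stats::density(a, bw = bw_a, from = lo, to = hi, n = n_grid)
  db <- stats::density(b, bw = bw_b, from = lo, to = hi, n = n_grid)
  y <- pmin(da$y, db$y)
  # trapezoidal integral on the shared grid
  sum(diff(da$x) * (y[-1] + y[-length(y)]) / 2)
}

#' Cross-validated discriminant-projection analysis
#'
#' For each time bin and resample: sample `n_per_condition` trials per
#' condition per neuron, and in a k-fold loop (leave-one-trial-per-
#' condition-out by default) z-score with the mean and SD of the small and
#' large training trials, build the discriminant from training means, and
#' project each condition's test vector onto it; fold projections are
#' averaged. Over `n_resamples` resamples this yields a distribution of
#' projections per condition and bin, compared pairwise with the overlap
#' index; a pair differs significantly where overlap < `overlap_threshold`
#' in at least `min_consecutive` consecutive bins.
#'
#' @inheritParams decode_timecourse
#' @param n_resamples number of pseudo-population resamples (reference:
#'   100).
#' @param k folds; `NULL` (default) = `n_per_condition`, i.e.
#'   leave-one-trial-per-condition-out.
#' @param small,large the conditions defining the discriminant.
#' @param overlap_threshold significance criterion on the overlap index.
#' @param min_consecutive consecutive-bin rule.
#' @return object of class `projection_result`: `projections` (array
#'   `n_resamples x n_bins x n_conditions`), `overlap` (matrix
#'   `n_pairs x n_bins`), `significant` (same shape, after the
#'   consecutive-bin rule), `pair_names`, `bin_centers`, `conditions`.
#' @export
run_projection_analysis <- function(binned, labels, n_per_condition = 60L,
                                    n_resamples = 100L, k = NULL,
                                    neurons = NULL, available = NULL,
                                    bins = NULL, small = "small",
                                    large = "large",
                                    overlap_threshold = 0.05,
                                    min_consecutive = 5L, seed = NULL) {
  stopifnot(inherits(binned, "binned_activity"))
  if (is.null(bins)) bins <- seq_along(binned$bin_centers)
  if (is.null(k)) k <- n_per_condition
  conds <- sort(unique(labels[!is.na(labels)]))
  if (!all(c(small, large) %in% conds)) {
    stop("labels must include '", small, "' and '", large, "'",
         call. = FALSE)
  }
  with_seed_(seed, {
    proj <- array(NA_real_,
                  dim = c(n_resamples, length(bins), length(conds)),
                  dimnames = list(NULL, NULL, conds))
    for (r in seq_len(n_resamples)) {
      smp <- assemble_sample(binned, labels, n_per_condition,
                             neurons = neurons, available = available)
      smp <- assign_folds(smp, k)
      for (bi in seq_along(bins)) {
        x <- sample_matrix(binned, smp, bins[bi])
        fold_proj <- matrix(NA_real_, k, length(conds))
        for (f in seq_len(k)) {
          z <- zscore_by_train(x, smp$col_labels, smp$fold, f,
                               mode = "small_large",
                               extremes = c(small, large))
          tr_lab <- smp$col_labels[z$train_cols]
          te_lab <- smp$col_labels[z$test_cols]
          train_means <- vapply(conds, function(cc) {
            rowMeans(z$train[, tr_lab == cc, drop = FALSE])
          }, numeric(nrow(x)))
          test_means <- vapply(conds, function(cc) {
            rowMeans(z$test[, te_lab == cc, drop = FALSE])
          }, numeric(nrow(x)))
          dirn <- compute_discriminant(train_means, small, large)
          fold_proj[f, ] <- project_conditions(dirn, test_means)
        }
        proj[r, bi, ] <- colMeans(fold_proj)
      }
    }
    pairs <- utils::combn(conds, 2L)
    pair_names <- apply(pairs, 2, paste, collapse = "-")
    overlap <- matrix(NA_real_, ncol(pairs), length(bins),
                      dimnames = list(pair_names, NULL))
    for (j in seq_len(ncol(pairs))) {
      for (bi in seq_along(bins)) {
        overlap[j, bi] <- overlap_index(proj[, bi, pairs[1, j]],
                                        proj[, bi, pairs[2, j]])
      }
    }
    sig <- overlap < overlap_threshold
    for (j in seq_len(nrow(sig))) {
      sig[j, ] <- consecutive_mask_(sig[j, ], min_consecutive)
    }
    structure(list(projections = proj, overlap = overlap,
                   significant = sig, pair_names = pair_names,
                   bin_centers = binned$bin_centers[bins],
                   conditions = conds,
                   overlap_threshold = overlap_threshold),
              class = "projection_result")
  })
}

#' @export
print.projection_result <- function(x, ...) {
  cat("<projection_result>", dim(x$projections)[1], "resamples x",
      dim(x$projections)[2], "bins;", length(x$conditions),
      "conditions\n")
  for (pn in x$pair_names) {
    cat(" ", pn, ": min overlap", signif(min(x$overlap[pn, ]), 3),
        "; significant bins:", sum(x$significant[pn, ]), "\n")
  }
  invisible(x)
}
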