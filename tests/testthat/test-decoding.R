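# SVM decoding, shuffle nulls, significance rules, sliding windows,
# balanced decoding

test_that("well-separated clusters decode perfectly, shuffled labels at chance", {
  withr::with_seed(1, {
    n_tr <- 30L
    labels <- rep(c("small", "large"), each = n_tr)
    # two neurons, clusters 10 SDs apart in both
    counts <- array(0, dim = c(2, 2 * n_tr, 2))
    for (b in 1:2) {
      counts[, labels == "small", b] <- matrix(rnorm(2 * n_tr, 0), 2)
      counts[, labels == "large", b] <- matrix(rnorm(2 * n_tr, 10), 2)
    }
    binned <- make_binned(counts)
    res <- decode_timecourse(binned, labels,
                             decoder_spec(k = 5, n_resamples = 3),
                             n_per_condition = 25, seed = 2)
    expect_equal(res$mean_accuracy, rep(1, 2))
    expect_equal(res$chance, 0.5)

    # shuffling the labels destroys the information
    shuffled <- sample(labels)
    null <- build_null(binned, shuffled,
                       decoder_spec(k = 5, n_resamples = 3),
                       n_per_condition = 25, n_shuffles = 5, seed = 3)
    res_s <- decode_timecourse(binned, shuffled,
                               decoder_spec(k = 5, n_resamples = 3),
                               n_per_condition = 25, seed = 4)
    expect_lt(abs(mean(res_s$mean_accuracy) - 0.5), 2 * null$sd + 1e-9)
  })
})

test_that("decoding is invariant to per-neuron affine rescaling", {
  s <- make_session(n_blocks = 6L, n_neurons = 8L, seed = 11L)
  b <- bin_spike_counts(s$spikes, s$trials, "feedback_onset",
                        span = c(0, 500), bin_width = 250, bin_step = 250)
  spec <- decoder_spec(k = 5, n_resamples = 2)
  r1 <- decode_timecourse(b, s$trials$reward_size, spec,
                          n_per_condition = 20, seed = 7)
  b2 <- b
  scale <- seq(0.5, 4, length.out = 8)
  shift <- seq(-2, 12, length.out = 8)
  b2$counts <- array(b$counts * scale + shift, dim = dim(b$counts))
  r2 <- decode_timecourse(b2, s$trials$reward_size, spec,
                          n_per_condition = 20, seed = 7)
  expect_equal(r1$mean_accuracy, r2$mean_accuracy, tolerance = 1e-10)
})

test_that("cross-validated accuracy matches a brute-force threshold oracle", {
  # 1 neuron, 4 columns, 2 labels: the linear SVM is a threshold rule.
  # Exhaustive oracle: for each fold, the max-margin threshold between the
  # two training classes; test points are classified by side.
  one_d_case <- function(vals, labels, fold) {
    k <- max(fold)
    accs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      # z-score with training stats (as the pipeline does)
      mu <- mean(vals[tr]); sdv <- stats::sd(vals[tr])
      z <- (vals - mu) / sdv
      lo_max <- max(z[tr][labels[tr] == "a"])
      hi_min <- min(z[tr][labels[tr] == "b"])
      thr <- (lo_max + hi_min) / 2      # max-margin threshold, a below b
      pred <- ifelse(z[!tr] < thr, "a", "b")
      mean(pred == labels[!tr])
    }, numeric(1))
    mean(accs)
  }
  vals <- c(0, 1, 10, 11)
  labels <- c("a", "a", "b", "b")
  fold <- c(1L, 2L, 1L, 2L)
  oracle <- one_d_case(vals, labels, fold)
  x <- matrix(vals, nrow = 1)
  acc <- mean(vapply(1:2, function(f) {
    z <- zscore_by_train(x, labels, fold, f)
    pred <- oiprdecode:::svm_train_predict_(z$train, labels[z$train_cols],
                                            z$test, "ovo", 1)
    mean(pred == labels[z$test_cols])
  }, numeric(1)))
  expect_equal(acc, oracle)
  expect_equal(acc, 1)
})

test_that("null pooling, corrected alpha and run-length rule are exact", {
  # arithmetic on a small instance: 1 bin x 5 shuffles -> pooled size 5
  withr::with_seed(5, {
    labels <- rep(c("small", "medium", "large"), each = 15)
    counts <- make_poisson_counts(4, labels,
                                  c(small = 2, medium = 2, large = 2),
                                  n_bins = 1)
    binned <- make_binned(counts)
    null <- build_null(binned, labels, decoder_spec(k = 3, n_resamples = 2),
                       n_per_condition = 12, n_shuffles = 5, seed = 1)
    expect_length(null$values, 5L)
    expect_equal(null$alpha, 0.05 / 5)
    expect_error(build_null(binned, labels, decoder_spec(),
                            n_per_condition = 12, n_shuffles = 1),
                 "n_shuffles")
  })
  # reference design: 63 bins x 20 shuffles
  expect_equal(0.05 / (63 * 20), 3.968254e-5, tolerance = 1e-6)

  # consecutive-bin rule on a synthetic result
  res <- structure(list(mean_accuracy = c(rep(0.9, 4), 0.3, rep(0.9, 5)),
                        bin_centers = 1:10),
                   class = "decoding_result")
  null <- structure(list(values = rep(c(0.32, 0.34), 50), n_shuffles = 10,
                         n_bins = 10, alpha = 0.05 / 100,
                         mean = 0.33, sd = 0.01), class = "null_model")
  sig <- assess_significance(res, null, min_consecutive = 5)
  # 4 passing bins then a gap then 5 passing: only the run of 5 survives
  expect_equal(sig$pass, c(rep(TRUE, 4), FALSE, rep(TRUE, 5)))
  expect_equal(sig$significant, c(rep(FALSE, 5), rep(TRUE, 5)))
  # observed below the null maximum everywhere -> nothing significant
  res2 <- structure(list(mean_accuracy = rep(0.335, 10), bin_centers = 1:10),
                    class = "decoding_result")
  sig2 <- assess_significance(res2, null, min_consecutive = 5,
                              p_method = "empirical")
  expect_true(all(!sig2$significant))
  # empirical p is the +1-corrected exceedance proportion
  expect_equal(sig2$p_value,
               rep((1 + sum(null$values >= 0.335)) / 101, 10))
})

test_that("sliding windows cover the block as designed", {
  s <- make_session(n_blocks = 10L, n_neurons = 6L, seed = 21L)
  # 30-trial blocks, window 10, step 1 -> 21 windows; first window pools
  # trials 1-10 of every block -> 100 trials in a 10-block session
  starts <- seq(1L, 30L - 10L + 1L, by = 1L)
  expect_length(starts, 21L)
  in_first <- s$trials$trial_index_in_block %in% 1:10
  expect_equal(sum(in_first), 100L)

  # window = block length gives a single window equal to whole-block decoding
  b <- bin_spike_counts(s$spikes, s$trials, "feedback_onset",
                        span = c(0, 500), bin_width = 250, bin_step = 250)
  spec <- decoder_spec(k = 4, n_resamples = 2)
  sw <- sliding_window_decode(b, s$trials, s$trials$reward_size,
                              window = 30L, spec = spec,
                              n_per_condition = 20, n_shuffles = 2,
                              min_consecutive = 1, seed = 5)
  expect_identical(dim(sw$accuracy), c(1L, 2L))
  whole <- decode_timecourse(b, s$trials$reward_size, spec,
                             n_per_condition = 20, seed = 5)
  # same procedure, same trial pool: accuracies agree closely
  expect_lt(max(abs(sw$accuracy[1, ] - whole$mean_accuracy)), 0.15)

  # too few trials per condition in a window is an eligibility error
  expect_error(
    sliding_window_decode(b, s$trials, s$trials$reward_size, window = 10L,
                          spec = spec, n_per_condition = 60,
                          n_shuffles = 2, seed = 6),
    "eligibility error")
})

test_that("balanced decoding removes a confound and keeps real signals", {
  withr::with_seed(31, {
    n <- 240L
    a <- sample(rep(c("small", "med_large"), each = n / 2))
    # B is 80% correlated with A
    agree <- runif(n) < 0.8
    b_lab <- ifelse(agree, ifelse(a == "small", "switch", "stay"),
                    ifelse(a == "small", "stay", "switch"))
    # only A drives the rates of 40 neurons
    gains <- runif(40, 2, 5)
    lam <- outer(gains, as.numeric(a == "small")) + 3
    x <- matrix(rpois(40 * n, lam), 40, n)
    bd <- balanced_decode(x, a, b_lab, n_shuffles = 25, seed = 1)
    expect_equal(bd$chance, 0.5)
    # A decodes above chance; B stays within the null spread of 50%
    expect_lt(bd$variable_a$p_value, 0.05)
    expect_gt(bd$variable_a$accuracy, 0.8)
    expect_lt(abs(bd$variable_b$accuracy - 0.5),
              2 * stats::sd(bd$variable_b$null) + 1e-9)

    # both variables independently coded in disjoint neuron subsets
    lam2 <- rbind(outer(gains[1:20], as.numeric(a == "small")) + 3,
                  outer(gains[21:40], as.numeric(b_lab == "switch")) + 3)
    x2 <- matrix(rpois(40 * n, lam2), 40, n)
    bd2 <- balanced_decode(x2, a, b_lab, n_shuffles = 25, seed = 2)
    expect_lt(bd2$variable_a$p_value, 0.05)
    expect_lt(bd2$variable_b$p_value, 0.05)
  })
})

test_that("balanced decoding enforces cell eligibility", {
  withr::with_seed(41, {
    n <- 60L
    a <- rep(c("x", "y"), each = n / 2)
    b_lab <- rep(c("u", "v"), n / 2)
    x <- matrix(rpois(10 * n, 3), 10, n)
    # empty cell -> error
    b_bad <- ifelse(a == "x", "u", b_lab)
    expect_error(balanced_decode(x, a, b_bad, seed = 1), "empty")
    # min_per_cell above availability -> no eligible neurons
    expect_error(balanced_decode(x, a, b_lab, min_per_cell = 50, seed = 1),
                 "no eligible neurons")
  })
})

test_that("decoding results are reproducible under a fixed seed", {
  s <- make_session(n_blocks = 6L, n_neurons = 5L, seed = 51L)
  b <- bin_spike_counts(s$spikes, s$trials, "feedback_onset",
                        span = c(0, 500), bin_width = 250, bin_step = 250)
  spec <- decoder_spec(k = 4, n_resamples = 2)
  r1 <- decode_timecourse(b, s$trials$reward_size, spec,
                          n_per_condition = 15, seed = 9)
  r2 <- decode_timecourse(b, s$trials$reward_size, spec,
                          n_per_condition = 15, seed = 9)
  expect_identical(r1$accuracy, r2$accuracy)
})
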