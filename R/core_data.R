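#' @keywords internal
"_PACKAGE"

# ---- domain constants -------------------------------------------------------

#' Reward size levels of the OIPR task
#'
#' The three per-scene reward sizes, ordered from smallest to largest
#' (nominally ~0.15, 0.3 and 0.6 ml of juice).
#' @export
reward_levels <- function() c("small", "medium", "large")

#' Columns of a trial table
#'
#' One row per completed trial. Event times (`scene_onset`, `go_signal`,
#' `feedback_onset`) are in milliseconds on a single session clock;
#' `reaction_time` and `movement_time` are in milliseconds. `stay_switch`
#' is `"stay"`/`"switch"` from run 2 on and `NA` in run 1 (a scene has no
#' previous-run choice in the first run).
#' @export
trial_table_columns <- function() {
  c("session_id", "block_index", "run_index", "scene_index",
    "trial_index_in_block", "reward_size", "correct", "chosen_object",
    "chosen_position", "stay_switch", "reaction_time", "movement_time",
    "scene_onset", "go_signal", "feedback_onset")
}

# ---- trial table validation -------------------------------------------------

#' Validate a trial table
#'
#' Checks the structural invariants of an OIPR trial table: required columns
#' and types, field ranges, `stay_switch` undefined exactly in run 1, one
#' reward size per (session, block, scene), and block completeness
#' (30 trials = 5 scenes x 6 runs). Errors are row-addressed.
#'
#' @param trials data.frame with the columns of [trial_table_columns()]
#'   (extra columns are allowed and ignored).
#' @param allow_incomplete if `TRUE`, blocks with fewer than 30 trials are
#'   tolerated (e.g. a session that ended mid-block); such blocks are still
#'   excluded from block-level analyses via [filter_complete_blocks()].
#' @return the validated data.frame, invisibly.
#' @export
validate_trial_table <- function(trials, allow_incomplete = TRUE) {
  stopifnot(is.data.frame(trials))
  missing_cols <- setdiff(trial_table_columns(), names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      stop("trial table validation error: ", what, " in row(s) ",
           paste(utils::head(idx, 10L), collapse = ", "),
           if (length(idx) > 10L) " ..." else "", call. = FALSE)
    }
  }
  bad_row(!trials$run_index %in% 1:6, "run_index outside 1..6")
  bad_row(!trials$scene_index %in% 1:5, "scene_index outside 1..5")
  bad_row(!trials$trial_index_in_block %in% 1:30,
          "trial_index_in_block outside 1..30")
  bad_row(!trials$reward_size %in% reward_levels(), "unknown reward_size")
  bad_row(!is.na(trials$stay_switch) &
            !trials$stay_switch %in% c("stay", "switch"),
          "unknown stay_switch value")
  bad_row(trials$run_index == 1L & !is.na(trials$stay_switch),
          "stay_switch defined in run 1")
  bad_row(!is.na(trials$reaction_time) & trials$reaction_time <= 0,
          "non-positive reaction_time")
  bad_row(!is.na(trials$movement_time) & trials$movement_time <= 0,
          "non-positive movement_time")

  key <- paste(trials$session_id, trials$block_index, trials$scene_index)
  n_sizes <- tapply(trials$reward_size, key, function(x) length(unique(x)))
  if (any(n_sizes > 1L)) {
    stop("trial table validation error: reward_size not constant for ",
         "(session, block, scene) ", names(n_sizes)[which(n_sizes > 1L)[1L]],
         call. = FALSE)
  }
  bkey <- paste(trials$session_id, trials$block_index)
  bn <- table(bkey)
  if (any(bn > 30L)) {
    stop("trial table validation error: block with more than 30 trials: ",
         names(bn)[which(bn > 30L)[1L]], call. = FALSE)
  }
  if (!allow_incomplete && any(bn != 30L)) {
    stop("trial table validation error: incomplete block (",
         names(bn)[which(bn != 30L)[1L]], ": ", bn[which(bn != 30L)[1L]],
         " trials, expected 30)", call. = FALSE)
  }
  invisible(trials)
}

#' Keep only completed blocks (30 trials)
#'
#' Block-level analyses (sliding-window decoding, per-run statistics over
#' whole blocks) use only blocks that reached the full 30 trials.
#' @param trials a validated trial table.
#' @return the subset of `trials` belonging to complete blocks.
#' @export
filter_complete_blocks <- function(trials) {
  bkey <- paste(trials$session_id, trials$block_index)
  bn <- table(bkey)
  trials[bkey %in% names(bn)[bn == 30L], , drop = FALSE]
}

# ---- spike data -------------------------------------------------------------

#' Construct a spike-train object
#'
#' @param neuron_id,session_id identifiers; a neuron belongs to exactly one
#'   session.
#' @param spike_times numeric vector of spike times in ms on the session
#'   clock; must be non-decreasing (they are sorted on construction).
#' @return an object of class `spike_data`.
#' @export
spike_data <- function(neuron_id, session_id, spike_times) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) spike_times <- sort(spike_times)
  structure(
    list(neuron_id = as.character(neuron_id),
         session_id = as.character(session_id),
         spike_times = spike_times),
    class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat("<spike_data> neuron", x$neuron_id, "session", x$session_id, "-",
      length(x$spike_times), "spikes\n")
  invisible(x)
}

# ---- session I/O ------------------------------------------------------------

#' Read / write a trial table (CSV)
#'
#' UTF-8 CSV with one header row and the columns of
#' [trial_table_columns()]; an undefined `stay_switch` (run 1) is encoded as
#' the empty string.
#' @param path file path.
#' @return `read_trial_table`: a validated trial table data.frame.
#' @export
read_trial_table <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(session_id = "character"))
  if ("stay_switch" %in% names(trials)) {
    trials$stay_switch <- as.character(trials$stay_switch)
    trials$stay_switch[!is.na(trials$stay_switch) &
                         trials$stay_switch == ""] <- NA_character_
  }
  validate_trial_table(trials)
  trials
}

#' @rdname read_trial_table
#' @param trials a validated trial table.
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  out <- trials[, trial_table_columns(), drop = FALSE]
  out$stay_switch[is.na(out$stay_switch)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a spike store (CSV)
#'
#' Long-format CSV with columns `neuron_id`, `session_id`, `spike_time_ms`,
#' one row per spike; neurons keep their order of first appearance.
#' @param path file path.
#' @return `read_spike_store`: a named list of [spike_data()] objects.
#' @export
read_spike_store <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(neuron_id = "character",
                                       session_id = "character"))
  need <- c("neuron_id", "session_id", "spike_time_ms")
  if (!all(need %in% names(df))) {
    stop("spike store schema error: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ids <- unique(df$neuron_id)
  spikes <- lapply(ids, function(id) {
    sub <- df[df$neuron_id == id, , drop = FALSE]
    sess <- unique(sub$session_id)
    if (length(sess) != 1L) {
      stop("spike store validation error: neuron ", id,
           " maps to more than one session", call. = FALSE)
    }
    spike_data(id, sess, sub$spike_time_ms)
  })
  names(spikes) <- ids
  spikes
}

#' @rdname read_spike_store
#' @param spikes a list of [spike_data()] objects.
#' @export
write_spike_store <- function(spikes, path) {
  df <- do.call(rbind, lapply(spikes, function(s) {
    data.frame(neuron_id = rep(s$neuron_id, length(s$spike_times)),
               session_id = rep(s$session_id, length(s$spike_times)),
               spike_time_ms = s$spike_times)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load / write a full session (trial table + spike store)
#'
#' @param trial_table_path,spike_store_path CSV paths as written by
#'   [write_session()].
#' @return `load_session`: `list(trials =, spikes =)` with validated objects.
#' @export
load_session <- function(trial_table_path, spike_store_path) {
  list(trials = read_trial_table(trial_table_path),
       spikes = read_spike_store(spike_store_path))
}

#' @rdname load_session
#' @param trials a validated trial table.
#' @param spikes a list of [spike_data()] objects.
#' @export
write_session <- function(trials, spikes, trial_table_path,
                          spike_store_path) {
  write_trial_table(trials, trial_table_path)
  write_spike_store(spikes, spike_store_path)
  invisible(list(trials = trial_table_path, spikes = spike_store_path))
}

# ---- event-aligned binning --------------------------------------------------

#' Bin spike counts around an alignment event
#'
#' Counts spikes in sliding bins aligned to a per-trial event, the substrate
#' of all decoding and geometry analyses (default 250 ms bins moved in 25 ms
#' steps). Bins are half-open `[lo, hi)`: a spike exactly on a boundary
#' belongs to the later bin. With the default span of -500 to +1300 ms this
#' yields 63 bins per epoch.
#'
#' @param spikes a single [spike_data()] or a list of them.
#' @param trials a validated trial table; the alignment event time must be
#'   present for every trial.
#' @param alignment_event `"scene_onset"` (Delay epoch) or
#'   `"feedback_onset"` (Feedback epoch).
#' @param span `c(start, end)` in ms relative to the event.
#' @param bin_width,bin_step bin width and step in ms.
#' @return an object of class `binned_activity`: a list with `counts`
#'   (array `n_neurons x n_trials x n_bins`), `bin_centers` (ms relative to
#'   the event), `bin_width`, `bin_step`, `span`, `alignment_event` and
#'   `neuron_ids`.
#' @export
bin_spike_counts <- function(spikes, trials,
                             alignment_event = c("scene_onset",
                                                 "feedback_onset"),
                             span = c(-500, 1300),
                             bin_width = 250, bin_step = 25) {
  alignment_event <- match.arg(alignment_event)
  if (inherits(spikes, "spike_data")) spikes <- list(spikes)
  stopifnot(length(span) == 2L, span[2] > span[1])
  span_len <- span[2] - span[1]
  if (span_len < bin_width) {
    stop("parameter error: span shorter than bin_width", call. = FALSE)
  }
  ev <- trials[[alignment_event]]
  if (anyNA(ev)) {
    stop("missing ", alignment_event, " time for ", sum(is.na(ev)),
         " trial(s)", call. = FALSE)
  }
  n_bins <- floor((span_len - bin_width) / bin_step) + 1L
  lows <- span[1] + (seq_len(n_bins) - 1L) * bin_step
  his <- lows + bin_width
  n_trials <- nrow(trials)
  n_neurons <- length(spikes)
  counts <- array(0L, dim = c(n_neurons, n_trials, n_bins))
  for (i in seq_len(n_neurons)) {
    st <- spikes[[i]]$spike_times
    if (length(st) == 0L) next
    for (t in seq_len(n_trials)) {
      edges <- findInterval(c(lows, his) + ev[t], st, left.open = TRUE)
      counts[i, t, ] <- edges[n_bins + seq_len(n_bins)] - edges[seq_len(n_bins)]
    }
  }
  structure(
    list(counts = counts,
         bin_centers = lows + bin_width / 2,
         bin_width = bin_width, bin_step = bin_step, span = span,
         alignment_event = alignment_event,
         neuron_ids = vapply(spikes, function(s) s$neuron_id, character(1))),
    class = "binned_activity")
}

#' @export
print.binned_activity <- function(x, ...) {
  d <- dim(x$counts)
  cat("<binned_activity>", d[1], "neurons x", d[2], "trials x", d[3],
      "bins; width", x$bin_width, "ms, step", x$bin_step,
      "ms, aligned to", x$alignment_event, "\n")
  invisible(x)
}

#' Mean firing rate in a single epoch window
#'
#' Convenience wrapper around [bin_spike_counts()] with one bin covering the
#' whole window; returns rates in Hz.
#' @inheritParams bin_spike_counts
#' @param window `c(start, end)` ms relative to the event.
#' @return matrix `n_neurons x n_trials` of firing rates (Hz).
#' @export
epoch_rates <- function(spikes, trials, alignment_event, window) {
  b <- bin_spike_counts(spikes, trials, alignment_event,
                        span = window,
                        bin_width = diff(window), bin_step = diff(window))
  b$counts[, , 1, drop = TRUE] * 1000 / diff(window)
}

# ---- internal helpers -------------------------------------------------------

# run body with a locally-set seed (no effect on the caller's RNG stream)
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# row-wise sd of a matrix (denominator n - 1)
row_sds_ <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  sqrt(pmax(rowSums((x - mu)^2), 0) / (n - 1))
}

# runs of >= min_consecutive TRUEs
consecutive_mask_ <- function(pass, min_consecutive) {
  pass[is.na(pass)] <- FALSE
  r <- rle(pass)
  keep <- r$values & r$lengths >= min_consecutive
  inverse.rle(list(values = keep, lengths = r$lengths))
}
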