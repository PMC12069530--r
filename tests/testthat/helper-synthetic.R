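# Shared fixtures, built in code.

# small complete session: design + behavior + (optionally) spikes
make_session <- function(n_blocks = 2L, n_neurons = 4L, seed = 42L,
                         with_spikes = TRUE, tuning = tuning_spec()) {
  design <- generate_block_design(task_design_params(n_blocks = n_blocks),
                                  seed = seed)
  trials <- simulate_behavior(design, agent_params(), seed = seed + 1L)
  spikes <- if (with_spikes) {
    simulate_spikes(trials, tuning, n_neurons, seed = seed + 2L)
  } else NULL
  list(trials = trials, spikes = spikes)
}

# a minimal hand-built trial table (one complete block)
make_hand_block <- function(session_id = "s1", block = 1L) {
  g <- expand.grid(scene_index = 1:5, run_index = 1:6)
  reward_map <- c("small", "small", "medium", "medium", "large")
  n <- nrow(g)
  data.frame(
    session_id = session_id, block_index = block,
    run_index = g$run_index, scene_index = g$scene_index,
    trial_index_in_block = seq_len(n),
    reward_size = reward_map[g$scene_index],
    correct = rep(TRUE, n),
    chosen_object = rep("A", n),
    chosen_position = rep(1L, n),
    stay_switch = ifelse(g$run_index == 1L, NA_character_, "stay"),
    reaction_time = rep(400, n), movement_time = rep(250, n),
    scene_onset = 5000 * seq_len(n),
    go_signal = 5000 * seq_len(n) + 800,
    feedback_onset = 5000 * seq_len(n) + 2000,
    stringsAsFactors = FALSE)
}

# binned_activity directly from a counts array (bypasses spike trains)
make_binned <- function(counts, bin_width = 250, bin_step = 25,
                        alignment_event = "scene_onset", span = NULL) {
  n_bins <- dim(counts)[3]
  if (is.null(span)) span <- c(0, bin_width + (n_bins - 1L) * bin_step)
  structure(
    list(counts = counts,
         bin_centers = span[1] + (seq_len(n_bins) - 1L) * bin_step +
           bin_width / 2,
         bin_width = bin_width, bin_step = bin_step, span = span,
         alignment_event = alignment_event,
         neuron_ids = sprintf("n%03d", seq_len(dim(counts)[1]))),
    class = "binned_activity")
}

# Poisson counts array [neurons x trials x bins] with per-condition rates:
# rates is a named vector of mean counts per bin, labels a per-trial vector
make_poisson_counts <- function(n_neurons, labels, rates, n_bins = 1L,
                                seed = 1L) {
  withr::with_seed(seed, {
    n_trials <- length(labels)
    lam <- rates[labels]
    counts <- array(stats::rpois(n_neurons * n_trials * n_bins,
                                 rep(lam, each = n_neurons)),
                    dim = c(n_neurons, n_trials, n_bins))
    counts
  })
}
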