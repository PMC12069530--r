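# Synthetic OIPR sessions: task design, agent behavior, Poisson spiking.
# The generator is first-class: its defaults define the statistical structure
# every downstream stage is tested against.

#' Task design parameters
#'
#' Structure of the OIPR block design: 5 scenes presented in the same order
#' for 6 runs (30 trials per block), each scene bound to one of three reward
#' sizes with the balancing constraint that all three sizes appear among the
#' five scenes and no size appears three times (so the per-block composition
#' is 2+2+1 in some order). Reward volumes are metadata only.
#'
#' @param n_blocks number of blocks to generate.
#' @param n_scenes,n_runs scenes per run and runs per block (fixed task
#'   structure; changing them leaves the 2+2+1 constraint undefined and is
#'   rejected).
#' @param delay_choices Delay-epoch durations (ms), drawn per trial.
#' @param holding_pt_choices holding period on the chosen object before
#'   feedback (ms), drawn per trial.
#' @param reward_volumes_ml named volumes (ml), metadata.
#' @return a list of class `task_design_params`.
#' @export
task_design_params <- function(n_blocks = 10L, n_scenes = 5L, n_runs = 6L,
                               delay_choices = c(800, 1200),
                               holding_pt_choices = c(400, 600),
                               reward_volumes_ml = c(small = 0.15,
                                                     medium = 0.3,
                                                     large = 0.6)) {
  if (n_scenes != 5L || n_runs != 6L) {
    stop("parameter error: the OIPR design is 5 scenes x 6 runs",
         call. = FALSE)
  }
  if (n_blocks < 0) stop("parameter error: n_blocks must be >= 0",
                         call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks), n_scenes = 5L, n_runs = 6L,
                 delay_choices = delay_choices,
                 holding_pt_choices = holding_pt_choices,
                 reward_volumes_ml = reward_volumes_ml),
            class = "task_design_params")
}

#' Agent (behavior) parameters
#'
#' A phenomenological agent: run-1 choices are uninformed (Bernoulli on the
#' correct object), and from run 2 the agent repeats its previous choice for
#' the same scene with a stay probability conditioned on reward size and on
#' the correctness of that previous choice. Defaults reproduce the task's
#' behavioral signature: fast learning and rare switching for medium/large
#' reward, slower learning and elevated switching for small reward even
#' after a correct choice, and longer reaction times for small reward.
#'
#' @param p_correct_run1 probability of choosing the correct object in run 1.
#' @param stay_after_correct,stay_after_incorrect named probabilities
#'   (small/medium/large) of repeating the previous choice given that it was
#'   correct / incorrect.
#' @param rt_meanlog,rt_sdlog named log-normal reaction-time parameters per
#'   reward size (ms scale).
#' @param mt_meanlog,mt_sdlog log-normal movement-time parameters (shared).
#' @return a list of class `agent_params`.
#' @export
agent_params <- function(p_correct_run1 = 0.5,
                         stay_after_correct = c(small = 0.70, medium = 0.95,
                                                large = 0.95),
                         stay_after_incorrect = c(small = 0.20,
                                                  medium = 0.15,
                                                  large = 0.15),
                         rt_meanlog = c(small = log(450), medium = log(380),
                                        large = log(380)),
                         rt_sdlog = c(small = 0.20, medium = 0.20,
                                      large = 0.20),
                         mt_meanlog = log(250), mt_sdlog = 0.15) {
  probs <- c(p_correct_run1, stay_after_correct, stay_after_incorrect)
  if (any(probs < 0 | probs > 1)) {
    stop("parameter error: probabilities must be in [0, 1]", call. = FALSE)
  }
  for (nm in list(stay_after_correct, stay_after_incorrect,
                  rt_meanlog, rt_sdlog)) {
    stopifnot(all(reward_levels() %in% names(nm)))
  }
  structure(list(p_correct_run1 = p_correct_run1,
                 stay_after_correct = stay_after_correct,
                 stay_after_incorrect = stay_after_incorrect,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 mt_meanlog = mt_meanlog, mt_sdlog = mt_sdlog),
            class = "agent_params")
}

#' Neural tuning specification
#'
#' Population-level gains (Hz) added to a Poisson baseline within
#' event-locked windows, matching the structure reported for frontopolar
#' reward coding: three-way reward separation at feedback from the start of
#' a block; delay-epoch reward coding with a merged medium/large
#' representation that emerges only late in the block (a trial-index
#' "learning gate"); and stay/switch action coding late in the Delay epoch,
#' independent of reward. Each neuron applies a private multiplicative gain
#' scale (drawn uniformly in `gain_scale_range`) to all its gains; with all
#' gains 0 the generator is condition-blind.
#'
#' @param baseline_hz baseline firing rate.
#' @param feedback_gain_hz named gains per reward size in the feedback
#'   window (three distinct levels, medium between small and large).
#' @param feedback_window ms after feedback onset in which the feedback
#'   gains apply.
#' @param delay_gain_hz named gains per reward size during the Delay epoch
#'   (two levels: small vs merged medium/large).
#' @param delay_onset_ms delay-coding onset latency after scene onset.
#' @param learning_gate_trial delay gains apply only from this
#'   trial-index-in-block onward (ground-truth handle for late-block onset).
#' @param action_gain_hz named gains (`stay`, `switch`) in the action
#'   window.
#' @param action_window ms after scene onset in which action gains apply.
#' @param gain_scale_range per-neuron multiplicative jitter on all gains.
#' @param pre_ms,post_ms simulated padding before scene onset / after the
#'   feedback window (spikes are generated for the whole padded trial span).
#' @return a list of class `tuning_spec`.
#' @export
tuning_spec <- function(baseline_hz = 10,
                        feedback_gain_hz = c(small = 0, medium = 5,
                                             large = 10),
                        feedback_window = 400,
                        delay_gain_hz = c(small = 0, medium = 6, large = 6),
                        delay_onset_ms = 400,
                        learning_gate_trial = 15L,
                        action_gain_hz = c(stay = 0, switch = 5),
                        action_window = c(800, 1000),
                        gain_scale_range = c(0.5, 1.5),
                        pre_ms = 1000, post_ms = 1000) {
  stopifnot(baseline_hz >= 0,
            all(reward_levels() %in% names(feedback_gain_hz)),
            all(reward_levels() %in% names(delay_gain_hz)),
            all(c("stay", "switch") %in% names(action_gain_hz)),
            length(action_window) == 2L,
            action_window[2] > action_window[1])
  structure(list(baseline_hz = baseline_hz,
                 feedback_gain_hz = feedback_gain_hz,
                 feedback_window = feedback_window,
                 delay_gain_hz = delay_gain_hz,
                 delay_onset_ms = delay_onset_ms,
                 learning_gate_trial = as.integer(learning_gate_trial),
                 action_gain_hz = action_gain_hz,
                 action_window = action_window,
                 gain_scale_range = gain_scale_range,
                 pre_ms = pre_ms, post_ms = post_ms),
            class = "tuning_spec")
}

# ---- design -----------------------------------------------------------------

# one 2+2+1 scene -> reward map over 5 scenes
sample_reward_map_ <- function() {
  sizes <- reward_levels()
  single <- sample(sizes, 1L)          # the size that appears once
  doubles <- setdiff(sizes, single)
  sample(c(single, rep(doubles, each = 2L)))  # random scene assignment
}

#' Generate the skeleton of an OIPR session design
#'
#' Produces `n_blocks * 30` trial rows: within each block the five scenes
#' are presented in the same (randomized) order for six runs, each scene is
#' bound to one reward size under the 2+2+1 composition constraint, and a
#' fresh correct object (A/B) and target position are drawn per scene.
#' Behavioral columns (choice, correctness, stay/switch, times) are left
#' `NA` and filled by [simulate_behavior()].
#'
#' @param params a [task_design_params()].
#' @param seed integer seed (optional).
#' @param session_id session label.
#' @return a trial-table data.frame skeleton (plus ground-truth columns
#'   `correct_object` and `delay_ms`/`holding_pt_ms`).
#' @export
generate_block_design <- function(params = task_design_params(), seed = NULL,
                                  session_id = "synthetic-01") {
  stopifnot(inherits(params, "task_design_params"))
  with_seed_(seed, {
    blocks <- lapply(seq_len(params$n_blocks), function(b) {
      scene_order <- sample(params$n_scenes)        # fixed across runs
      reward_map <- sample_reward_map_()            # per scene identity
      correct_obj <- sample(c("A", "B"), params$n_scenes, replace = TRUE)
      rows <- expand.grid(scene_pos = seq_len(params$n_scenes),
                          run_index = seq_len(params$n_runs))
      scene <- scene_order[rows$scene_pos]
      data.frame(
        session_id = session_id,
        block_index = b,
        run_index = rows$run_index,
        scene_index = scene,
        trial_index_in_block = seq_len(params$n_scenes * params$n_runs),
        reward_size = reward_map[scene],
        correct = NA,
        chosen_object = NA_character_,
        chosen_position = NA_integer_,
        stay_switch = NA_character_,
        reaction_time = NA_real_,
        movement_time = NA_real_,
        scene_onset = NA_real_,
        go_signal = NA_real_,
        feedback_onset = NA_real_,
        correct_object = correct_obj[scene],
        delay_ms = sample(params$delay_choices,
                          params$n_scenes * params$n_runs, replace = TRUE),
        holding_pt_ms = sample(params$holding_pt_choices,
                               params$n_scenes * params$n_runs,
                               replace = TRUE),
        stringsAsFactors = FALSE)
    })
    if (length(blocks) == 0L) {
      empty <- generate_block_design(task_design_params(n_blocks = 1L),
                                     seed = 1L, session_id = session_id)
      return(empty[0L, , drop = FALSE])
    }
    do.call(rbind, blocks)
  })
}

# ---- behavior ---------------------------------------------------------------

#' Simulate agent behavior on a design skeleton
#'
#' Fills choices, correctness, stay/switch labels, reaction and movement
#' times and session-clock event times. Run-1 choices hit the correct
#' object with `p_correct_run1`; from run 2 the agent stays on its previous
#' choice for the same scene with the size- and outcome-conditional stay
#' probability, otherwise it switches to the alternative object.
#'
#' @param design output of [generate_block_design()].
#' @param agent an [agent_params()].
#' @param seed integer seed (optional).
#' @return a complete, validated trial table.
#' @export
simulate_behavior <- function(design, agent = agent_params(), seed = NULL) {
  stopifnot(inherits(agent, "agent_params"))
  trials <- design
  n <- nrow(trials)
  if (n == 0L) return(trials)
  with_seed_(seed, {
    ord <- order(trials$block_index, trials$trial_index_in_block)
    trials <- trials[ord, , drop = FALSE]
    clock <- 0
    prev_choice <- list()   # key: block|scene -> chosen object
    prev_correct <- list()
    for (i in seq_len(n)) {
      size <- trials$reward_size[i]
      key <- paste(trials$block_index[i], trials$scene_index[i])
      if (trials$run_index[i] == 1L) {
        chose_correct <- stats::runif(1) < agent$p_correct_run1
        choice <- if (chose_correct) trials$correct_object[i] else
          setdiff(c("A", "B"), trials$correct_object[i])
        trials$stay_switch[i] <- NA_character_
      } else {
        p_stay <- if (prev_correct[[key]]) agent$stay_after_correct[[size]]
                  else agent$stay_after_incorrect[[size]]
        stay <- stats::runif(1) < p_stay
        choice <- if (stay) prev_choice[[key]] else
          setdiff(c("A", "B"), prev_choice[[key]])
        trials$stay_switch[i] <- if (stay) "stay" else "switch"
      }
      trials$chosen_object[i] <- choice
      trials$correct[i] <- choice == trials$correct_object[i]
      prev_choice[[key]] <- choice
      prev_correct[[key]] <- trials$correct[i]
      trials$reaction_time[i] <- stats::rlnorm(1, agent$rt_meanlog[[size]],
                                               agent$rt_sdlog[[size]])
      trials$movement_time[i] <- stats::rlnorm(1, agent$mt_meanlog,
                                               agent$mt_sdlog)
      trials$chosen_position[i] <- sample.int(10L, 1L)
      # session clock: holding-CT, scene (Delay), go, reach, holding-PT,
      # feedback, inter-trial interval
      trials$scene_onset[i] <- clock + 650
      trials$go_signal[i] <- trials$scene_onset[i] + trials$delay_ms[i]
      trials$feedback_onset[i] <- trials$go_signal[i] +
        trials$reaction_time[i] + trials$movement_time[i] +
        trials$holding_pt_ms[i]
      clock <- trials$feedback_onset[i] + 600 + 1000
    }
    validate_trial_table(trials)
    trials
  })
}

# ---- spiking ----------------------------------------------------------------

# per-trial piecewise-constant gain segments (population level, Hz);
# returns data.frame(trial, t0, t1, gain)
trial_gain_segments_ <- function(trials, tuning) {
  segs <- vector("list", nrow(trials))
  for (t in seq_len(nrow(trials))) {
    scene <- trials$scene_onset[t]
    go <- trials$go_signal[t]
    fb <- trials$feedback_onset[t]
    t0 <- scene - tuning$pre_ms
    t1 <- fb + tuning$feedback_window + tuning$post_ms
    windows <- list()
    if (trials$trial_index_in_block[t] >= tuning$learning_gate_trial) {
      g <- tuning$delay_gain_hz[[trials$reward_size[t]]]
      if (g != 0) {
        windows[[length(windows) + 1L]] <-
          c(scene + tuning$delay_onset_ms, go, g)
      }
    }
    ss <- trials$stay_switch[t]
    if (!is.na(ss)) {
      g <- tuning$action_gain_hz[[ss]]
      if (g != 0) {
        windows[[length(windows) + 1L]] <-
          c(scene + tuning$action_window[1], scene + tuning$action_window[2],
            g)
      }
    }
    gfb <- tuning$feedback_gain_hz[[trials$reward_size[t]]]
    if (gfb != 0) {
      windows[[length(windows) + 1L]] <- c(fb, fb + tuning$feedback_window,
                                           gfb)
    }
    brk <- sort(unique(c(t0, t1,
                         unlist(lapply(windows, function(w) w[1:2])))))
    brk <- brk[brk >= t0 & brk <= t1]
    lo <- brk[-length(brk)]
    hi <- brk[-1]
    gain <- rep(0, length(lo))
    for (w in windows) {
      inside <- lo >= w[1] & hi <= w[2]
      gain[inside] <- gain[inside] + w[3]
    }
    segs[[t]] <- data.frame(trial = t, t0 = lo, t1 = hi, gain = gain)
  }
  do.call(rbind, segs)
}

#' Simulate Poisson spike trains for a trial table
#'
#' Inhomogeneous-Poisson spiking with piecewise-constant rates:
#' `rate = baseline + neuron_scale * (applicable gains)` within the
#' event-locked windows of the [tuning_spec()]. The delay reward gain is
#' applied only when `trial_index_in_block >= learning_gate_trial`. Rates
#' that would fall below zero are clipped at 0 (with a warning).
#'
#' @param trials a completed trial table (event times present).
#' @param tuning a [tuning_spec()].
#' @param n_neurons number of neurons to simulate.
#' @param seed integer seed (optional).
#' @return a named list of [spike_data()] objects.
#' @export
simulate_spikes <- function(trials, tuning = tuning_spec(), n_neurons = 80L,
                            seed = NULL) {
  stopifnot(inherits(tuning, "tuning_spec"), n_neurons >= 1L)
  if (anyNA(trials$scene_onset) || anyNA(trials$feedback_onset)) {
    stop("event times missing: run simulate_behavior() first", call. = FALSE)
  }
  segs <- trial_gain_segments_(trials, tuning)
  len_s <- (segs$t1 - segs$t0) / 1000
  session <- unique(trials$session_id)[1]
  with_seed_(seed, {
    scales <- stats::runif(n_neurons, tuning$gain_scale_range[1],
                           tuning$gain_scale_range[2])
    clipped <- FALSE
    spikes <- lapply(seq_len(n_neurons), function(i) {
      rate <- tuning$baseline_hz + scales[i] * segs$gain
      if (any(rate < 0)) {
        clipped <<- TRUE
        rate <- pmax(rate, 0)
      }
      counts <- stats::rpois(length(rate), rate * len_s)
      tot <- sum(counts)
      times <- rep(segs$t0, counts) +
        stats::runif(tot) * rep(segs$t1 - segs$t0, counts)
      spike_data(sprintf("n%03d", i), session, sort(times))
    })
    if (clipped) {
      warning("negative rates clipped at 0 for some segments",
              call. = FALSE)
    }
    names(spikes) <- vapply(spikes, function(s) s$neuron_id, character(1))
    spikes
  })
}

#' Generate a complete synthetic session
#'
#' Design + behavior + spiking in one call, each stage with a seed derived
#' from `seed`.
#'
#' @param n_blocks number of blocks.
#' @param n_neurons number of neurons.
#' @param params,agent,tuning stage parameter objects.
#' @param seed integer seed.
#' @param session_id session label.
#' @return `list(trials =, spikes =)`.
#' @export
simulate_session <- function(n_blocks = 10L, n_neurons = 80L,
                             params = task_design_params(n_blocks = n_blocks),
                             agent = agent_params(),
                             tuning = tuning_spec(),
                             seed = 1L, session_id = "synthetic-01") {
  design <- generate_block_design(params, seed = seed,
                                  session_id = session_id)
  trials <- simulate_behavior(design, agent, seed = seed + 1L)
  spikes <- simulate_spikes(trials, tuning, n_neurons, seed = seed + 2L)
  list(trials = trials, spikes = spikes)
}
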