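# End-to-end orchestration: synthetic generation -> behavior stats ->
# decoding -> balanced decoding -> geometry -> encoding models, driven by
# one YAML config, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' Every stochastic stage has an explicit seed; stage blocks can be
#' disabled with `enabled: false`. Sizes default to a small demonstration
#' run (full-scale reference values are 50 decoding resamples, 20 shuffles,
#' 100 projection resamples over 63 bins per epoch).
#'
#' @return nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    session_id = "synthetic-01",
    simulate = list(enabled = TRUE, n_blocks = 10L, n_neurons = 40L,
                    seed = 101L),
    behavior = list(enabled = TRUE),
    decode = list(enabled = TRUE, epoch = "feedback_onset",
                  span = c(-500, 1300), bin_width = 250, bin_step = 100,
                  n_per_condition = 20L, n_resamples = 5L, k = 5L,
                  n_shuffles = 4L, seed = 202L),
    balanced = list(enabled = TRUE, window = c(800, 1000),
                    min_per_cell = 10L, folds = 10L, n_shuffles = 25L,
                    seed = 303L),
    geometry = list(enabled = TRUE, epoch = "feedback_onset",
                    span = c(-500, 1300), bin_width = 250, bin_step = 100,
                    n_per_condition = 20L, n_resamples = 30L, seed = 404L),
    encode = list(enabled = TRUE, delay_window = c(400, 800),
                  feedback_window = c(0, 400), seed = 505L)
  )
}

# deep-merge user config over defaults
merge_config_ <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config_(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration
#'
#' YAML file merged over [default_pipeline_config()].
#' @param path YAML file, or `NULL` for the defaults.
#' @return config list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    cfg <- merge_config_(cfg, yaml::read_yaml(path))
  }
  cfg
}

stage_enabled_ <- function(cfg, stage) isTRUE(cfg[[stage]]$enabled)

#' Run the full analysis pipeline
#'
#' Generates (or loads) a session, then runs the enabled stages and writes
#' every stage report as CSV plus a `manifest.json` (package version,
#' config echo, per-stage wall time, seeds) into `out_dir`. Deterministic
#' given the seeds in the config.
#'
#' @param config a config list ([read_pipeline_config()]) or a YAML path.
#' @param out_dir output directory (created if needed).
#' @param session optional `list(trials =, spikes =)` to analyze instead of
#'   simulating.
#' @return invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("oipr_run_"), session = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("oiprdecode")),
                   config = config, stages = list())
  results <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    manifest$stages[[name]] <<- list(seconds =
                                       proc.time()[["elapsed"]] - t0)
    val
  }

  # -- simulate ---------------------------------------------------------------
  if (is.null(session)) {
    if (!stage_enabled_(config, "simulate")) {
      stop("pipeline error [simulate]: no session supplied and simulation ",
           "disabled", call. = FALSE)
    }
    sim <- config$simulate
    session <- timed("simulate", simulate_session(
      n_blocks = sim$n_blocks, n_neurons = sim$n_neurons, seed = sim$seed,
      session_id = config$session_id))
    write_session(session$trials, session$spikes,
                  file.path(out_dir, "trials.csv"),
                  file.path(out_dir, "spikes.csv"))
  }
  trials <- session$trials
  spikes <- session$spikes
  results$session <- session

  # -- behavior ---------------------------------------------------------------
  if (stage_enabled_(config, "behavior")) {
    rep <- timed("behavior", behavior_report(trials))
    for (nm in names(rep)) {
      if (!is.null(rep[[nm]])) {
        utils::write.csv(rep[[nm]],
                         file.path(out_dir, paste0("behavior_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
    results$behavior <- rep
  }

  # -- decoding ---------------------------------------------------------------
  if (stage_enabled_(config, "decode")) {
    dc <- config$decode
    results$decode <- timed("decode", {
      binned <- bin_spike_counts(spikes, trials, dc$epoch,
                                 span = dc$span, bin_width = dc$bin_width,
                                 bin_step = dc$bin_step)
      spec <- decoder_spec(k = dc$k, n_resamples = dc$n_resamples)
      res <- decode_timecourse(binned, trials$reward_size, spec,
                               n_per_condition = dc$n_per_condition,
                               seed = dc$seed)
      null <- build_null(binned, trials$reward_size, spec,
                         n_per_condition = dc$n_per_condition,
                         n_shuffles = dc$n_shuffles, seed = dc$seed + 1L)
      sig <- assess_significance(res, null)
      utils::write.csv(
        cbind(sig, sd_accuracy = res$sd_accuracy, chance = res$chance),
        file.path(out_dir, "decoding_reward.csv"), row.names = FALSE)
      list(result = res, null = null, significance = sig)
    })
  }

  # -- balanced decoding ------------------------------------------------------
  if (stage_enabled_(config, "balanced")) {
    bc <- config$balanced
    results$balanced <- timed("balanced", {
      x <- epoch_rates(spikes, trials, "scene_onset", bc$window)
      reward2 <- ifelse(trials$reward_size == "small", "small", "med_large")
      bd <- balanced_decode(x, reward2, trials$stay_switch,
                            folds = bc$folds,
                            min_per_cell = bc$min_per_cell,
                            n_shuffles = bc$n_shuffles, seed = bc$seed)
      utils::write.csv(
        data.frame(variable = c("reward_small_vs_medlarge",
                                "action_stay_vs_switch"),
                   accuracy = c(bd$variable_a$accuracy,
                                bd$variable_b$accuracy),
                   p_value = c(bd$variable_a$p_value,
                               bd$variable_b$p_value),
                   stars = c(bd$variable_a$stars, bd$variable_b$stars),
                   chance = bd$chance),
        file.path(out_dir, "balanced_decoding.csv"), row.names = FALSE)
      bd
    })
  }

  # -- geometry ---------------------------------------------------------------
  if (stage_enabled_(config, "geometry")) {
    gc_ <- config$geometry
    results$geometry <- timed("geometry", {
      binned <- bin_spike_counts(spikes, trials, gc_$epoch,
                                 span = gc_$span,
                                 bin_width = gc_$bin_width,
                                 bin_step = gc_$bin_step)
      pr <- run_projection_analysis(binned, trials$reward_size,
                                    n_per_condition = gc_$n_per_condition,
                                    n_resamples = gc_$n_resamples,
                                    seed = gc_$seed)
      ov <- data.frame(bin_center = rep(pr$bin_centers,
                                        each = length(pr$pair_names)),
                       pair = rep(pr$pair_names, length(pr$bin_centers)),
                       overlap = as.vector(pr$overlap),
                       significant = as.vector(pr$significant))
      utils::write.csv(ov, file.path(out_dir, "geometry_overlap.csv"),
                       row.names = FALSE)
      pr
    })
  }

  # -- encoding models --------------------------------------------------------
  if (stage_enabled_(config, "encode")) {
    ec <- config$encode
    results$encode <- timed("encode", {
      rt_mov <- trials$reaction_time + trials$movement_time
      part <- list()
      for (ep in c("delay", "feedback")) {
        ev <- if (ep == "delay") "scene_onset" else "feedback_onset"
        win <- if (ep == "delay") ec$delay_window else ec$feedback_window
        rates <- epoch_rates(spikes, trials, ev, win)
        part[[ep]] <- population_variance_partition(
          rates, rt_mov, trials$reward_size, epoch = ep)
      }
      part <- do.call(rbind, part)
      utils::write.csv(part, file.path(out_dir, "variance_partition.csv"),
                       row.names = FALSE)
      part
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(out_dir = out_dir, manifest = manifest)))
}
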