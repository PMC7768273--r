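# End-to-end orchestration: synthesize (or load) a recording, build the
# state-space trajectory, fit control-period boundaries, score NRt, compute
# bout statistics and condition effects, and write a manifest sufficient to
# re-run bit-identically.

default_pipeline_config <- function() {
  list(
    n_epochs = 1500,
    control_frac = 0.5,       # first fraction of epochs = control period
    smooth_window = 5,
    drug = TRUE,              # also generate and score a drug condition
    synth = list()            # overrides for synth_config()
  )
}

validate_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    abort(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  config <- utils::modifyList(base, config)
  if (!is.numeric(config$n_epochs) || config$n_epochs < 200)
    abort("config$n_epochs must be >= 200")
  if (config$control_frac <= 0 || config$control_frac >= 1)
    abort("config$control_frac must be in (0, 1)")
  config
}

#' Score a recording against control-period boundaries
#'
#' Convenience wrapper over the scoring chain: trajectory, control-period
#' intersections, state boundaries, NRt space, 4-stage scoring, bout
#' statistics. Boundaries are defined from the control epochs and reused to
#' score the whole recording.
#'
#' @param powers Band-power tibble.
#' @param hypnogram3 3-stage hypnogram tibble.
#' @param control_epochs Epoch indices of the control period.
#' @param smooth_window Trajectory smoothing window (default 5).
#' @return List with `trajectory`, `boundaries`, `nrt_space`, `scored`
#'   (4-stage tibble), and `bouts` (`bout_table`).
#' @export
score_recording <- function(powers, hypnogram3, control_epochs,
                            smooth_window = 5) {
  traj <- compute_trajectory(powers, smooth_window = smooth_window)
  ctrl <- traj$epoch_index %in% control_epochs
  traj_c <- traj[ctrl, , drop = FALSE]
  hyp_c <- hypnogram3[hypnogram3$epoch_index %in% control_epochs, , drop = FALSE]
  events <- find_intersections(traj_c)
  bounds <- fit_state_boundaries(events, traj_c, hyp_c)
  space <- define_nrt_space(traj_c, hyp_c, bounds)
  scored <- score_4stage(traj, hypnogram3, bounds, space)
  hyp4 <- tibble::tibble(epoch_index = scored$epoch_index, label = scored$label)
  list(trajectory = traj, boundaries = bounds, nrt_space = space,
       scored = scored, bouts = bout_stats(hyp4))
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates baseline (and optionally drug) recordings, scores them with
#' boundaries defined on the baseline control period, writes all stage
#' outputs as CSV/JSON under `out_dir`, and writes `manifest.json`
#' (config snapshot, seeds, package version, output file hashes) that
#' re-runs bit-identically with the same config and seed.
#'
#' @param config Named list (see `default_pipeline_config()`), or a path to
#'   a YAML file with those fields.
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level seed; stage sub-seeds derive from it via
#'   [split_seed()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(synth_config, config$synth)
  conditions <- c("baseline", if (isTRUE(config$drug)) "drug")
  ctrl_epochs <- seq_len(floor(config$n_epochs * config$control_frac))

  summaries <- list()
  files <- character(0)
  bounds0 <- NULL
  for (cond in conditions) {
    rec <- generate_recording(cfg, config$n_epochs,
                              seed = split_seed(seed, paste0("synth_", cond)),
                              condition = cond)
    res <- score_recording(rec$band_powers, rec$hypnogram3, ctrl_epochs,
                           smooth_window = config$smooth_window)
    if (cond == "baseline") bounds0 <- res$boundaries
    prefix <- file.path(out_dir, cond)
    write_band_powers(rec$band_powers, paste0(prefix, "_bandpower.csv"))
    write_hypnogram(rec$hypnogram3, paste0(prefix, "_hyp3.csv"))
    write_hypnogram(tibble::tibble(epoch_index = res$scored$epoch_index,
                                   label = res$scored$label),
                    paste0(prefix, "_hyp4.csv"))
    readr::write_csv(res$bouts$bouts, paste0(prefix, "_bouts.csv"))
    readr::write_csv(res$bouts$summary, paste0(prefix, "_bout_summary.csv"))
    write_boundaries_json(res$boundaries, paste0(prefix, "_boundaries.json"),
                          nrt_space = res$nrt_space)
    files <- c(files, paste0(prefix, c("_bandpower.csv", "_hyp3.csv",
                                       "_hyp4.csv", "_bouts.csv",
                                       "_bout_summary.csv",
                                       "_boundaries.json")))
    summaries[[cond]] <- res$bouts$summary
  }

  manifest <- list(
    package = "sleepswitch",
    version = as.character(utils::packageVersion("sleepswitch")),
    seed = seed,
    config = config,
    stage_seeds = lapply(setNames(conditions, conditions), function(cond)
      split_seed(seed, paste0("synth_", cond))),
    summaries = summaries,
    file_hashes = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
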