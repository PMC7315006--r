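#' Pipeline configuration
#'
#' Bundles every tunable threshold of the analysis pipeline with its
#' default. Configurations round-trip through YAML via
#' [write_config()] / [read_config()], and every output file written by
#' the command wrappers carries the configuration hash.
#'
#' @param mm_per_px Spatial calibration, mm/px.
#' @param fps Frame rate, frames/s.
#' @param likelihood_threshold Cleaning gate on detection confidence.
#' @param jump_px Optional jump gate, px/frame (`NULL` = off).
#' @param smoothing_window Speed-estimation smoothing window, frames.
#' @param prey_ref Prey reference point (`"eyes_mid"`, `"hook"`,
#'   `"centroid"`).
#' @param alpha_max,t_min,gap_max Attention-episode thresholds
#'   (degrees, s, s).
#' @param e_on,v_on Strike detection thresholds (ML, ML/s).
#' @param extension_threshold Tentacle-extended gate, ML.
#' @param v_still,v_split Prey-phase speed thresholds, mm/s.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mm_per_px = 0.5, fps = 90,
                            likelihood_threshold = 0.9, jump_px = NULL,
                            smoothing_window = 5, prey_ref = "eyes_mid",
                            alpha_max = 30, t_min = 1, gap_max = 0.5,
                            e_on = 0.5, v_on = 2,
                            extension_threshold = 0.35,
                            v_still = 5, v_split = 50) {
  if (likelihood_threshold < 0 || likelihood_threshold > 1)
    stop("`likelihood_threshold` must lie in [0, 1]", call. = FALSE)
  if (!(v_still < v_split))
    stop("`v_still` must be below `v_split`", call. = FALSE)
  if (smoothing_window < 1 || smoothing_window %% 2 == 0)
    stop("`smoothing_window` must be a positive odd integer",
         call. = FALSE)
  structure(list(mm_per_px = mm_per_px, fps = fps,
                 likelihood_threshold = likelihood_threshold,
                 jump_px = jump_px, smoothing_window = smoothing_window,
                 prey_ref = prey_ref, alpha_max = alpha_max,
                 t_min = t_min, gap_max = gap_max, e_on = e_on,
                 v_on = v_on, extension_threshold = extension_threshold,
                 v_still = v_still, v_split = v_split),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Hash of a pipeline configuration
#'
#' MD5 of the YAML serialisation; stamped into every output file for
#' provenance.
#'
#' @param config A [pipeline_config()].
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Analyse a pursuit trial
#'
#' The central entry point: takes a raw pose track through cleaning,
#' kinematics, prey-phase classification, attention-episode and strike
#' segmentation, and the per-trial paired velocity summary, returning a
#' single object that the print, summary and plot methods describe.
#'
#' @param track A [pose_track()] (e.g. from [read_dlc_csv()] or the
#'   simulator).
#' @param config A [pipeline_config()]; defaults match the track's
#'   metadata where they overlap.
#' @return An object of class `pursuit_analysis` with components
#'   `config`, `clean`, `kinematics`, `phase`, `episodes`, `strikes`,
#'   `strike_timing` and `velocity_summary`.
#' @export
#' @examples
#' tr <- simulate_trial(sim_scenario(seed = 3, duration_s = 10))
#' fit <- analyze_pursuit(tr$track)
#' summary(fit)
analyze_pursuit <- function(track, config = NULL) {
  stopifnot(inherits(track, "pose_track"))
  if (is.null(config))
    config <- pipeline_config(mm_per_px = track$metadata$mm_per_px,
                              fps = track$metadata$fps)
  clean <- clean_pose_track(track, config$likelihood_threshold,
                            config$jump_px)
  kin <- compute_kinematics(clean, prey_ref = config$prey_ref,
                            smoothing_window = config$smoothing_window,
                            extension_threshold =
                              config$extension_threshold)
  phase <- classify_prey_phase(kin$prey_speed_mm_s,
                               fps = track$metadata$fps,
                               v_still = config$v_still,
                               v_split = config$v_split)
  episodes <- detect_attention_episodes(kin, config$alpha_max,
                                        config$t_min, config$gap_max)
  strikes <- detect_strikes(kin, config$e_on, config$v_on)
  timing <- if (nrow(strikes) > 0) strike_timing(strikes, phase) else NULL
  vel <- if (nrow(episodes) > 0)
    paired_velocity_summary(kin, phase, episodes) else NULL
  structure(list(config = config, clean = clean, kinematics = kin,
                 phase = phase, episodes = episodes, strikes = strikes,
                 strike_timing = timing, velocity_summary = vel,
                 metadata = track$metadata),
            class = "pursuit_analysis")
}

#' @export
print.pursuit_analysis <- function(x, ...) {
  cat(sprintf("Pursuit analysis of trial %s/%s (%d frames)\n",
              x$metadata$animal_id, x$metadata$trial_id,
              nrow(x$kinematics)))
  cat(sprintf("  attention episodes: %d (total %.1f s)\n",
              nrow(x$episodes), sum(x$episodes$duration_s)))
  cat(sprintf("  tentacular strikes: %d\n", nrow(x$strikes)))
  invisible(x)
}

#' @export
summary.pursuit_analysis <- function(object, ...) {
  out <- list(
    trial = sprintf("%s/%s", object$metadata$animal_id,
                    object$metadata$trial_id),
    n_frames = nrow(object$kinematics),
    interpolated_fraction = mean(object$clean$interpolated),
    n_episodes = nrow(object$episodes),
    total_attention_s = sum(object$episodes$duration_s),
    n_strikes = nrow(object$strikes),
    velocity_summary = object$velocity_summary,
    episodes = object$episodes,
    strikes = object$strikes)
  class(out) <- "summary.pursuit_analysis"
  out
}

#' @export
print.summary.pursuit_analysis <- function(x, ...) {
  cat(sprintf("Trial %s: %d frames (%.1f%% interpolated)\n", x$trial,
              x$n_frames, 100 * x$interpolated_fraction))
  cat(sprintf("Attention: %d episode(s), %.1f s total\n", x$n_episodes,
              x$total_attention_s))
  if (x$n_episodes > 0) {
    print(format(as.data.frame(x$episodes), digits = 3))
  }
  if (!is.null(x$velocity_summary)) {
    cat(sprintf("Mean |speed| in episodes: slow %.1f mm/s, fast %.1f mm/s\n",
                x$velocity_summary$mean_speed_slow,
                x$velocity_summary$mean_speed_fast))
  }
  cat(sprintf("Strikes: %d\n", x$n_strikes))
  if (x$n_strikes > 0)
    print(format(as.data.frame(x$strikes), digits = 3))
  invisible(x)
}

#' Plot a pursuit analysis
#'
#' Three stacked panels against time: horizontal speeds of prey and
#' cuttlefish, the visual attack angle with attention episodes shaded,
#' and tentacle extension with detected strikes shaded.
#'
#' @param x A `pursuit_analysis`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.pursuit_analysis <- function(x, ...) {
  kin <- x$kinematics
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  shade <- function(iv, col) {
    if (nrow(iv) > 0)
      graphics::rect(iv[[1]], graphics::par("usr")[3], iv[[2]],
                     graphics::par("usr")[4], col = col, border = NA)
  }
  graphics::plot(kin$time_s, kin$prey_speed_mm_s, type = "l",
                 col = "steelblue", xlab = "", ylab = "speed (mm/s)")
  graphics::lines(kin$time_s, kin$cutt_speed_mm_s, col = "darkorange")
  graphics::legend("topright", c("prey", "cuttlefish"), lty = 1,
                   col = c("steelblue", "darkorange"), bty = "n")
  graphics::plot(kin$time_s, kin$alpha_deg, type = "n", xlab = "",
                 ylab = expression(alpha ~ (deg)))
  shade(x$episodes[, c("start_s", "end_s")],
        grDevices::adjustcolor("palegreen", 0.4))
  graphics::lines(kin$time_s, kin$alpha_deg)
  ext <- pmax(kin$ext_left_ml, kin$ext_right_ml)
  graphics::plot(kin$time_s, ext, type = "n", xlab = "time (s)",
                 ylab = "extension (ML)")
  if (nrow(x$strikes) > 0)
    shade(x$strikes[, c("onset_s", "end_s")],
          grDevices::adjustcolor("gold", 0.5))
  graphics::lines(kin$time_s, ext)
  invisible(x)
}

#' Export episode and strike tables as tidy CSV
#'
#' Episode tables are written in the same schema as the packaged
#' reference table (`animal`, `trial`, `attempt`, `success`,
#' `duration_s`, `pre_strike`), so real annotations and pipeline output
#' are interchangeable for the statistics stage.
#'
#' @param fit A `pursuit_analysis`.
#' @param episodes_path,strikes_path Output paths (`NULL` skips).
#' @return Named vector of written paths, invisibly.
#' @export
export_tables <- function(fit, episodes_path = NULL, strikes_path = NULL) {
  stopifnot(inherits(fit, "pursuit_analysis"))
  written <- character(0)
  md <- fit$metadata
  if (!is.null(episodes_path)) {
    ep <- fit$episodes
    pre <- rep(FALSE, nrow(ep))
    # an episode is pre-strike when a detected strike begins within it
    # or within one second after it
    if (nrow(fit$strikes) > 0 && nrow(ep) > 0) {
      for (i in seq_len(nrow(ep)))
        pre[i] <- any(fit$strikes$onset_s >= ep$start_s[i] &
                        fit$strikes$onset_s <= ep$end_s[i] + 1)
    }
    out <- data.frame(animal = md$animal_id, trial = md$trial_id,
                      attempt = nrow(fit$strikes) > 0,
                      success = NA, duration_s = ep$duration_s,
                      pre_strike = pre,
                      start_s = ep$start_s, end_s = ep$end_s)
    utils::write.csv(out, episodes_path, row.names = FALSE)
    written["episodes"] <- episodes_path
  }
  if (!is.null(strikes_path)) {
    st <- as.data.frame(fit$strikes)
    if (!is.null(fit$strike_timing)) st <- cbind(st, fit$strike_timing)
    st$animal <- md$animal_id
    st$trial <- md$trial_id
    utils::write.csv(st, strikes_path, row.names = FALSE)
    written["strikes"] <- strikes_path
  }
  invisible(written)
}
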