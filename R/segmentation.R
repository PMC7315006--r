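#' Classify prey motion phases
#'
#' Labels every frame of a prey speed series as `stationary`
#' (|v| < `v_still`), `slow` (`v_still` <= |v| < `v_split`) or `fast`
#' (|v| >= `v_split`), matching the rig's protocol of a slow leg in one
#' direction and a fast leg in the other. Labels are median-filtered
#' over 5 frames to suppress flicker at the thresholds. Reversals are
#' the instants where the sign of the (non-stationary) speed flips.
#'
#' @param prey_speed Numeric vector of signed prey speed, mm/s.
#' @param fps Frames per second.
#' @param v_still Stationary threshold, mm/s (default 5).
#' @param v_split Slow/fast split, mm/s (default 50).
#' @return An object of class `prey_phase`: list with `label` (factor
#'   per frame), `reversal_times_s` (numeric) and `fps`.
#' @export
classify_prey_phase <- function(prey_speed, fps, v_still = 5,
                                v_split = 50) {
  if (!(v_still < v_split))
    stop("`v_still` must be smaller than `v_split`", call. = FALSE)
  if (v_still < 0) stop("thresholds must be non-negative", call. = FALSE)
  n <- length(prey_speed)
  a <- abs(prey_speed)
  code <- ifelse(a < v_still, 0L, ifelse(a < v_split, 1L, 2L))
  if (n >= 5) code <- as.integer(stats::runmed(code, 5))
  lab <- factor(c("stationary", "slow", "fast")[code + 1L],
                levels = c("stationary", "slow", "fast"))
  # reversal = sign change between consecutive non-stationary frames
  moving <- which(code > 0L)
  rev_t <- numeric(0)
  if (length(moving) > 1) {
    s <- sign(prey_speed[moving])
    flip <- which(s[-1] * s[-length(s)] < 0)
    if (length(flip) > 0)
      rev_t <- (moving[flip] + moving[flip + 1] - 2) / 2 / fps
  }
  structure(list(label = lab, reversal_times_s = rev_t, fps = fps),
            class = "prey_phase")
}

#' @export
print.prey_phase <- function(x, ...) {
  cat(sprintf("<prey_phase> %d frames: %s; %d reversal(s)\n",
              length(x$label),
              paste(sprintf("%s %.0f%%", levels(x$label),
                            100 * prop.table(table(x$label))),
                    collapse = ", "),
              length(x$reversal_times_s)))
  invisible(x)
}

.merge_runs <- function(ok, fps, t_min, gap_max) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  iv <- data.frame(start_frame = starts[on], end_frame = ends[on])
  # merge interruptions shorter than gap_max
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      gap <- (iv$start_frame[i] - merged$end_frame[nrow(merged)] - 1) / fps
      if (gap < gap_max) {
        merged$end_frame[nrow(merged)] <- iv$end_frame[i]
      } else {
        merged <- rbind(merged, iv[i, ])
      }
    }
  }
  dur <- (merged$end_frame - merged$start_frame + 1) / fps
  merged[dur >= t_min, , drop = FALSE]
}

#' Detect attention episodes
#'
#' Attention is operationalised as body alignment toward the prey:
#' maximal intervals in which the visual attack angle stays within
#' `alpha_max` degrees of zero. Interruptions shorter than `gap_max`
#' seconds are bridged, and intervals shorter than `t_min` seconds are
#' dropped. This is a reconstruction of the behavioural scoring, with
#' all thresholds exposed.
#'
#' @param kin A `kinematic_series`.
#' @param alpha_max Alignment tolerance, degrees (default 30).
#' @param t_min Minimum episode duration, seconds (default 1).
#' @param gap_max Maximum bridged interruption, seconds (default 0.5).
#' @return A `data.frame` of class `episodes` with columns `start_s`,
#'   `end_s`, `duration_s` (end-exclusive frame convention, so a full
#'   trial yields `duration_s` equal to the session length).
#' @export
detect_attention_episodes <- function(kin, alpha_max = 30, t_min = 1,
                                      gap_max = 0.5) {
  stopifnot(inherits(kin, "kinematic_series"))
  if (alpha_max <= 0 || t_min < 0 || gap_max < 0)
    stop("invalid segmentation thresholds", call. = FALSE)
  fps <- attr(kin, "metadata")$fps
  ok <- !is.na(kin$alpha_deg) & abs(kin$alpha_deg) <= alpha_max
  iv <- .merge_runs(ok, fps, t_min, gap_max)
  out <- data.frame(
    start_s = (iv$start_frame - 1) / fps,
    end_s = iv$end_frame / fps)
  out$duration_s <- out$end_s - out$start_s
  class(out) <- c("episodes", "data.frame")
  out
}

#' Detect tentacular strikes
#'
#' A strike is a rapid ballistic extension of the tentacles: per side,
#' the extension series crosses `e_on` mantle lengths upward with an
#' extension rate of at least `v_on` mantle lengths per second, and the
#' event lasts until extension falls back below `e_on`. The tentacles
#' are shot as a pair, so detections on the two sides whose onsets fall
#' within `merge_ms` are merged into one event. For each event the peak
#' extension, the visual attack angle at onset (the strike angle), and
#' the excursion of each eye angle over the window from half a second
#' before onset to the event end are recorded.
#'
#' @param kin A `kinematic_series`.
#' @param e_on Extension threshold, mantle lengths (default 0.5).
#' @param v_on Minimum extension rate at onset, ML/s (default 2).
#' @param merge_ms Bilateral merge window, milliseconds (default 100).
#' @param beta_pre_s Look-back before onset for the eye-angle
#'   excursion, seconds (default 0.5).
#' @return A `data.frame` of class `strike_events` with columns
#'   `onset_s`, `end_s`, `side`, `peak_extension_ml`,
#'   `strike_angle_deg`, `delta_beta_left_deg`, `delta_beta_right_deg`,
#'   `success` (`NA`; to be filled from ground truth or annotation,
#'   never inferred from kinematics).
#' @export
detect_strikes <- function(kin, e_on = 0.5, v_on = 2, merge_ms = 100,
                           beta_pre_s = 0.5) {
  stopifnot(inherits(kin, "kinematic_series"))
  md <- attr(kin, "metadata")
  fps <- md$fps
  if (!is.finite(attr(kin, "mantle_scale_px")) ||
      attr(kin, "mantle_scale_px") <= 0)
    stop("mantle-length scale undefined", call. = FALSE)
  n <- nrow(kin)
  ev <- list()
  for (side in c("left", "right")) {
    e <- kin[[paste0("ext_", side, "_ml")]]
    if (n < 3) break
    de <- c(e[2] - e[1], (e[3:n] - e[1:(n - 2)]) / 2, e[n] - e[n - 1]) * fps
    above <- e >= e_on
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      # rate condition at the upward crossing (skip slow drifts)
      if (max(de[i0:min(i0 + 2L, i1)]) < v_on) next
      ev[[length(ev) + 1]] <- data.frame(
        side = side,
        onset_frame = i0, end_frame = i1,
        peak_extension_ml = max(e[i0:i1]))
    }
  }
  if (length(ev) == 0) {
    out <- data.frame(onset_s = numeric(0), end_s = numeric(0),
                      side = character(0), peak_extension_ml = numeric(0),
                      strike_angle_deg = numeric(0),
                      delta_beta_left_deg = numeric(0),
                      delta_beta_right_deg = numeric(0),
                      success = logical(0))
    class(out) <- c("strike_events", "data.frame")
    return(out)
  }
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$onset_frame), , drop = FALSE]
  # merge bilateral detections whose onsets fall within merge_ms
  merged <- ev[1, , drop = FALSE]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      j <- nrow(merged)
      if ((ev$onset_frame[i] - merged$onset_frame[j]) / fps * 1000 <=
          merge_ms && !identical(ev$side[i], merged$side[j])) {
        merged$side[j] <- "both"
        merged$end_frame[j] <- max(merged$end_frame[j], ev$end_frame[i])
        merged$peak_extension_ml[j] <- max(merged$peak_extension_ml[j],
                                           ev$peak_extension_ml[i])
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
  }
  pre <- round(beta_pre_s * fps)
  out <- data.frame(
    onset_s = (merged$onset_frame - 1) / fps,
    end_s = merged$end_frame / fps,
    side = merged$side,
    peak_extension_ml = merged$peak_extension_ml,
    strike_angle_deg = kin$alpha_deg[merged$onset_frame],
    delta_beta_left_deg = NA_real_,
    delta_beta_right_deg = NA_real_,
    success = NA)
  for (i in seq_len(nrow(merged))) {
    w <- max(1L, merged$onset_frame[i] - pre):merged$end_frame[i]
    bl <- kin$beta_left_deg[w]; br <- kin$beta_right_deg[w]
    out$delta_beta_left_deg[i] <- diff(range(bl, na.rm = TRUE))
    out$delta_beta_right_deg[i] <- diff(range(br, na.rm = TRUE))
  }
  class(out) <- c("strike_events", "data.frame")
  out
}

#' Paired cuttlefish speed summary by prey phase
#'
#' Mean absolute horizontal cuttlefish speed over attention-episode
#' frames, split by the prey's motion phase. One (slow, fast) pair per
#' trial, the unit entering the paired signed-rank comparison. A phase
#' absent within the episodes yields `NA` and a missing-phase flag.
#'
#' @param kin A `kinematic_series`.
#' @param phase A [classify_prey_phase()] result for the same frames.
#' @param episodes An `episodes` data frame.
#' @return One-row `data.frame` with `mean_speed_slow`,
#'   `mean_speed_fast` (mm/s), frame counts and `missing_phase`.
#' @export
paired_velocity_summary <- function(kin, phase, episodes) {
  stopifnot(inherits(kin, "kinematic_series"))
  if (nrow(episodes) == 0)
    stop("at least one attention episode is required", call. = FALSE)
  t <- kin$time_s
  in_ep <- rep(FALSE, nrow(kin))
  for (i in seq_len(nrow(episodes)))
    in_ep <- in_ep | (t >= episodes$start_s[i] & t < episodes$end_s[i])
  v <- abs(kin$cutt_speed_mm_s)
  slow <- in_ep & phase$label == "slow"
  fast <- in_ep & phase$label == "fast"
  data.frame(
    mean_speed_slow = if (any(slow)) mean(v[slow]) else NA_real_,
    mean_speed_fast = if (any(fast)) mean(v[fast]) else NA_real_,
    n_slow_frames = sum(slow), n_fast_frames = sum(fast),
    missing_phase = !any(slow) || !any(fast))
}

#' Strike timing relative to the prey's motion
#'
#' For each strike, the prey phase at onset and the time elapsed since
#' the most recent reversal of the prey's direction (`Inf` when no
#' reversal precedes the onset).
#'
#' @param strikes A `strike_events` data frame.
#' @param phase A [classify_prey_phase()] result.
#' @return `data.frame` with `phase_at_onset` and
#'   `time_since_reversal_s`, one row per strike.
#' @export
strike_timing <- function(strikes, phase) {
  n <- nrow(strikes)
  out <- data.frame(phase_at_onset = character(n),
                    time_since_reversal_s = numeric(n))
  for (i in seq_len(n)) {
    fr <- min(length(phase$label),
              max(1L, round(strikes$onset_s[i] * phase$fps) + 1L))
    out$phase_at_onset[i] <- as.character(phase$label[fr])
    prev <- phase$reversal_times_s[phase$reversal_times_s <=
                                     strikes$onset_s[i]]
    out$time_since_reversal_s[i] <-
      if (length(prev) == 0) Inf else strikes$onset_s[i] - max(prev)
  }
  out
}
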