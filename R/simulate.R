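# Ground-truthed pursuit simulator emulating the experimental rig: a
# shrimp target on a one-dimensional rail moving slowly leftward and
# fast rightward with instantaneous reversals, and a cuttlefish agent
# that tracks the delayed prey velocity during attention windows and
# launches scripted ballistic tentacular strikes. Everything is
# deterministic given the scenario; observation noise enters only when
# poses are rendered.

#' Define a simulation scenario
#'
#' All study conditions live here: the rig protocol (rail span, slow
#' and fast speeds, session length, frame rate), the agent (mantle
#' length, phase-dependent pursuit gains, sensorimotor delay, turning
#' rate), the attention schedule, the scripted strikes, and the
#' pose-level observation model (coordinate noise, occlusion rate).
#'
#' @param seed Integer RNG seed for pose rendering.
#' @param duration_s Session length, seconds (default 120).
#' @param fps Frames per second (default 90).
#' @param rail_span_mm Length of the prey rail, mm (default 250).
#' @param v_slow_mm_s Slow (leftward) prey speed, mm/s (default 25).
#' @param v_fast_mm_s Fast (rightward) prey speed, mm/s (default 75).
#' @param mantle_len_mm Cuttlefish mantle length, mm (default 80).
#' @param mm_per_px Calibration (default 0.5 mm/px).
#' @param frame_size Image size in px (default 2048 x 2048).
#' @param pursuit_gain_slow,pursuit_gain_fast Fraction of the delayed
#'   prey velocity matched by the agent in each phase, in \[0, 1\]
#'   (defaults 0.9 and 0.05: the agent keeps up with slow prey and all
#'   but freezes for fast prey).
#' @param sensorimotor_delay_ms Visual-to-motor latency (default 150).
#' @param turn_rate_max_deg_s Maximum heading turn rate (default 90).
#' @param attention_schedule `"auto"` (attending the whole session) or
#'   a list of `c(start_s, end_s)` windows.
#' @param strikes List of strike commands, each a list with `time_s`,
#'   and optionally `predictive` (default `TRUE`),
#'   `terminal_correction_deg` (default 0), `duration_ms` (default
#'   120), `peak_extension_ml` (default 1.8).
#' @param noise_sigma_px Gaussian coordinate noise, px (default 1).
#' @param occlusion_prob Per frame-and-part occlusion probability
#'   (default 0.02).
#' @param standoff_mm Perpendicular distance from the agent to the
#'   rail, mm (default 100).
#' @param success_radius_mm Tip-to-prey distance counting as a capture,
#'   mm (default 5; a free simulator parameter of the order of a shrimp
#'   body width).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(seed = 1L, duration_s = 120, fps = 90,
                         rail_span_mm = 250, v_slow_mm_s = 25,
                         v_fast_mm_s = 75, mantle_len_mm = 80,
                         mm_per_px = 0.5, frame_size = c(2048L, 2048L),
                         pursuit_gain_slow = 0.9,
                         pursuit_gain_fast = 0.05,
                         sensorimotor_delay_ms = 150,
                         turn_rate_max_deg_s = 90,
                         attention_schedule = "auto",
                         strikes = list(),
                         noise_sigma_px = 1.0, occlusion_prob = 0.02,
                         standoff_mm = 100, success_radius_mm = 5) {
  pos <- c(duration_s = duration_s, fps = fps, rail_span_mm = rail_span_mm,
           v_slow_mm_s = v_slow_mm_s, v_fast_mm_s = v_fast_mm_s,
           mantle_len_mm = mantle_len_mm, mm_per_px = mm_per_px,
           turn_rate_max_deg_s = turn_rate_max_deg_s,
           standoff_mm = standoff_mm, success_radius_mm = success_radius_mm)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad) > 0)
    stop("scenario parameters must be positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (pursuit_gain_slow < 0 || pursuit_gain_slow > 1 ||
      pursuit_gain_fast < 0 || pursuit_gain_fast > 1)
    stop("pursuit gains must lie in [0, 1]", call. = FALSE)
  if (sensorimotor_delay_ms < 0 || noise_sigma_px < 0 ||
      occlusion_prob < 0 || occlusion_prob > 1)
    stop("invalid observation/delay parameters", call. = FALSE)
  strikes <- lapply(strikes, function(st) {
    st <- utils::modifyList(list(predictive = TRUE,
                                 terminal_correction_deg = 0,
                                 duration_ms = 120,
                                 peak_extension_ml = 1.8), st)
    if (is.null(st$time_s))
      stop("each strike command needs `time_s`", call. = FALSE)
    if (st$time_s < 0 || st$time_s >= duration_s)
      stop("strike time outside the session", call. = FALSE)
    st
  })
  if (!identical(attention_schedule, "auto")) {
    for (w in attention_schedule)
      if (length(w) != 2 || w[1] < 0 || w[2] <= w[1] || w[2] > duration_s)
        stop("attention windows must be c(start_s, end_s) within the session",
             call. = FALSE)
  }
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 fps = fps, rail_span_mm = rail_span_mm,
                 v_slow_mm_s = v_slow_mm_s, v_fast_mm_s = v_fast_mm_s,
                 mantle_len_mm = mantle_len_mm, mm_per_px = mm_per_px,
                 frame_size = frame_size,
                 pursuit_gain_slow = pursuit_gain_slow,
                 pursuit_gain_fast = pursuit_gain_fast,
                 sensorimotor_delay_ms = sensorimotor_delay_ms,
                 turn_rate_max_deg_s = turn_rate_max_deg_s,
                 attention_schedule = attention_schedule,
                 strikes = strikes, noise_sigma_px = noise_sigma_px,
                 occlusion_prob = occlusion_prob,
                 standoff_mm = standoff_mm,
                 success_radius_mm = success_radius_mm),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("<sim_scenario> seed %d: %g s @ %g fps, rail %g mm ",
                     "(%g / %g mm/s), %d strike(s), noise %g px\n"),
              x$seed, x$duration_s, x$fps, x$rail_span_mm, x$v_slow_mm_s,
              x$v_fast_mm_s, length(x$strikes), x$noise_sigma_px))
  invisible(x)
}

# arena layout in the y-up mm frame
.arena <- function(s) {
  w_mm <- s$frame_size[1] * s$mm_per_px
  h_mm <- s$frame_size[2] * s$mm_per_px
  list(rail_x0 = (w_mm - s$rail_span_mm) / 2,
       rail_y = 0.65 * h_mm,
       agent_y = 0.65 * h_mm - s$standoff_mm)
}

#' Simulate the prey rig
#'
#' Triangle-wave trajectory on the rail: constant slow leftward motion
#' to the left end, instantaneous reversal, constant fast rightward
#' motion to the right end, repeating for the whole session. The phase
#' command log (slow/fast per frame) and the exact reversal times are
#' part of the output.
#'
#' @param s A [sim_scenario()].
#' @return List with `time_s`, `x_mm` (absolute position), `v_mm_s`
#'   (signed), `phase` (factor, slow/fast), `reversal_times_s`.
#' @export
simulate_prey <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  n <- round(s$duration_s * s$fps)
  t <- (0:(n - 1)) / s$fps
  t_slow <- s$rail_span_mm / s$v_slow_mm_s
  t_fast <- s$rail_span_mm / s$v_fast_mm_s
  cyc <- t_slow + t_fast
  tau <- t %% cyc
  slow <- tau < t_slow
  x_rel <- ifelse(slow, s$rail_span_mm - s$v_slow_mm_s * tau,
                  s$v_fast_mm_s * (tau - t_slow))
  v <- ifelse(slow, -s$v_slow_mm_s, s$v_fast_mm_s)
  ncyc <- ceiling(s$duration_s / cyc)
  revs <- sort(c((0:ncyc) * cyc, (0:ncyc) * cyc + t_slow))
  revs <- revs[revs > 0 & revs < s$duration_s]
  list(time_s = t, x_mm = .arena(s)$rail_x0 + x_rel, v_mm_s = v,
       phase = factor(ifelse(slow, "slow", "fast"),
                      levels = c("stationary", "slow", "fast")),
       reversal_times_s = revs)
}

.wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a <= -180] <- 180
  a
}

#' Simulate the pursuing cuttlefish agent
#'
#' During attention windows the agent's horizontal velocity tracks the
#' prey velocity delayed by the sensorimotor latency and scaled by the
#' phase-appropriate pursuit gain, and its heading turns toward the
#' prey at up to the maximum turn rate, so the visual attack angle
#' decays. Outside attention the agent is stationary with its heading
#' held 90 degrees off the prey bearing. Scripted strikes freeze the
#' agent's translation and extend the tentacle tips ballistically
#' toward the aim point (the delayed observed prey position,
#' extrapolated by the delay times the prey velocity when
#' `predictive`), reaching it at the end of the extension phase --
#' capped at the commanded peak extension -- and retracting over the
#' same duration; any terminal correction rotates the club bearing
#' over the final 30 percent of the extension. A strike succeeds when
#' the tip ends within the success radius of the true prey position,
#' so a predictive strike on constant-velocity prey misses only by the
#' prey's travel during the strike itself.
#'
#' @param s A [sim_scenario()].
#' @param prey Output of [simulate_prey()].
#' @return List with per-frame `x_mm`, `y_mm`, `heading_deg`,
#'   `attention`, tip coordinates `tip_left/right` (n x 2 matrices, mm)
#'   and a `strike_log` data frame.
#' @export
simulate_cuttlefish <- function(s, prey) {
  stopifnot(inherits(s, "sim_scenario"))
  n <- length(prey$time_s)
  ar <- .arena(s)
  d <- round(s$sensorimotor_delay_ms / 1000 * s$fps)

  att <- rep(TRUE, n)
  if (!identical(s$attention_schedule, "auto")) {
    att <- rep(FALSE, n)
    for (w in s$attention_schedule)
      att[prey$time_s >= w[1] & prey$time_s < w[2]] <- TRUE
  }

  gain <- ifelse(prey$phase == "fast", s$pursuit_gain_fast,
                 s$pursuit_gain_slow)
  v_del <- c(rep(0, d), prey$v_mm_s[seq_len(n - d)])
  g_del <- c(rep(0, d), gain[seq_len(n - d)])
  v_agent <- att * g_del * v_del
  # the agent holds still while a strike is in flight
  strike_iv <- lapply(s$strikes, function(st) {
    i0 <- round(st$time_s * s$fps) + 1L
    durf <- max(2L, round(st$duration_ms / 1000 * s$fps))
    c(i0, min(n, i0 + 2L * durf))
  })
  for (iv in strike_iv)
    if (iv[1] >= 1 && iv[1] <= n) v_agent[iv[1]:iv[2]] <- 0
  x <- ar$rail_x0 + s$rail_span_mm / 2 +
    c(0, cumsum(v_agent[-n]) / s$fps)
  y <- rep(ar$agent_y, n)

  # heading: turn toward the target bearing at most turn_rate_max
  bearing <- atan2(ar$rail_y - y, prey$x_mm - x) * 180 / pi
  desired <- ifelse(att, bearing, bearing + 90)
  hd <- numeric(n)
  hd[1] <- desired[1] + if (att[1]) 20 else 0  # start slightly off-target
  step <- s$turn_rate_max_deg_s / s$fps
  for (i in 2:n) {
    diffang <- .wrap180(desired[i] - hd[i - 1])
    hd[i] <- hd[i - 1] + max(-step, min(step, diffang))
  }
  hd <- .wrap180(hd)

  ml <- s$mantle_len_mm
  u <- cbind(cos(hd * pi / 180), sin(hd * pi / 180))
  perp <- cbind(-u[, 2], u[, 1])
  rest_ext <- 0.12 * ml
  ext <- rep(rest_ext, n)
  rot <- rep(0, n)
  aim_u <- u  # per-frame tip direction (unit), defaults to the heading
  log_rows <- list()
  for (st in s$strikes) {
    i0 <- round(st$time_s * s$fps) + 1L
    if (i0 < 1 || i0 > n) next
    if (!att[i0])
      stop(sprintf("strike commanded at %.2f s falls outside an attention window",
                   st$time_s), call. = FALSE)
    durf <- max(2L, round(st$duration_ms / 1000 * s$fps))
    i_peak <- min(n, i0 + durf)
    i_end <- min(n, i0 + 2L * durf)
    iobs <- max(1L, i0 - d)
    aim_x <- prey$x_mm[iobs]
    if (isTRUE(st$predictive))
      aim_x <- aim_x + d / s$fps * prey$v_mm_s[iobs]
    dir0 <- c(aim_x - x[i0], ar$rail_y - y[i0])
    dist0 <- sqrt(sum(dir0^2))
    dir0 <- dir0 / dist0
    # the tip reaches the aim point (capped at the commanded reach)
    peak <- min(dist0, st$peak_extension_ml * ml)
    for (i in i0:i_end) {
      frac <- if (i <= i_peak) (i - i0) / durf else
        1 - (i - i_peak) / durf
      ext[i] <- rest_ext + frac * (peak - rest_ext)
      cf <- (i - i0) / durf  # correction ramps over the last 30%
      rot[i] <- if (cf <= 0.7) 0 else
        min(1, (cf - 0.7) / 0.3) * st$terminal_correction_deg
      a <- rot[i] * pi / 180
      aim_u[i, ] <- c(cos(a) * dir0[1] - sin(a) * dir0[2],
                      sin(a) * dir0[1] + cos(a) * dir0[2])
    }
    tip_peak <- c(x[i_peak], y[i_peak]) + aim_u[i_peak, ] * ext[i_peak]
    miss <- sqrt((tip_peak[1] - prey$x_mm[i_peak])^2 +
                   (tip_peak[2] - ar$rail_y)^2)
    log_rows[[length(log_rows) + 1]] <- data.frame(
      onset_s = (i0 - 1) / s$fps, peak_s = (i_peak - 1) / s$fps,
      end_s = (i_end - 1) / s$fps,
      aim_x_mm = aim_x,
      aim_bearing_deg = atan2(dir0[2], dir0[1]) * 180 / pi,
      predictive = isTRUE(st$predictive),
      terminal_correction_deg = st$terminal_correction_deg,
      commanded_peak_ml = st$peak_extension_ml,
      peak_extension_ml = peak / ml,
      miss_mm = miss, success = miss <= s$success_radius_mm)
  }
  strike_log <- if (length(log_rows) > 0) do.call(rbind, log_rows) else
    data.frame(onset_s = numeric(0), peak_s = numeric(0),
               end_s = numeric(0), aim_x_mm = numeric(0),
               aim_bearing_deg = numeric(0), predictive = logical(0),
               terminal_correction_deg = numeric(0),
               commanded_peak_ml = numeric(0),
               peak_extension_ml = numeric(0), miss_mm = numeric(0),
               success = logical(0))

  tip_c <- cbind(x, y) + aim_u * ext
  lat <- 0.05 * ml
  list(x_mm = x, y_mm = y, heading_deg = hd, attention = att,
       tip_left = tip_c + perp * lat, tip_right = tip_c - perp * lat,
       strike_log = strike_log)
}

#' Run a full simulated trial
#'
#' Simulates the prey rig and the pursuing agent and assembles the
#' frame-aligned ground truth.
#'
#' @param s A [sim_scenario()].
#' @return An object of class `ground_truth`: list with `frames` (data
#'   frame of true per-frame state), `strike_log`, `reversal_times_s`
#'   and the `scenario`.
#' @export
simulate_trial_truth <- function(s) {
  prey <- simulate_prey(s)
  ag <- simulate_cuttlefish(s, prey)
  frames <- data.frame(
    frame = seq_along(prey$time_s) - 1L,
    time_s = prey$time_s,
    prey_x_mm = prey$x_mm, prey_v_mm_s = prey$v_mm_s,
    phase = as.character(prey$phase),
    attention = ag$attention,
    agent_x_mm = ag$x_mm, agent_y_mm = ag$y_mm,
    heading_deg = ag$heading_deg,
    tip_left_x_mm = ag$tip_left[, 1], tip_left_y_mm = ag$tip_left[, 2],
    tip_right_x_mm = ag$tip_right[, 1],
    tip_right_y_mm = ag$tip_right[, 2])
  structure(list(frames = frames, strike_log = ag$strike_log,
                 reversal_times_s = prey$reversal_times_s, scenario = s),
            class = "ground_truth")
}

#' Render a ground-truth trial as a pose track
#'
#' Converts the true state to image coordinates for the nine canonical
#' body parts (eyes laterally offset from the head perpendicular to the
#' heading, mantle end one mantle length behind it, shrimp parts at
#' fixed offsets from the prey point on the rail), flips the y axis to
#' image convention, adds Gaussian coordinate noise, and draws
#' per-frame-and-part occlusions whose likelihood falls in \[0, 0.5\]
#' (visible parts get \[0.95, 1\]). Deterministic given the scenario
#' seed.
#'
#' @param s A [sim_scenario()].
#' @param truth A [simulate_trial_truth()] result.
#' @return A [pose_track()].
#' @export
render_poses <- function(s, truth) {
  stopifnot(inherits(s, "sim_scenario"), inherits(truth, "ground_truth"))
  fr <- truth$frames
  n <- nrow(fr)
  ar <- .arena(s)
  ml <- s$mantle_len_mm
  hd <- fr$heading_deg * pi / 180
  u <- cbind(cos(hd), sin(hd))
  perp <- cbind(-u[, 2], u[, 1])
  head <- cbind(fr$agent_x_mm, fr$agent_y_mm)
  pts <- list(
    left_eye = head + perp * (0.15 * ml),
    right_eye = head - perp * (0.15 * ml),
    left_club_tip = cbind(fr$tip_left_x_mm, fr$tip_left_y_mm),
    right_club_tip = cbind(fr$tip_right_x_mm, fr$tip_right_y_mm),
    mantle_end = head - u * ml,
    shrimp_left_eye = cbind(fr$prey_x_mm, ar$rail_y + 1.5),
    shrimp_right_eye = cbind(fr$prey_x_mm, ar$rail_y - 1.5),
    hook = cbind(fr$prey_x_mm + 4, ar$rail_y + 2),
    tail = cbind(fr$prey_x_mm + 18, ar$rail_y))
  parts <- body_parts()
  x <- y <- lik <- matrix(NA_real_, n, length(parts),
                          dimnames = list(NULL, parts))
  set.seed(s$seed)
  for (p in parts) {
    x[, p] <- pts[[p]][, 1] / s$mm_per_px
    y[, p] <- s$frame_size[2] - pts[[p]][, 2] / s$mm_per_px
    if (s$noise_sigma_px > 0) {
      x[, p] <- x[, p] + stats::rnorm(n, 0, s$noise_sigma_px)
      y[, p] <- y[, p] + stats::rnorm(n, 0, s$noise_sigma_px)
    }
    occ <- stats::runif(n) < s$occlusion_prob
    lik[, p] <- ifelse(occ, stats::runif(n, 0, 0.5),
                       stats::runif(n, 0.95, 1))
  }
  md <- trial_metadata(animal_id = "sim",
                       trial_id = sprintf("seed%d", s$seed),
                       mm_per_px = s$mm_per_px, fps = s$fps,
                       frame_size = s$frame_size,
                       session_length_s = s$duration_s)
  pose_track(x, y, lik, md)
}

#' Simulate and render a full trial
#'
#' @param s A [sim_scenario()].
#' @return List of class `sim_trial` with `scenario`, `truth`
#'   (ground truth) and `track` (rendered `pose_track`).
#' @export
simulate_trial <- function(s) {
  truth <- simulate_trial_truth(s)
  structure(list(scenario = s, truth = truth,
                 track = render_poses(s, truth)),
            class = "sim_trial")
}

#' Write a simulated dataset to disk
#'
#' Writes three cross-referencing files: the rendered pose table in the
#' DeepLabCut CSV dialect, the frame-aligned ground-truth CSV (with the
#' strike log appended as a separate block is avoided; strike outcomes
#' live in the scenario snapshot), and the scenario as a YAML snapshot
#' including the strike log.
#'
#' @param s A [sim_scenario()].
#' @param outdir Output directory (created if absent).
#' @return Named character vector with paths `pose`, `truth`,
#'   `scenario`.
#' @export
make_dataset <- function(s, outdir) {
  stopifnot(inherits(s, "sim_scenario"))
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  id <- sprintf("sim_seed%d", s$seed)
  trial <- simulate_trial(s)
  pose_path <- file.path(outdir, paste0("pose_", id, ".csv"))
  truth_path <- file.path(outdir, paste0("truth_", id, ".csv"))
  scen_path <- file.path(outdir, paste0("scenario_", id, ".yaml"))
  write_dlc_csv(trial$track, pose_path)
  fr <- trial$truth$frames
  fr$scenario_id <- id
  num <- vapply(fr, is.numeric, logical(1))
  fr[num] <- lapply(fr[num], function(v) round(v, 6))
  utils::write.csv(fr, truth_path, row.names = FALSE)
  snap <- unclass(s)
  snap$scenario_id <- id
  snap$strike_log <- if (nrow(trial$truth$strike_log) > 0)
    lapply(seq_len(nrow(trial$truth$strike_log)),
           function(i) as.list(trial$truth$strike_log[i, ])) else list()
  snap$reversal_times_s <- round(trial$truth$reversal_times_s, 6)
  yaml::write_yaml(snap, scen_path)
  c(pose = pose_path, truth = truth_path, scenario = scen_path)
}
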