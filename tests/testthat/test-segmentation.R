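test_that("prey phase labels follow the speed thresholds", {
  ph0 <- classify_prey_phase(rep(0, 300), fps = 90)
  expect_true(all(ph0$label == "stationary"))
  expect_length(ph0$reversal_times_s, 0)

  ph_f <- classify_prey_phase(rep(75, 300), fps = 90)
  expect_true(all(ph_f$label == "fast"))

  expect_error(classify_prey_phase(rep(0, 10), 90, v_still = 50,
                                   v_split = 5), "v_still")
})

test_that("estimated prey speeds reproduce the generator's phase log", {
  s <- sim_scenario(seed = 13, duration_s = 40)
  trial <- simulate_trial(s)
  cl <- clean_pose_track(trial$track)
  v <- horizontal_speed(cl, "prey")
  ph <- classify_prey_phase(v, fps = s$fps)
  agree <- mean(as.character(ph$label) == trial$truth$frames$phase)
  expect_gte(agree, 0.98)
  # estimated reversals land near the true ones
  expect_equal(length(ph$reversal_times_s),
               length(trial$truth$reversal_times_s))
  expect_lt(max(abs(ph$reversal_times_s - trial$truth$reversal_times_s)),
            0.1)
})

# builds a kinematic series directly from an alpha trace, bypassing
# geometry, to test episode logic in isolation
kin_from_alpha <- function(alpha, fps = 90) {
  n <- length(alpha)
  kin <- data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) / fps,
                    alpha_deg = alpha,
                    ext_left_ml = 0.12, ext_right_ml = 0.12,
                    beta_left_deg = 8, beta_right_deg = -8,
                    cutt_speed_mm_s = 0, prey_speed_mm_s = 0)
  attr(kin, "metadata") <- test_metadata(fps = fps,
                                         session_s = n / fps + 1)
  attr(kin, "mantle_scale_px") <- 160
  class(kin) <- c("kinematic_series", "data.frame")
  kin
}

test_that("attention episodes are maximal aligned intervals with merging and minimum duration", {
  fps <- 90
  # perfectly aligned for the whole session: one full-length episode
  kin <- kin_from_alpha(rep(0, 120 * fps))
  ep <- detect_attention_episodes(kin)
  expect_identical(nrow(ep), 1L)
  expect_equal(ep$duration_s, 120)

  # never aligned: nothing
  expect_identical(nrow(detect_attention_episodes(
    kin_from_alpha(rep(90, 1000)))), 0L)

  # a 0.3 s interruption is bridged, a 1 s one is not
  a <- rep(0, 10 * fps)
  a[(4 * fps):(4 * fps + 0.3 * fps)] <- 90
  ep1 <- detect_attention_episodes(kin_from_alpha(a))
  expect_identical(nrow(ep1), 1L)
  a2 <- rep(0, 10 * fps)
  a2[(4 * fps):(5 * fps)] <- 90
  ep2 <- detect_attention_episodes(kin_from_alpha(a2))
  expect_identical(nrow(ep2), 2L)

  # sub-t_min snippets are dropped
  a3 <- rep(90, 10 * fps)
  a3[1:45] <- 0  # half a second
  expect_identical(nrow(detect_attention_episodes(kin_from_alpha(a3))), 0L)

  # episodes are disjoint, ordered, and never exceed the session
  set.seed(5)
  a4 <- ifelse(stats::runif(20 * fps) < 0.5, 0, 90)
  ep4 <- detect_attention_episodes(kin_from_alpha(a4), t_min = 0.1,
                                   gap_max = 0.05)
  if (nrow(ep4) > 1) {
    expect_true(all(diff(ep4$start_s) > 0))
    expect_true(all(ep4$start_s[-1] >= ep4$end_s[-nrow(ep4)]))
  }
  expect_lte(sum(ep4$duration_s), 20)
})

test_that("a scripted attention schedule is recovered at its boundaries", {
  sched <- list(c(5, 15), c(20, 25), c(30, 50))
  s <- sim_scenario(seed = 19, duration_s = 55,
                    attention_schedule = sched,
                    turn_rate_max_deg_s = 450)
  trial <- simulate_trial(s)
  fit <- analyze_pursuit(trial$track)
  ep <- fit$episodes
  expect_identical(nrow(ep), 3L)
  for (i in 1:3) {
    expect_lt(abs(ep$start_s[i] - sched[[i]][1]), 0.2)
    expect_lt(abs(ep$end_s[i] - sched[[i]][2]), 0.2)
  }
})

test_that("strike detection finds commanded strikes and nothing else", {
  # no extension anywhere: no events
  kin0 <- kin_from_alpha(rep(0, 900))
  expect_identical(nrow(detect_strikes(kin0)), 0L)

  s <- sim_scenario(seed = 29, duration_s = 20,
                    strikes = list(list(time_s = 7.5,
                                        peak_extension_ml = 1.8)))
  trial <- simulate_trial(s)
  kin <- compute_kinematics(clean_pose_track(trial$track))
  st <- detect_strikes(kin)
  expect_identical(nrow(st), 1L)
  expect_lte(abs(st$onset_s - 7.5), 0.05)
  expect_lt(abs(st$peak_extension_ml -
                  trial$truth$strike_log$peak_extension_ml), 0.1)
  expect_identical(st$side, "both")
  # the strike angle is alpha at onset: the agent had been attending
  expect_lt(abs(st$strike_angle_deg), 15)
})

test_that("paired velocity summaries split attention frames by prey phase", {
  # stationary cuttlefish: zero speeds in both phases
  fps <- 90
  n <- 20 * fps
  kin <- kin_from_alpha(rep(0, n))
  v <- rep(c(-25, 75), each = n / 2)
  kin$prey_speed_mm_s <- v
  ph <- classify_prey_phase(v, fps = fps)
  ep <- detect_attention_episodes(kin)
  out <- paired_velocity_summary(kin, ph, ep)
  expect_equal(out$mean_speed_slow, 0)
  expect_equal(out$mean_speed_fast, 0)
  expect_false(out$missing_phase)

  # slow-phase-only episodes: the fast member is flagged missing
  ph_slow <- classify_prey_phase(rep(-25, n), fps = fps)
  out2 <- paired_velocity_summary(kin, ph_slow, ep)
  expect_true(out2$missing_phase)
  expect_true(is.na(out2$mean_speed_fast))

  # generator gains: tracks slow prey, nearly freezes for fast prey
  s <- sim_scenario(seed = 37, duration_s = 40)
  trial <- simulate_trial(s)
  fit <- analyze_pursuit(trial$track)
  expect_lt(abs(fit$velocity_summary$mean_speed_slow -
                  0.9 * 25) / (0.9 * 25), 0.15)
  expect_lt(fit$velocity_summary$mean_speed_fast, 10)
})

test_that("strike timing reports the phase at onset and time since reversal", {
  fps <- 90
  v <- rep(c(-25, 75), each = 5 * fps)  # one reversal at 5 s
  ph <- classify_prey_phase(v, fps = fps)
  st <- data.frame(onset_s = c(5 + 1 / fps, 8), end_s = c(5.2, 8.2))
  tm <- strike_timing(st, ph)
  expect_lte(tm$time_since_reversal_s[1], 0.1)
  expect_identical(tm$phase_at_onset[2], "fast")
  expect_equal(tm$time_since_reversal_s[2], 3, tolerance = 0.05)
  # onset before any reversal: infinite sentinel
  st0 <- data.frame(onset_s = 2, end_s = 2.2)
  expect_identical(strike_timing(st0, ph)$time_since_reversal_s, Inf)
  # generator strikes commanded in the slow phase are labeled slow
  s <- sim_scenario(seed = 43, duration_s = 20,
                    strikes = list(list(time_s = 4), list(time_s = 17)))
  trial <- simulate_trial(s)
  fit <- analyze_pursuit(trial$track)
  expect_true(all(fit$strike_timing$phase_at_onset == "slow"))
})
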