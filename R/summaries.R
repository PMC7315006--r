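#' Summarise attention-episode durations
#'
#' Splits episode durations by whether the episode immediately preceded
#' a tentacular strike attempt and reports range and count per group,
#' as in the study's attention-time comparison.
#'
#' @param episodes A data frame with columns `duration_s` and
#'   `pre_strike` (the packaged reference table or pipeline output with
#'   an annotation column).
#' @return A `data.frame` with one row per group (`pre_strike`,
#'   `no_strike`): `n`, `min_s`, `max_s`, `median_s`; total episode
#'   count in attribute `n_total`.
#' @export
#' @examples
#' summarize_attention(load_table1())
summarize_attention <- function(episodes) {
  if (!all(c("duration_s", "pre_strike") %in% names(episodes)))
    stop("`episodes` needs columns duration_s and pre_strike",
         call. = FALSE)
  if (nrow(episodes) == 0)
    stop("at least one episode is required", call. = FALSE)
  grp <- ifelse(episodes$pre_strike, "pre_strike", "no_strike")
  out <- do.call(rbind, lapply(c("pre_strike", "no_strike"), function(g) {
    d <- episodes$duration_s[grp == g]
    if (length(d) == 0) return(NULL)
    data.frame(group = g, n = length(d), min_s = min(d), max_s = max(d),
               median_s = stats::median(d))
  }))
  attr(out, "n_total") <- nrow(episodes)
  out
}

#' Strike-geometry distribution tables
#'
#' Produces the four tidy tables describing a set of detected strikes:
#' normalised strike lengths (mantle lengths), body-axis angles
#' relative to the moving prey at onset, left/right eye-angle
#' excursions during the attack, and strike timing relative to the
#' prey's motion (phase at onset, time since the last reversal).
#'
#' The body-axis angle is reported relative to the prey's instantaneous
#' movement direction along the rail when a `kinematic_series` and
#' `prey_phase` are supplied; 90 degrees then means the strike was
#' launched perpendicular to the prey's path.
#'
#' @param strikes A `strike_events` data frame.
#' @param kin Optional `kinematic_series` for the same trial.
#' @param phase Optional [classify_prey_phase()] result; required for
#'   the timing table.
#' @return A list of data frames: `lengths`, `angles`, `delta_beta`,
#'   `timing` (the latter `NULL` without `phase`).
#' @export
summarize_strike_geometry <- function(strikes, kin = NULL, phase = NULL) {
  if (nrow(strikes) == 0)
    stop("at least one strike is required", call. = FALSE)
  lengths <- data.frame(strike = seq_len(nrow(strikes)),
                        length_ml = strikes$peak_extension_ml)
  angle <- strikes$strike_angle_deg
  if (!is.null(kin) && !is.null(phase)) {
    # heading vs prey travel direction along the rail (+x rightward)
    fps <- attr(kin, "metadata")$fps
    fr <- pmin(nrow(kin), pmax(1L, round(strikes$onset_s * fps) + 1L))
    dir <- sign(kin$prey_speed_mm_s[fr])
    dir[dir == 0] <- 1
    head_vec <- cbind(kin$heading_x[fr], kin$heading_y[fr])
    prey_vec <- cbind(dir, 0)
    angle <- signed_angle(prey_vec, head_vec)
  }
  angles <- data.frame(strike = seq_len(nrow(strikes)),
                       axis_vs_prey_deg = angle)
  delta_beta <- data.frame(
    strike = rep(seq_len(nrow(strikes)), 2),
    eye = rep(c("left", "right"), each = nrow(strikes)),
    delta_beta_deg = c(strikes$delta_beta_left_deg,
                       strikes$delta_beta_right_deg))
  timing <- NULL
  if (!is.null(phase)) {
    tm <- strike_timing(strikes, phase)
    timing <- cbind(strike = seq_len(nrow(strikes)), tm)
  }
  list(lengths = lengths, angles = angles, delta_beta = delta_beta,
       timing = timing)
}
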