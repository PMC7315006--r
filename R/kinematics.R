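# Geometry is done in a y-up mathematical frame; pose files use image
# convention (origin top-left, y down), so y is negated on the way in.
# Positive angles are counter-clockwise in the y-up frame.

.math_xy <- function(clean, part) {
  cbind(x = unname(clean$x[, part]), y = -unname(clean$y[, part]))
}

.unit <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop("degenerate geometry: zero-length vector", call. = FALSE)
  m / nrm
}

#' Signed angle between two vectors
#'
#' Counter-clockwise angle from `u` to `v` in a y-up frame, in degrees
#' in (-180, 180]. Antisymmetric up to the 180-degree branch:
#' `signed_angle(u, v) == -signed_angle(v, u)` except at 180.
#'
#' @param u,v Numeric vectors of length 2, or n x 2 matrices for a
#'   vectorised call.
#' @return Numeric vector of angles in degrees.
#' @export
#' @examples
#' signed_angle(c(1, 0), c(0, 1))  # +90
signed_angle <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 2)
  if (is.null(dim(v))) v <- matrix(v, ncol = 2)
  if (nrow(u) == 1 && nrow(v) > 1) u <- u[rep(1, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1 && nrow(u) > 1) v <- v[rep(1, nrow(u)), , drop = FALSE]
  if (any(rowSums(u^2) == 0, na.rm = TRUE) ||
      any(rowSums(v^2) == 0, na.rm = TRUE))
    stop("degenerate geometry: zero-length vector", call. = FALSE)
  cross <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  dot <- u[, 1] * v[, 1] + u[, 2] * v[, 2]
  ang <- unname(atan2(cross, dot) * 180 / pi)
  # atan2 returns (-pi, pi]; force the -180 representative onto +180
  ang[!is.na(ang) & ang <= -180] <- 180
  ang
}

#' Cuttlefish body axis per frame
#'
#' The head reference point is the midpoint of the two eyes; the heading
#' is the unit vector along the anterior-posterior axis, pointing from
#' the dorsal mantle end toward the head; the mantle length is the
#' distance between the two, in pixels.
#'
#' @param clean A `clean_track`.
#' @return A list with `head_px` (n x 2 matrix, image convention),
#'   `heading` (n x 2 unit vectors, y-up frame) and `mantle_len_px`
#'   (numeric vector).
#' @export
body_axis <- function(clean) {
  le <- .math_xy(clean, "left_eye")
  re <- .math_xy(clean, "right_eye")
  me <- .math_xy(clean, "mantle_end")
  head <- (le + re) / 2
  ax <- head - me
  len <- sqrt(rowSums(ax^2))
  if (any(len == 0))
    stop("degenerate geometry: mantle end coincides with the head",
         call. = FALSE)
  list(head_px = cbind(x = head[, 1], y = -head[, 2]),
       head = head,
       heading = ax / len,
       mantle_len_px = len)
}

.prey_ref_point <- function(clean, prey_ref = c("eyes_mid", "hook",
                                                "centroid")) {
  prey_ref <- match.arg(prey_ref)
  switch(prey_ref,
         eyes_mid = (.math_xy(clean, "shrimp_left_eye") +
                       .math_xy(clean, "shrimp_right_eye")) / 2,
         hook = .math_xy(clean, "hook"),
         centroid = (.math_xy(clean, "shrimp_left_eye") +
                       .math_xy(clean, "shrimp_right_eye") +
                       .math_xy(clean, "hook") +
                       .math_xy(clean, "tail")) / 4)
}

#' Visual attack angle per frame
#'
#' The angle between the cuttlefish anterior-posterior axis and the
#' direction from its head to the prey reference point (by default the
#' midpoint of the shrimp's eyes). Zero means the prey lies on the
#' heading ray; positive is counter-clockwise.
#'
#' @param clean A `clean_track`.
#' @param prey_ref Prey reference point: `"eyes_mid"` (default),
#'   `"hook"` or `"centroid"`.
#' @return Numeric vector of angles (degrees).
#' @export
visual_attack_angle <- function(clean, prey_ref = "eyes_mid") {
  ax <- body_axis(clean)
  to_prey <- .prey_ref_point(clean, prey_ref) - ax$head
  if (any(rowSums(to_prey^2) == 0))
    stop("degenerate geometry: prey reference coincides with the head",
         call. = FALSE)
  signed_angle(ax$heading, to_prey)
}

#' Eye angle per frame
#'
#' Angle between the ocular axis and the anterior-posterior axis, one
#' value per eye. With one labelled point per eye the ocular axis is
#' realised as the vector from the mantle end to the eye point; a
#' vergence change then shows up as a change in this angle.
#'
#' @param clean A `clean_track`.
#' @param side `"left"` or `"right"`.
#' @return Numeric vector of angles (degrees).
#' @export
eye_angle <- function(clean, side = c("left", "right")) {
  side <- match.arg(side)
  ax <- body_axis(clean)
  eye <- .math_xy(clean, paste0(side, "_eye"))
  me <- .math_xy(clean, "mantle_end")
  v <- eye - me
  if (any(rowSums(v^2) == 0))
    stop("degenerate geometry: eye coincides with the mantle end",
         call. = FALSE)
  signed_angle(ax$heading, v)
}

#' Tentacle extension per frame, in mantle lengths
#'
#' Distance from the head to a tentacle club tip divided by the trial
#' mantle-length scale (median over frames of the per-frame mantle
#' length, robust to soft-body shape change).
#'
#' @param clean A `clean_track`.
#' @param side `"left"` or `"right"`.
#' @return Numeric vector (mantle lengths).
#' @export
tentacle_extension <- function(clean, side = c("left", "right")) {
  side <- match.arg(side)
  ax <- body_axis(clean)
  tip <- .math_xy(clean, paste0(side, "_club_tip"))
  scale <- stats::median(ax$mantle_len_px)
  sqrt(rowSums((tip - ax$head)^2)) / scale
}

#' Tentacular strike angle per frame
#'
#' Angle between the tentacle direction (head to club tip) and the
#' anterior-posterior axis. Reported only while the tentacle is
#' extended beyond `extension_threshold` mantle lengths; a retracted
#' club sits between the arms and its direction is noise, so those
#' frames are `NA`.
#'
#' @param clean A `clean_track`.
#' @param side `"left"` or `"right"`.
#' @param extension_threshold Extension below which the angle is
#'   undefined, in mantle lengths (default 0.35).
#' @return Numeric vector of angles (degrees), `NA` where retracted.
#' @export
tentacle_angle <- function(clean, side = c("left", "right"),
                           extension_threshold = 0.35) {
  side <- match.arg(side)
  ax <- body_axis(clean)
  tip <- .math_xy(clean, paste0(side, "_club_tip"))
  v <- tip - ax$head
  ext <- tentacle_extension(clean, side)
  ok <- ext > extension_threshold & rowSums(v^2) > 0
  out <- rep(NA_real_, nrow(tip))
  if (any(ok))
    out[ok] <- signed_angle(ax$heading[ok, , drop = FALSE],
                            v[ok, , drop = FALSE])
  out
}

#' Tentacle club angle per frame
#'
#' Direction of club travel relative to the tentacle axis: the club's
#' movement direction is estimated from the tip displacement over a
#' centred window, and the angle is measured from the head-to-tip line
#' to that direction. Changes late in a strike indicate closed-loop
#' trajectory correction. Undefined (`NA`) while the tentacle is
#' retracted or when the tip moved less than `d_min` pixels over the
#' window.
#'
#' @param clean A `clean_track`.
#' @param side `"left"` or `"right"`.
#' @param window Centred displacement window in frames (odd, >= 3).
#' @param d_min Minimum tip displacement over the window, px.
#' @param extension_threshold Extension gate in mantle lengths.
#' @return Numeric vector of angles (degrees), `NA` where undefined.
#' @export
club_angle <- function(clean, side = c("left", "right"), window = 5,
                       d_min = 2, extension_threshold = 0.35) {
  side <- match.arg(side)
  if (!is.numeric(window) || length(window) != 1 || window < 3 ||
      window %% 2 == 0)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  ax <- body_axis(clean)
  tip <- .math_xy(clean, paste0(side, "_club_tip"))
  n <- nrow(tip)
  half <- (window - 1) / 2
  out <- rep(NA_real_, n)
  if (n < window) return(out)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  disp <- tip[hi, , drop = FALSE] - tip[lo, , drop = FALSE]
  dmag <- sqrt(rowSums(disp^2))
  axis_vec <- tip - ax$head
  ext <- tentacle_extension(clean, side)
  ok <- dmag >= d_min & ext > extension_threshold & rowSums(axis_vec^2) > 0
  if (any(ok))
    out[ok] <- signed_angle(axis_vec[ok, , drop = FALSE],
                            disp[ok, , drop = FALSE])
  out
}

#' Horizontal speed of a tracked point
#'
#' Signed speed along the rail (image x axis, rightward positive) of a
#' body part or reference point, estimated by a central difference of
#' the smoothed x coordinate and converted to mm/s with the trial
#' calibration. Endpoints use one-sided differences.
#'
#' @param clean A `clean_track`.
#' @param part `"head"` (cuttlefish eye midpoint), `"prey"` (shrimp eye
#'   midpoint), or any canonical body-part label.
#' @param window Smoothing window passed to [smooth_series()]; default 5
#'   frames (about 56 ms at 90 fps).
#' @return Numeric vector, mm/s per frame.
#' @export
horizontal_speed <- function(clean, part = "head", window = 5) {
  md <- clean$metadata
  xs <- if (identical(part, "head")) {
    (clean$x[, "left_eye"] + clean$x[, "right_eye"]) / 2
  } else if (identical(part, "prey")) {
    (clean$x[, "shrimp_left_eye"] + clean$x[, "shrimp_right_eye"]) / 2
  } else {
    if (!part %in% colnames(clean$x))
      stop("unknown body part: ", part, call. = FALSE)
    clean$x[, part]
  }
  n <- length(xs)
  if (n < 3)
    stop("at least 3 frames are needed to estimate speed", call. = FALSE)
  sm <- smooth_series(xs, min(window, if (n %% 2 == 0) n - 1 else n))
  v <- c(sm[2] - sm[1],
         (sm[3:n] - sm[1:(n - 2)]) / 2,
         sm[n] - sm[n - 1])
  v * md$fps * md$mm_per_px
}

#' Head-to-prey distance in mantle lengths
#'
#' @param clean A `clean_track`.
#' @param prey_ref Prey reference point (see [visual_attack_angle()]).
#' @return Numeric vector of distances (mantle lengths).
#' @export
target_distance <- function(clean, prey_ref = "eyes_mid") {
  ax <- body_axis(clean)
  scale <- stats::median(ax$mantle_len_px)
  if (!is.finite(scale) || scale <= 0)
    stop("degenerate mantle-length scale", call. = FALSE)
  prey <- .prey_ref_point(clean, prey_ref)
  sqrt(rowSums((prey - ax$head)^2)) / scale
}

#' Per-frame kinematic series for a cleaned track
#'
#' Computes every kinematic variable used downstream: visual attack
#' angle, eye angles, tentacular strike angles and club angles per side,
#' tentacle extensions, horizontal speeds of predator and prey,
#' positions in mm, and target distance in mantle lengths.
#'
#' @param clean A `clean_track`.
#' @param prey_ref Prey reference point (default `"eyes_mid"`).
#' @param smoothing_window Window for speed estimation (frames).
#' @param extension_threshold Tentacle extension gate (mantle lengths).
#' @param club_window,club_d_min Parameters of [club_angle()].
#' @return A `data.frame` of class `kinematic_series`, one row per
#'   frame, with the trial mantle-length scale (px) in attribute
#'   `mantle_scale_px` and the metadata in attribute `metadata`.
#' @export
compute_kinematics <- function(clean, prey_ref = "eyes_mid",
                               smoothing_window = 5,
                               extension_threshold = 0.35,
                               club_window = 5, club_d_min = 2) {
  stopifnot(inherits(clean, "clean_track"))
  md <- clean$metadata
  n <- n_frames(clean)
  ax <- body_axis(clean)
  prey <- .prey_ref_point(clean, prey_ref)
  scale <- stats::median(ax$mantle_len_px)
  kin <- data.frame(
    frame = 0:(n - 1),
    time_s = (0:(n - 1)) / md$fps,
    head_x_px = ax$head_px[, 1],
    head_y_px = ax$head_px[, 2],
    heading_x = ax$heading[, 1],
    heading_y = ax$heading[, 2],
    mantle_len_px = ax$mantle_len_px,
    alpha_deg = visual_attack_angle(clean, prey_ref),
    beta_left_deg = eye_angle(clean, "left"),
    beta_right_deg = eye_angle(clean, "right"),
    delta_left_deg = tentacle_angle(clean, "left", extension_threshold),
    delta_right_deg = tentacle_angle(clean, "right", extension_threshold),
    theta_left_deg = club_angle(clean, "left", club_window, club_d_min,
                                extension_threshold),
    theta_right_deg = club_angle(clean, "right", club_window, club_d_min,
                                 extension_threshold),
    ext_left_ml = tentacle_extension(clean, "left"),
    ext_right_ml = tentacle_extension(clean, "right"),
    cutt_speed_mm_s = horizontal_speed(clean, "head", smoothing_window),
    prey_speed_mm_s = horizontal_speed(clean, "prey", smoothing_window),
    cutt_x_mm = (clean$x[, "left_eye"] + clean$x[, "right_eye"]) / 2 *
      md$mm_per_px,
    prey_x_mm = (clean$x[, "shrimp_left_eye"] +
                   clean$x[, "shrimp_right_eye"]) / 2 * md$mm_per_px,
    target_dist_ml = target_distance(clean, prey_ref)
  )
  attr(kin, "mantle_scale_px") <- scale
  attr(kin, "metadata") <- md
  class(kin) <- c("kinematic_series", "data.frame")
  kin
}

#' Write a kinematic series as tidy CSV
#'
#' One row per frame, one column per variable; undefined values are
#' written empty.
#'
#' @param kin A `kinematic_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(kin, path) {
  utils::write.csv(as.data.frame(kin), path, row.names = FALSE, na = "")
  invisible(path)
}
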