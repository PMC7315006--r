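#' Gate coordinates by detection likelihood
#'
#' Marks as missing every coordinate whose detection confidence falls
#' below `threshold`, emulating the exclusion of occluded body parts
#' from a pose estimator's probabilistic score map. Coordinates at or
#' above the threshold are untouched.
#'
#' @param track A [pose_track()].
#' @param threshold Likelihood threshold in \[0, 1\]; default 0.9.
#' @return A `pose_track` in which gated coordinates are `NA`.
#' @export
gate_by_likelihood <- function(track, threshold = 0.9) {
  stopifnot(inherits(track, "pose_track"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("`threshold` must be a single number in [0, 1]", call. = FALSE)
  drop <- !is.na(track$likelihood) & track$likelihood < threshold
  drop[is.na(track$likelihood)] <- TRUE
  track$x[drop] <- NA_real_
  track$y[drop] <- NA_real_
  track
}

#' Flag implausible frame-to-frame jumps
#'
#' Optional outlier gate for mislabeled but high-confidence points: any
#' coordinate whose displacement from the previous retained frame
#' exceeds `jump_px` pixels per frame is marked missing, then filled by
#' interpolation downstream. Off by default in the pipeline.
#'
#' @param track A `pose_track` (possibly with gaps).
#' @param jump_px Maximum plausible displacement in px/frame.
#' @return A `pose_track` with jump outliers set to `NA`.
#' @export
gate_by_jump <- function(track, jump_px) {
  stopifnot(inherits(track, "pose_track"))
  if (!is.numeric(jump_px) || length(jump_px) != 1 || jump_px <= 0)
    stop("`jump_px` must be a single positive number", call. = FALSE)
  n <- n_frames(track)
  if (n < 2) return(track)
  for (p in colnames(track$x)) {
    xs <- track$x[, p]; ys <- track$y[, p]
    last <- NA_integer_
    for (i in seq_len(n)) {
      if (is.na(xs[i]) || is.na(ys[i])) next
      if (!is.na(last)) {
        d <- sqrt((xs[i] - xs[last])^2 + (ys[i] - ys[last])^2) / (i - last)
        if (d > jump_px) {
          xs[i] <- NA_real_; ys[i] <- NA_real_
          next
        }
      }
      last <- i
    }
    track$x[, p] <- xs; track$y[, p] <- ys
  }
  track
}

#' Fill coordinate gaps by linear interpolation
#'
#' Interior gaps are filled by linear interpolation in frame index,
#' independently for x and y; gaps at the start or end of the recording
#' are filled by constant extension of the nearest observed value, so no
#' motion is invented at the boundaries. The returned track records
#' which coordinates were filled.
#'
#' @param track A `pose_track`, typically after [gate_by_likelihood()].
#' @return An object of class `clean_track` with fields `metadata`, `x`,
#'   `y` (gap-free matrices) and `interpolated` (logical matrix, `TRUE`
#'   where a coordinate was filled).
#' @export
interpolate_gaps <- function(track) {
  stopifnot(inherits(track, c("pose_track", "clean_track")))
  n <- n_frames(track)
  parts <- colnames(track$x)
  x <- track$x; y <- track$y
  mask <- is.na(x) | is.na(y)
  for (p in parts) {
    obs <- which(!mask[, p])
    if (length(obs) == 0)
      stop(sprintf("body part '%s' is missing in every frame", p),
           call. = FALSE)
    if (length(obs) == n) next
    idx <- seq_len(n)
    if (length(obs) == 1) {
      x[, p] <- x[obs, p]; y[, p] <- y[obs, p]
    } else {
      # rule = 2: constant extension beyond the first/last observation
      x[, p] <- stats::approx(obs, x[obs, p], xout = idx, rule = 2)$y
      y[, p] <- stats::approx(obs, y[obs, p], xout = idx, rule = 2)$y
    }
  }
  structure(list(metadata = track$metadata, x = x, y = y,
                 interpolated = mask),
            class = "clean_track")
}

#' @export
print.clean_track <- function(x, ...) {
  cat(sprintf("<clean_track> %d frames x %d body parts (%.1f%% interpolated)\n",
              nrow(x$x), ncol(x$x), 100 * mean(x$interpolated)))
  invisible(x)
}

#' Gate and interpolate a raw pose track
#'
#' Convenience wrapper running [gate_by_likelihood()], optionally
#' [gate_by_jump()], then [interpolate_gaps()].
#'
#' @param track A raw [pose_track()].
#' @param likelihood_threshold Likelihood gate; default 0.9.
#' @param jump_px Optional jump gate in px/frame (`NULL` disables it).
#' @return A `clean_track`.
#' @export
clean_pose_track <- function(track, likelihood_threshold = 0.9,
                             jump_px = NULL) {
  g <- gate_by_likelihood(track, likelihood_threshold)
  if (!is.null(jump_px)) g <- gate_by_jump(g, jump_px)
  interpolate_gaps(g)
}

#' Centred moving-average smoothing
#'
#' Smooths a per-frame scalar with a centred moving average whose window
#' shrinks symmetrically at the series edges, so affine (linear-in-time)
#' signals pass through unchanged everywhere. `window = 1` is the
#' identity. Used inside derivative estimation only; stored coordinates
#' are never smoothed.
#'
#' @param series Numeric vector.
#' @param window Odd positive integer window length, at most
#'   `length(series)`.
#' @return Numeric vector of the same length.
#' @export
smooth_series <- function(series, window) {
  n <- length(series)
  if (!is.numeric(window) || length(window) != 1 || is.na(window) ||
      window < 1 || window %% 2 == 0)
    stop("`window` must be a positive odd integer", call. = FALSE)
  if (window > n)
    stop("`window` must not exceed the series length", call. = FALSE)
  if (window == 1 || n == 0) return(series)
  half <- (window - 1) / 2
  out <- as.numeric(stats::filter(series, rep(1 / window, window),
                                  sides = 2))
  # shrink the window symmetrically where the full window does not fit
  for (i in seq_len(half)) {
    k <- i - 1
    out[i] <- mean(series[(i - k):(i + k)])
    j <- n - i + 1
    out[j] <- mean(series[(j - k):(j + k)])
  }
  out
}
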