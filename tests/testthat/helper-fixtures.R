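# Shared fixtures and independent oracles for the test suite.

test_metadata <- function(fps = 90, mm_per_px = 0.5, session_s = 120) {
  trial_metadata("T", "1", mm_per_px = mm_per_px, fps = fps,
                 session_length_s = session_s)
}

# a track with every part laid out explicitly, image coordinates
# `layout` is a named list of n x 2 matrices (or length-2 vectors
# recycled over frames), keys = body_parts()
make_track <- function(layout, n = NULL, metadata = test_metadata(),
                       likelihood = 1) {
  parts <- body_parts()
  if (is.null(n))
    n <- max(vapply(layout, function(m)
      if (is.matrix(m)) nrow(m) else 1L, integer(1)))
  x <- y <- matrix(NA_real_, n, length(parts),
                   dimnames = list(NULL, parts))
  for (p in parts) {
    m <- layout[[p]]
    if (is.null(m)) m <- c(0, 0)
    if (!is.matrix(m)) m <- matrix(m, n, 2, byrow = TRUE)
    x[, p] <- m[, 1]; y[, p] <- m[, 2]
  }
  lik <- matrix(likelihood, n, length(parts),
                dimnames = list(NULL, parts))
  pose_track(x, y, lik, metadata)
}

random_track <- function(n = 50, seed = 1, metadata = test_metadata()) {
  set.seed(seed)
  parts <- body_parts()
  x <- matrix(stats::runif(n * 9, 100, 1900), n, 9,
              dimnames = list(NULL, parts))
  y <- matrix(stats::runif(n * 9, 100, 1900), n, 9,
              dimnames = list(NULL, parts))
  lik <- matrix(stats::runif(n * 9), n, 9, dimnames = list(NULL, parts))
  pose_track(x, y, lik, metadata)
}

# rigid transform of a track in the image plane (rotation in the y-up
# sense by `deg` about `center`, then translation)
transform_track <- function(track, deg = 0, shift = c(0, 0),
                            center = c(1024, 1024)) {
  th <- deg * pi / 180
  for (p in colnames(track$x)) {
    xm <- track$x[, p] - center[1]
    ym <- -(track$y[, p] - center[2])  # to y-up
    xr <- cos(th) * xm - sin(th) * ym
    yr <- sin(th) * xm + cos(th) * ym
    track$x[, p] <- xr + center[1] + shift[1]
    track$y[, p] <- -(yr) + center[2] - shift[2]
  }
  track
}

# mirror a track about a vertical line (left-right flip), swapping
# left/right labels so the anatomy stays consistent
mirror_track <- function(track, axis_x = 1024) {
  swap <- c(left_eye = "right_eye", right_eye = "left_eye",
            left_club_tip = "right_club_tip",
            right_club_tip = "left_club_tip",
            mantle_end = "mantle_end",
            shrimp_left_eye = "shrimp_right_eye",
            shrimp_right_eye = "shrimp_left_eye",
            hook = "hook", tail = "tail")
  x <- track$x; y <- track$y; lik <- track$likelihood
  for (p in names(swap)) {
    track$x[, swap[p]] <- 2 * axis_x - x[, p]
    track$y[, swap[p]] <- y[, p]
    track$likelihood[, swap[p]] <- lik[, p]
  }
  track
}

# --- independent oracles ------------------------------------------------

# angle via absolute polar angles, wrapped to (-180, 180]
oracle_angle <- function(u, v) {
  a <- (atan2(v[2], v[1]) - atan2(u[2], u[1])) * 180 / pi
  a <- ((a + 180) %% 360) - 180
  if (a <= -180) a <- a + 360
  if (a == -180) a <- 180
  a
}

# exact two-sided signed-rank p by explicit enumeration over sign
# masks, statistic recomputed per mask from scratch
oracle_signed_rank_p <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    pos <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    w <- sum(r[pos])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# exact two-sided Mann-Whitney p; U computed by pair counting (not
# rank sums) and enumerated over all group labelings
oracle_mann_whitney_p <- function(x, y) {
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bj in b)
      u <- u + (ai > bj) + 0.5 * (ai == bj)
    u
  }
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  mu <- n1 * n2 / 2
  u_obs <- u_of(x, y)
  sets <- utils::combn(n1 + n2, n1)
  count <- 0L
  for (k in seq_len(ncol(sets))) {
    a <- pool[sets[, k]]; b <- pool[-sets[, k]]
    if (abs(u_of(a, b) - mu) >= abs(u_obs - mu) - 1e-9)
      count <- count + 1L
  }
  count / ncol(sets)
}
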