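#' Canonical tracked body parts
#'
#' Nine body parts are tracked per frame: five on the cuttlefish (both
#' eyes, both tentacle club tips, and the dorsal mantle end) and four on
#' the shrimp target (both eyes, the hook attaching it to the rig, and
#' the tail). Shrimp labels carry a `shrimp_` prefix so the two sets are
#' disjoint.
#'
#' @param animal `"cuttlefish"`, `"shrimp"` or `"all"` (default).
#' @return Character vector of canonical body-part labels.
#' @export
#' @examples
#' body_parts("cuttlefish")
body_parts <- function(animal = c("all", "cuttlefish", "shrimp")) {
  animal <- match.arg(animal)
  cf <- c("left_eye", "right_eye", "left_club_tip", "right_club_tip",
          "mantle_end")
  sh <- c("shrimp_left_eye", "shrimp_right_eye", "hook", "tail")
  switch(animal, cuttlefish = cf, shrimp = sh, all = c(cf, sh))
}

#' Trial metadata and calibration
#'
#' Bundles the acquisition parameters attached to every pose track:
#' frame rate, spatial calibration, frame size and session length. The
#' pixel-to-millimetre calibration is a required input because it cannot
#' be inferred from a pose table.
#'
#' @param animal_id,trial_id Identifiers (coerced to character).
#' @param mm_per_px Millimetres per pixel (> 0).
#' @param fps Frames per second (default 90).
#' @param frame_size Integer vector `c(width, height)` in pixels.
#' @param session_length_s Session length in seconds (default 120).
#' @return An object of class `trial_metadata`.
#' @export
trial_metadata <- function(animal_id, trial_id, mm_per_px, fps = 90,
                           frame_size = c(2048L, 2048L),
                           session_length_s = 120) {
  stopifnot(length(mm_per_px) == 1, length(fps) == 1,
            length(session_length_s) == 1, length(frame_size) == 2)
  if (!is.finite(fps) || fps <= 0)
    stop("`fps` must be a positive number", call. = FALSE)
  if (!is.finite(mm_per_px) || mm_per_px <= 0)
    stop("`mm_per_px` must be a positive number", call. = FALSE)
  if (!is.finite(session_length_s) || session_length_s <= 0)
    stop("`session_length_s` must be a positive number", call. = FALSE)
  if (any(frame_size <= 0))
    stop("`frame_size` must be positive", call. = FALSE)
  structure(
    list(animal_id = as.character(animal_id),
         trial_id = as.character(trial_id),
         fps = as.numeric(fps), mm_per_px = as.numeric(mm_per_px),
         frame_size = as.numeric(frame_size),
         session_length_s = as.numeric(session_length_s)),
    class = "trial_metadata")
}

#' @export
print.trial_metadata <- function(x, ...) {
  cat(sprintf("Trial %s/%s: %g fps, %g mm/px, %gx%g px, %g s\n",
              x$animal_id, x$trial_id, x$fps, x$mm_per_px,
              x$frame_size[1], x$frame_size[2], x$session_length_s))
  invisible(x)
}

#' Construct a pose track
#'
#' A pose track holds per-frame image coordinates and detection
#' confidence for all nine canonical body parts, in image convention
#' (origin top-left, y increasing downward), with 0-based frame indices.
#'
#' @param x,y Numeric matrices, one row per frame, one column per body
#'   part (column names must be `body_parts()`). `NA` marks a missing
#'   (gated-out) coordinate.
#' @param likelihood Numeric matrix of the same shape with values in
#'   \[0, 1\] (`NA` allowed where coordinates are missing).
#' @param metadata A [trial_metadata()] object.
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(x, y, likelihood, metadata) {
  stopifnot(inherits(metadata, "trial_metadata"))
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  parts <- body_parts()
  for (m in list(x, y, likelihood)) {
    if (!identical(dim(m), dim(x)))
      stop("x, y and likelihood must have identical dimensions", call. = FALSE)
  }
  if (ncol(x) != length(parts) || !setequal(colnames(x), parts))
    stop("pose track must have one column per canonical body part",
         call. = FALSE)
  x <- x[, parts, drop = FALSE]
  y <- y[, parts, drop = FALSE]
  likelihood <- likelihood[, parts, drop = FALSE]
  bad <- likelihood[!is.na(likelihood)]
  if (any(bad < 0 | bad > 1))
    stop("likelihood values must lie in [0, 1]", call. = FALSE)
  nmax <- metadata$fps * metadata$session_length_s + 1
  if (nrow(x) > nmax)
    stop(sprintf("track has %d frames but the session admits at most %d",
                 nrow(x), as.integer(nmax)), call. = FALSE)
  structure(list(metadata = metadata, x = x, y = y,
                 likelihood = likelihood),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames x %d body parts (%s/%s)\n",
              nrow(x$x), ncol(x$x), x$metadata$animal_id,
              x$metadata$trial_id))
  invisible(x)
}

#' Number of frames in a track
#' @param track A `pose_track` or `clean_track`.
#' @return Integer frame count.
#' @export
n_frames <- function(track) nrow(track$x)

#' Read a pose table in the DeepLabCut CSV dialect
#'
#' The dialect has three header rows (scorer, bodyparts, coords), a
#' first column holding the frame index, and then `x`, `y`,
#' `likelihood` columns cycling per body part. File body-part names are
#' mapped onto the canonical nine labels through `label_map`; shrimp
#' parts whose file names collide with cuttlefish ones (left/right eye)
#' must be disambiguated there.
#'
#' @param path Path to the CSV file.
#' @param metadata A [trial_metadata()] object.
#' @param label_map Named character vector mapping file body-part names
#'   to canonical labels, e.g. `c(cf_eye_l = "left_eye")`. Defaults to
#'   the identity map on the canonical names.
#' @return A [pose_track()].
#' @export
read_dlc_csv <- function(path, metadata, label_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 3)
    stop("not a DeepLabCut table: fewer than 3 header rows", call. = FALSE)
  parts_row <- as.character(raw[2, -1])
  coords_row <- tolower(as.character(raw[3, -1]))
  if (is.null(label_map)) {
    label_map <- stats::setNames(body_parts(), body_parts())
  }
  file_parts <- unique(parts_row)
  canon <- unname(label_map[file_parts])
  if (anyNA(canon)) {
    canon <- canon[!is.na(canon)]
  }
  missing_parts <- setdiff(body_parts(), canon)
  if (length(missing_parts) > 0)
    stop("pose table header lacks required body part(s): ",
         paste(missing_parts, collapse = ", "), call. = FALSE)

  dat <- raw[-(1:3), , drop = FALSE]
  n <- nrow(dat)
  parts <- body_parts()
  x <- y <- lik <- matrix(NA_real_, n, length(parts),
                          dimnames = list(NULL, parts))
  for (fp in file_parts) {
    cp <- unname(label_map[fp])
    if (is.na(cp) || !(cp %in% parts)) next
    cols <- which(parts_row == fp) + 1L  # offset for the index column
    for (j in cols) {
      kind <- coords_row[j - 1L]
      if (!kind %in% c("x", "y", "likelihood")) next
      vals <- suppressWarnings(as.numeric(dat[[j]]))
      bad <- which(is.na(vals) & !(dat[[j]] %in% c("", "NA", "NaN")))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value '%s' at data row %d, column %d",
                     dat[[j]][bad[1]], bad[1], j), call. = FALSE)
      if (kind == "x") x[, cp] <- vals
      if (kind == "y") y[, cp] <- vals
      if (kind == "likelihood") {
        if (any(vals < 0 | vals > 1, na.rm = TRUE))
          stop(sprintf("likelihood outside [0, 1] for body part '%s'", cp),
               call. = FALSE)
        lik[, cp] <- vals
      }
    }
  }
  pose_track(x, y, lik, metadata)
}

#' Write a pose track in the DeepLabCut CSV dialect
#'
#' Emits the three-header-row dialect read by [read_dlc_csv()].
#' Coordinates are printed with six decimal places, so a write/read
#' round trip preserves them to well under 1e-6 px.
#'
#' @param track A [pose_track()].
#' @param path Output file path.
#' @param scorer Scorer name placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(track, path, scorer = "pursuitkin") {
  stopifnot(inherits(track, "pose_track"))
  parts <- colnames(track$x)
  ncols <- 1L + 3L * length(parts)
  h1 <- c("scorer", rep(scorer, 3L * length(parts)))
  h2 <- c("bodyparts", rep(parts, each = 3L))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(h1, collapse = ","), con)
  writeLines(paste(h2, collapse = ","), con)
  writeLines(paste(h3, collapse = ","), con)
  n <- n_frames(track)
  if (n > 0) {
    body <- matrix("", n, ncols)
    body[, 1] <- as.character(0:(n - 1))
    fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
    for (k in seq_along(parts)) {
      body[, 3 * k - 1] <- fmt(track$x[, k])
      body[, 3 * k]     <- fmt(track$y[, k])
      body[, 3 * k + 1] <- fmt(track$likelihood[, k])
    }
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Load the packaged attention-episode reference table
#'
#' The packaged fixture transcribes the study's summary table of all
#' responding animals: one row per attention episode with the animal and
#' trial identifiers, whether the trial contained a tentacular strike
#' attempt and whether it succeeded, the episode duration in seconds,
#' and whether the episode immediately preceded a strike attempt.
#' Integrity is checked on load: 10 animals, 16 trials, 29 episodes, 10
#' pre-strike episodes.
#'
#' @param path Path to the fixture CSV; defaults to the packaged copy.
#' @return A `data.frame` of class `table1_fixture` with columns
#'   `animal`, `trial`, `attempt`, `success`, `duration_s`, `pre_strike`.
#' @export
#' @examples
#' tab <- load_table1()
#' nrow(tab)  # 29 episodes
load_table1 <- function(path = system.file("extdata", "table1_episodes.csv",
                                           package = "pursuitkin")) {
  if (!nzchar(path) || !file.exists(path))
    stop("episode fixture not found", call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "trial", "attempt", "success", "duration_s",
            "pre_strike")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("fixture lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_animals <- length(unique(tab$animal))
  n_trials <- nrow(unique(tab[, c("animal", "trial")]))
  if (n_animals != 10 || n_trials != 16 || nrow(tab) != 29 ||
      sum(tab$pre_strike) != 10)
    stop(sprintf(paste0("fixture integrity check failed: ",
                        "%d animals, %d trials, %d episodes, %d pre-strike ",
                        "(expected 10/16/29/10)"),
                 n_animals, n_trials, nrow(tab), sum(tab$pre_strike)),
         call. = FALSE)
  class(tab) <- c("table1_fixture", "data.frame")
  tab
}
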