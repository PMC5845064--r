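# Trial recording container and CSV dialect.
#
# One trial per file. Long CSV with columns
#   t, channel, x, y, z, qw, qx, qy, qz, voltage
# where channel is one of maryland_pose, needle_pose, scope_pose,
# maryland_grip, needle_grip. Pose rows leave `voltage` empty; grip rows
# leave the pose fields empty. A JSON sidecar (same path, .json extension)
# carries subject id, trial index, nominal rate, and optional seed and
# ground-truth rating.

POSE_CHANNELS <- c("maryland_pose", "needle_pose", "scope_pose")
GRIP_CHANNELS <- c("maryland_grip", "needle_grip")
TRIAL_COLUMNS <- c("t", "channel", "x", "y", "z", "qw", "qx", "qy", "qz", "voltage")
TOOLS <- c("maryland", "needle")

#' Construct a trial recording
#'
#' A trial recording holds the raw timestamped sensor streams of one task
#' performance: 6-DOF poses (position in cm, orientation as unit quaternion
#' w,x,y,z, sensor-to-world) for the two instruments and the endoscope, plus
#' the two grip-sensor voltage streams, sampled at approximately 20 Hz.
#' Timestamps are trial-relative seconds (t = 0 at the earliest sample).
#'
#' @param streams named list with elements `maryland_pose`, `needle_pose`,
#'   `scope_pose`; each a data.frame with columns t, x, y, z, qw, qx, qy, qz.
#' @param grip named list with elements `maryland`, `needle`; each a
#'   data.frame with columns t, voltage.
#' @param subject_id character scalar.
#' @param trial_index integer, 1 or 2.
#' @param rate_hz nominal sampling rate (Hz).
#' @param completed logical, whether the task finished before the 600 s cap.
#' @param rating optional [osats_rating()] ground truth.
#' @param seed optional integer recorded for synthetic trials.
#' @return object of class `trial_recording`.
#' @export
trial_recording <- function(streams, grip, subject_id, trial_index = 1L,
                            rate_hz = 20, completed = TRUE, rating = NULL,
                            seed = NULL) {
  rec <- structure(
    list(streams = streams, grip = grip,
         meta = list(subject_id = as.character(subject_id),
                     trial_index = as.integer(trial_index),
                     rate_hz = rate_hz, completed = isTRUE(completed),
                     seed = seed, rating = rating)),
    class = "trial_recording")
  assert_trial_structure(rec)
  rec
}

# hard structural invariants; softer quality checks live in validate_trial()
assert_trial_structure <- function(rec) {
  if (!setequal(names(rec$streams), POSE_CHANNELS))
    stop("trial must contain exactly the pose streams: ",
         paste(POSE_CHANNELS, collapse = ", "))
  if (!setequal(names(rec$grip), TOOLS))
    stop("trial must contain grip streams for: ", paste(TOOLS, collapse = ", "))
  for (ch in POSE_CHANNELS) {
    s <- rec$streams[[ch]]
    if (nrow(s) == 0) stop("empty channel: ", ch)
    if (any(!is.finite(s$t)) || any(s$t < 0)) stop("bad timestamps in ", ch)
    if (any(diff(s$t) <= 0)) stop("non-monotone timestamps in ", ch)
    qn <- sqrt(s$qw^2 + s$qx^2 + s$qy^2 + s$qz^2)
    if (any(abs(qn - 1) > 1e-6)) stop("non-unit quaternion in ", ch)
  }
  for (tool in TOOLS) {
    g <- rec$grip[[tool]]
    if (nrow(g) == 0) stop("empty channel: ", tool, "_grip")
    if (any(diff(g$t) <= 0)) stop("non-monotone timestamps in ", tool, "_grip")
  }
  invisible(rec)
}

#' @export
print.trial_recording <- function(x, ...) {
  d <- trial_duration(x)
  cat(sprintf("<trial_recording> subject %s, trial %d, %.1f s, %d pose samples/channel\n",
              x$meta$subject_id, x$meta$trial_index, d,
              nrow(x$streams$maryland_pose)))
  invisible(x)
}

#' Duration of a trial recording
#'
#' Last common timestamp over all five streams, in seconds.
#' @param rec a `trial_recording`.
#' @return numeric scalar, seconds.
#' @export
trial_duration <- function(rec) {
  ends <- c(vapply(rec$streams, function(s) max(s$t), 0),
            vapply(rec$grip, function(g) max(g$t), 0))
  min(ends)
}

#' Construct an OSATS rating
#'
#' Five expert domain scores (Respect for Tissue, Time and Motion, Instrument
#' Handling, Flow of Operation, Knowledge of Specific Procedure), each an
#' integer 1-5. The summed score (5-25) and the rounded average (1-5) are
#' derived.
#'
#' @param domains integer vector of length 5, values in 1..5.
#' @return object of class `osats_rating` with fields `domains`, `summed`,
#'   `rounded_avg`.
#' @export
osats_rating <- function(domains) {
  domains <- as.integer(domains)
  if (length(domains) != 5 || any(domains < 1L) || any(domains > 5L))
    stop("an OSATS rating is five integers in 1..5")
  names(domains) <- osats_domain_names()
  structure(list(domains = domains, summed = sum(domains),
                 rounded_avg = rounded_average(sum(domains))),
            class = "osats_rating")
}

#' OSATS domain names used throughout the package
#' @return character vector of length 5.
#' @export
osats_domain_names <- function() {
  c("respect_for_tissue", "time_and_motion", "instrument_handling",
    "flow_of_operation", "knowledge_of_procedure")
}

#' Rounded average OSATS score from a summed score
#'
#' `round(summed / 5)`. Because the summed score is an integer, the average
#' is never exactly on a .5 boundary, so no tie-break rule is needed.
#'
#' @param summed integer in 5..25.
#' @return integer in 1..5.
#' @export
rounded_average <- function(summed) {
  if (any(summed < 5) || any(summed > 25) || any(summed != round(summed)))
    stop("summed OSATS score must be an integer in 5..25")
  as.integer(round(summed / 5))
}

#' Write a trial recording to CSV (+ JSON sidecar)
#'
#' The recording is validated structurally before any write. Numeric fields
#' survive a read/write round trip to better than 1e-9.
#'
#' @param rec a `trial_recording`.
#' @param path output CSV path; the metadata sidecar is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  assert_trial_structure(rec)
  rows <- vector("list", 5L)
  for (ch in POSE_CHANNELS) {
    s <- rec$streams[[ch]]
    rows[[ch]] <- data.frame(t = s$t, channel = ch, x = s$x, y = s$y, z = s$z,
                             qw = s$qw, qx = s$qx, qy = s$qy, qz = s$qz,
                             voltage = NA_real_)
  }
  for (tool in TOOLS) {
    g <- rec$grip[[tool]]
    rows[[paste0(tool, "_grip")]] <-
      data.frame(t = g$t, channel = paste0(tool, "_grip"),
                 x = NA_real_, y = NA_real_, z = NA_real_, qw = NA_real_,
                 qx = NA_real_, qy = NA_real_, qz = NA_real_,
                 voltage = g$voltage)
  }
  out <- do.call(rbind, rows[c(POSE_CHANNELS, paste0(TOOLS, "_grip"))])
  num <- setdiff(TRIAL_COLUMNS, "channel")
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), "", sprintf("%.15g", v)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  meta <- rec$meta
  meta$rating <- if (!is.null(meta$rating)) unname(meta$rating$domains)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a trial recording from CSV
#'
#' Inverse of [write_trial()]. Channels are mapped by the `channel` column;
#' a missing channel or non-monotone timestamps raise an error.
#'
#' @param path CSV path in the trial dialect.
#' @return a `trial_recording`.
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("trial file missing column(s): ", paste(missing_cols, collapse = ", "))
  streams <- list()
  for (ch in POSE_CHANNELS) {
    s <- df[df$channel == ch, c("t", "x", "y", "z", "qw", "qx", "qy", "qz")]
    if (nrow(s) == 0) stop("trial file missing channel: ", ch)
    streams[[ch]] <- s[order(s$t), , drop = FALSE]
    rownames(streams[[ch]]) <- NULL
  }
  grip <- list()
  for (tool in TOOLS) {
    ch <- paste0(tool, "_grip")
    g <- df[df$channel == ch, c("t", "voltage")]
    if (nrow(g) == 0) stop("trial file missing channel: ", ch)
    grip[[tool]] <- g[order(g$t), , drop = FALSE]
    rownames(grip[[tool]]) <- NULL
  }
  meta <- list(subject_id = "unknown", trial_index = 1L, rate_hz = 20,
               completed = TRUE, seed = NULL, rating = NULL)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    m <- jsonlite::read_json(sp, simplifyVector = TRUE)
    for (k in intersect(names(m), c("subject_id", "trial_index", "rate_hz",
                                    "completed", "seed")))
      meta[[k]] <- m[[k]]
    if (!is.null(m$rating)) meta$rating <- osats_rating(m$rating)
  }
  trial_recording(streams, grip, meta$subject_id, meta$trial_index,
                  meta$rate_hz, meta$completed, meta$rating, meta$seed)
}

#' Validate a trial recording
#'
#' Pure quality report: returns a data.frame of issues (empty when the
#' recording satisfies all invariants). Checked: presence and monotonicity of
#' all five streams, unit quaternions, the 600 s duration cap, and a median
#' sampling interval within [0.033, 0.1] s per stream (~10-30 Hz, bracketing
#' the nominal 20 Hz).
#'
#' @param rec a `trial_recording`.
#' @return data.frame with columns `severity`, `location`, `message`;
#'   zero rows when clean.
#' @export
validate_trial <- function(rec) {
  issues <- list()
  add <- function(severity, location, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, location = location, message = message)
  all_streams <- c(rec$streams,
                   stats::setNames(rec$grip, paste0(TOOLS, "_grip")))
  for (ch in names(all_streams)) {
    s <- all_streams[[ch]]
    if (nrow(s) == 0) { add("error", ch, "empty channel"); next }
    if (any(diff(s$t) <= 0)) add("error", ch, "non-monotone timestamps")
    if (nrow(s) >= 2) {
      md <- stats::median(diff(s$t))
      if (md < 0.033 || md > 0.1)
        add("warning", ch, sprintf(
          "median sampling interval %.4f s outside [0.033, 0.1] s", md))
    }
    if (max(s$t) > 600)
      add("error", ch, sprintf("duration %.1f s exceeds 600 s cap", max(s$t)))
    if (!is.null(s$qw)) {
      qn <- sqrt(s$qw^2 + s$qx^2 + s$qy^2 + s$qz^2)
      if (any(abs(qn - 1) > 1e-6)) add("error", ch, "non-unit quaternion")
    }
  }
  if (length(issues) == 0)
    return(data.frame(severity = character(), location = character(),
                      message = character()))
  do.call(rbind, issues)
}
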