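#' Construct a per-trial head/eye recording
#'
#' A `trial_recording` holds one participant-trial's paired eye and head
#' rotation series (yaw and pitch, in degrees) sampled at a fixed rate,
#' optionally with a vehicle speed trace. Samples that failed to parse or were
#' lost (blinks, tracker dropouts) are kept in place and flagged in
#' `missing_mask` rather than dropped, so the time base stays intact.
#'
#' @param timestamps numeric vector, seconds, strictly increasing.
#' @param eye_yaw,eye_pitch,head_yaw,head_pitch numeric vectors, degrees;
#'   `NA` where the sample is missing.
#' @param speed optional numeric vector, km/h.
#' @param sample_rate samples per second; inferred from the median timestamp
#'   spacing when `NULL`. The median spacing must agree with `1/sample_rate`
#'   to within 1%.
#' @param participant_id,trial_id identifier strings.
#' @param missing_mask logical vector; defaults to `NA` in any rotation
#'   channel.
#' @param unwrapped set `TRUE` when the yaw/pitch channels have been
#'   continuity-corrected and may legitimately leave (-180, 180].
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(timestamps, eye_yaw, eye_pitch, head_yaw, head_pitch,
                            speed = NULL, sample_rate = NULL,
                            participant_id = "unknown", trial_id = "unknown",
                            missing_mask = NULL, unwrapped = FALSE) {
  n <- length(timestamps)
  chans <- list(eye_yaw = eye_yaw, eye_pitch = eye_pitch,
                head_yaw = head_yaw, head_pitch = head_pitch)
  if (!is.null(speed)) chans$speed <- speed
  if (n < 2L) stop("recording must have at least 2 samples", call. = FALSE)
  if (any(vapply(chans, length, 0L) != n)) {
    stop("all channel vectors must have the same length as `timestamps`", call. = FALSE)
  }
  if (anyNA(timestamps) || any(diff(timestamps) <= 0)) {
    stop("non-monotone timestamps", call. = FALSE)
  }
  if (is.null(missing_mask)) {
    missing_mask <- is.na(eye_yaw) | is.na(eye_pitch) | is.na(head_yaw) | is.na(head_pitch)
  }
  stopifnot(is.logical(missing_mask), length(missing_mask) == n)
  dt <- stats::median(diff(timestamps))
  if (is.null(sample_rate)) sample_rate <- 1 / dt
  if (sample_rate <= 0) stop("`sample_rate` must be positive", call. = FALSE)
  if (abs(dt - 1 / sample_rate) > 0.01 / sample_rate) {
    stop("median timestamp spacing is not within 1% of 1/sample_rate", call. = FALSE)
  }
  if (!unwrapped) {
    rot <- c(eye_yaw, eye_pitch, head_yaw, head_pitch)
    rot <- rot[!is.na(rot)]
    if (length(rot) && (any(rot <= -180) || any(rot > 180))) {
      stop("rotation values outside (-180, 180]; pass unwrapped = TRUE for continuity-corrected data",
           call. = FALSE)
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         trial_id = as.character(trial_id),
         sample_rate = sample_rate,
         timestamps = as.numeric(timestamps),
         eye_yaw = as.numeric(eye_yaw), eye_pitch = as.numeric(eye_pitch),
         head_yaw = as.numeric(head_yaw), head_pitch = as.numeric(head_pitch),
         speed = if (is.null(speed)) NULL else as.numeric(speed),
         missing_mask = missing_mask,
         unwrapped = isTRUE(unwrapped),
         fraction_interpolated = 0,
         all_missing = all(missing_mask)),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> participant %s, trial %s\n", x$participant_id, x$trial_id))
  cat(sprintf("  %d samples at %.6g Hz (%.1f s), %d masked (%.1f%%)%s\n",
              length(x$timestamps), x$sample_rate,
              diff(range(x$timestamps)), sum(x$missing_mask),
              100 * mean(x$missing_mask),
              if (is.null(x$speed)) "" else ", with speed trace"))
  invisible(x)
}

#' Default column mapping for trial files
#'
#' Maps the recording's fields to column names of a delimited trial file.
#' Override entries to adapt arbitrary logger exports.
#'
#' @param ... named overrides, e.g. `eye_yaw = "gaze_x_deg"`.
#' @return Named character vector.
#' @export
trial_schema <- function(...) {
  schema <- c(time = "time_s",
              eye_yaw = "eye_yaw_deg", eye_pitch = "eye_pitch_deg",
              head_yaw = "head_yaw_deg", head_pitch = "head_pitch_deg",
              speed = "speed_kmh")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    schema[names(over)] <- over
  }
  schema
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' Read a per-trial recording from a delimited text file
#'
#' Expects UTF-8 delimited text (tab, comma, or whitespace separated) with a
#' header row. Rows whose rotation values fail numeric parsing (empty, `"NA"`,
#' garbage) are retained and flagged in `missing_mask`, never silently
#' dropped. Timestamps must parse and be strictly increasing.
#'
#' @param path file path.
#' @param schema column mapping from [trial_schema()].
#' @param participant_id,trial_id identifiers; default derived from the file
#'   name.
#' @param sample_rate override for the inferred sampling rate (Hz).
#' @param unwrapped see [trial_recording()].
#' @return A [trial_recording()].
#' @export
load_trial <- function(path, schema = trial_schema(),
                       participant_id = NULL, trial_id = NULL,
                       sample_rate = NULL, unwrapped = FALSE) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), strip.white = TRUE)
  need <- schema[c("time", "eye_yaw", "eye_pitch", "head_yaw", "head_pitch")]
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from file: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  ts <- num(need[["time"]])
  if (anyNA(ts)) stop("timestamp column contains non-numeric values", call. = FALSE)
  has_speed <- schema[["speed"]] %in% names(raw)
  rec_id <- sub("\\.[^.]*$", "", basename(path))
  trial_recording(
    timestamps = ts,
    eye_yaw = num(schema[["eye_yaw"]]), eye_pitch = num(schema[["eye_pitch"]]),
    head_yaw = num(schema[["head_yaw"]]), head_pitch = num(schema[["head_pitch"]]),
    speed = if (has_speed) num(schema[["speed"]]) else NULL,
    sample_rate = sample_rate,
    participant_id = participant_id %||% rec_id,
    trial_id = trial_id %||% rec_id,
    unwrapped = unwrapped
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording to the standard trial file format
#'
#' Tab-separated, header row, masked samples written as `NA`.
#' `load_trial(write_trial(rec, path))` is the identity up to float
#' formatting.
#'
#' @param rec a [trial_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  stopifnot(inherits(rec, "trial_recording"))
  df <- data.frame(time_s = rec$timestamps,
                   eye_yaw_deg = rec$eye_yaw, eye_pitch_deg = rec$eye_pitch,
                   head_yaw_deg = rec$head_yaw, head_pitch_deg = rec$head_pitch)
  if (!is.null(rec$speed)) df$speed_kmh <- rec$speed
  df[rec$missing_mask, setdiff(names(df), c("time_s", "speed_kmh"))] <- NA
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interpolate short gaps in a recording
#'
#' Runs of missing samples no longer than `max_gap` seconds are filled by
#' linear interpolation per channel (the standard blink-artifact treatment);
#' longer runs, and runs touching either end of the recording, stay masked
#' for pairwise exclusion downstream. The returned recording reports the
#' fraction of samples interpolated.
#'
#' @param rec a [trial_recording()].
#' @param max_gap maximum gap duration to fill, seconds (default 0.1 s,
#'   about 9 samples at 90 Hz).
#' @return A [trial_recording()] with short gaps filled.
#' @export
clean_gaps <- function(rec, max_gap = 0.1) {
  stopifnot(inherits(rec, "trial_recording"), max_gap >= 0)
  if (rec$all_missing) {
    warning("recording is entirely missing; returned unchanged")
    return(rec)
  }
  mask <- rec$missing_mask
  if (!any(mask)) return(rec)
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  fill <- logical(length(mask))
  for (i in seq_along(runs$lengths)) {
    if (!runs$values[i]) next
    if (starts[i] == 1L || ends[i] == length(mask)) next   # no anchor on one side
    if (runs$lengths[i] / rec$sample_rate <= max_gap) fill[starts[i]:ends[i]] <- TRUE
  }
  if (any(fill)) {
    good <- !mask
    for (ch in c("eye_yaw", "eye_pitch", "head_yaw", "head_pitch", "speed")) {
      v <- rec[[ch]]
      if (is.null(v)) next
      ok <- good & !is.na(v)
      rec[[ch]][fill] <- stats::approx(rec$timestamps[ok], v[ok],
                                       xout = rec$timestamps[fill])$y
    }
    rec$missing_mask[fill] <- FALSE
  }
  rec$fraction_interpolated <- mean(fill)
  rec
}

#' Extract the aligned eye/head pair for one rotation axis
#'
#' Returns the two channel vectors for the requested axis, restricted to
#' samples where neither is masked; the same indices are removed from both so
#' the pairing (and temporal order) is preserved. Yaw is the conventional
#' analysis axis for head-eye coordination during driving.
#'
#' @param rec a [trial_recording()].
#' @param axis `"yaw"` or `"pitch"`.
#' @return List with elements `eye`, `head`, `timestamps`, `axis`.
#' @export
select_axis <- function(rec, axis = c("yaw", "pitch")) {
  stopifnot(inherits(rec, "trial_recording"))
  axis <- match.arg(axis)
  keep <- !rec$missing_mask
  list(eye = rec[[paste0("eye_", axis)]][keep],
       head = rec[[paste0("head_", axis)]][keep],
       timestamps = rec$timestamps[keep],
       axis = axis)
}
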