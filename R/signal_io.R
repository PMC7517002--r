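#' Construct a multi-channel physiological recording
#'
#' A recording holds one or more simultaously acquired channels (e.g. ECG at
#' 256 Hz together with EMG/RSP/SC at 32 Hz), a label, and metadata. All
#' channels must span the same duration: `length(channels[[ch]]) ==
#' round(duration_s * fs[ch])` for every channel.
#'
#' The label is either a single emotion name (discrete labelling, as in
#' music-induced four-emotion protocols) or a numeric `c(valence, arousal)`
#' pair on 1--9 scales (dimensional labelling, as in video-induced
#' protocols); rating pairs are mapped to quadrant classes by
#' [quadrant_label()] at segmentation time.
#'
#' @param id recording identifier (character scalar).
#' @param channels named list of numeric sample series, in channel order.
#' @param fs named numeric vector of sampling rates (Hz), same names as
#'   `channels`.
#' @param label emotion name (character) or numeric `c(valence, arousal)`.
#' @param duration_s recording duration in seconds; inferred from the first
#'   channel when `NULL`.
#' @param meta optional list of tags (subject, trial, day, ...).
#' @return an object of class `"recording"`.
#' @seealso [segment_recording()], [load_manifest()]
#' @export
recording <- function(id, channels, fs, label, duration_s = NULL, meta = list()) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
    stop("`channels` must be a non-empty named list of numeric series")
  if (!all(names(channels) %in% names(fs)))
    stop("every channel needs a sampling rate in `fs`")
  fs <- fs[names(channels)]
  if (any(fs <= 0)) stop("all sampling rates must be > 0")
  if (is.null(duration_s))
    duration_s <- length(channels[[1L]]) / fs[[1L]]
  for (ch in names(channels)) {
    expected <- round(duration_s * fs[[ch]])
    got <- length(channels[[ch]])
    if (got != expected)
      stop(sprintf(
        "channel '%s': %d samples but round(%g s x %g Hz) = %d expected",
        ch, got, duration_s, fs[[ch]], expected))
  }
  structure(
    list(id = as.character(id), channels = channels,
         fs = fs, label = label, duration_s = duration_s, meta = meta),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  lab <- if (is.numeric(x$label))
    sprintf("valence=%.2g arousal=%.2g", x$label[[1L]], x$label[[2L]])
  else as.character(x$label)
  cat(sprintf("<recording '%s'> %.6g s, label: %s\n", x$id, x$duration_s, lab))
  for (ch in names(x$channels))
    cat(sprintf("  %-8s %6g Hz  %d samples\n",
                ch, x$fs[[ch]], length(x$channels[[ch]])))
  invisible(x)
}

# Resolve a recording's label to a class name (quadrant for rating pairs).
recording_class <- function(rec) {
  if (is.numeric(rec$label)) {
    quadrant_label(rec$label[[1L]], rec$label[[2L]])
  } else {
    as.character(rec$label)
  }
}

#' Map valence/arousal ratings to quadrant emotion classes
#'
#' Ratings on the 1--9 scales are split at 5: strictly greater than 5 counts
#' as High, less than or equal to 5 as Low, yielding the four classes HVHA,
#' HVLA, LVLA and LVHA. Vectorised.
#'
#' @param valence,arousal numeric ratings in \[1, 9\].
#' @return character vector of class names.
#' @examples
#' quadrant_label(6, 7)  # "HVHA"
#' quadrant_label(5, 5)  # "LVLA": exactly 5 counts as Low
#' @export
quadrant_label <- function(valence, arousal) {
  if (any(valence < 1 | valence > 9) || any(arousal < 1 | arousal > 9))
    stop("ratings must lie in [1, 9]")
  v <- ifelse(valence > 5, "HV", "LV")
  a <- ifelse(arousal > 5, "HA", "LA")
  paste0(v, a)
}

#' Segment a recording into fixed-duration analysis windows
#'
#' Windows are half-open in time, `[t, t + window_s)`, consecutive and
#' non-overlapping, starting after an optional leading baseline that is
#' discarded (e.g. the 3 s pre-stimulus baseline of video trials). A trailing
#' partial window is dropped, so the number of segments is
#' `floor((duration_s - drop_baseline_s) / window_s)`. Segmentation is by
#' time, not sample count, so channels with different sampling rates stay
#' aligned; per-channel window lengths are `round(window_s * fs)`.
#'
#' Each segment inherits its recording's class label (rating pairs are
#' resolved through [quadrant_label()]).
#'
#' @param rec a [recording()].
#' @param window_s window length in seconds (> 0).
#' @param drop_baseline_s leading duration to discard, in seconds (>= 0,
#'   < duration).
#' @return list of `"segment_sample"` objects with fields `parent_id`,
#'   `window_index` (0-based), `channels`, `fs`, `label`, `window_s`.
#' @examples
#' rec <- recording("r1", list(sc = sin(1:3840 / 7)), c(sc = 32), "joy")
#' length(segment_recording(rec, window_s = 12))  # 10 from 120 s
#' @export
segment_recording <- function(rec, window_s, drop_baseline_s = 0) {
  stopifnot(inherits(rec, "recording"), window_s > 0, drop_baseline_s >= 0)
  if (drop_baseline_s >= rec$duration_s)
    stop("drop_baseline_s must be smaller than the recording duration")
  n_win <- floor((rec$duration_s - drop_baseline_s) / window_s + 1e-9)
  if (n_win < 1L) return(list())
  cls <- recording_class(rec)
  lapply(seq_len(n_win) - 1L, function(w) {
    chans <- lapply(names(rec$channels), function(ch) {
      len <- round(window_s * rec$fs[[ch]])
      off <- round(drop_baseline_s * rec$fs[[ch]])
      rec$channels[[ch]][(off + w * len + 1L):(off + (w + 1L) * len)]
    })
    names(chans) <- names(rec$channels)
    structure(
      list(parent_id = rec$id, window_index = w, channels = chans,
           fs = rec$fs, label = cls, window_s = window_s),
      class = "segment_sample")
  })
}

#' Load recordings from a manifest file
#'
#' The manifest is a JSON file with a top-level `recordings` array; each
#' entry has `id`, `label` (string, or object with `valence`/`arousal`),
#' optional `duration_s` and metadata fields, and a `channels` array of
#' `{name, fs, file}` objects. Channel files are single-column plain text
#' (one sample per row, optional `#` comments), resolved relative to the
#' manifest's directory. [generate_dataset()] writes this layout.
#'
#' @param path path to the manifest JSON.
#' @return list of [recording()] objects, channels in manifest order.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  lapply(man$recordings, function(entry) {
    chans <- list()
    fs <- numeric()
    for (chdef in entry$channels) {
      f <- file.path(base, chdef$file)
      if (!file.exists(f))
        stop(sprintf("channel '%s' of recording '%s': file not found: %s",
                     chdef$name, entry$id, chdef$file))
      chans[[chdef$name]] <- scan(f, what = double(), quiet = TRUE,
                                  comment.char = "#")
      fs[[chdef$name]] <- as.numeric(chdef$fs)
    }
    label <- if (is.list(entry$label))
      c(valence = as.numeric(entry$label$valence),
        arousal = as.numeric(entry$label$arousal))
    else as.character(entry$label)
    meta <- entry[setdiff(names(entry),
                          c("id", "label", "channels", "duration_s"))]
    recording(entry$id, chans, fs, label,
              duration_s = if (!is.null(entry$duration_s))
                as.numeric(entry$duration_s),
              meta = meta)
  })
}
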