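#' Specification for a synthetic labelled multi-channel dataset
#'
#' Each class is given its own signal-complexity parameters: the logistic-map
#' chaos parameter `a` (in \[3.5, 4\]; 3.5 is periodic, larger values are
#' increasingly chaotic) and a noise-to-signal ratio `nsr`. Every channel of
#' a recording is a sinusoid at the channel's base frequency plus the
#' class's logistic-map component (burn-in discarded, resampled to the
#' channel rate) plus Gaussian noise at the class NSR. Amplitude is
#' randomised per recording and channel, so class information is carried by
#' signal complexity -- what the entropy features measure -- and not by
#' trivial amplitude statistics.
#'
#' @param classes data.frame with columns `name`, `a`, `nsr`.
#' @param channels data.frame with columns `name`, `fs` (Hz), `f0` (base
#'   sinusoid frequency, Hz).
#' @param duration_s recording length in seconds.
#' @param recordings_per_class recordings generated for each class.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @param label_mode `"discrete"` stores the class name as label; `"rating"`
#'   stores a `(valence, arousal)` pair drawn inside the class's quadrant
#'   (class names must then be quadrant names HVHA/HVLA/LVLA/LVHA).
#' @return list of class `"synth_spec"`.
#' @seealso [synth_spec_augsburg()], [synth_spec_deap()], [synth_spec_demo()]
#' @export
synth_spec <- function(classes, channels, duration_s, recordings_per_class,
                       seed = 1L, label_mode = c("discrete", "rating")) {
  label_mode <- match.arg(label_mode)
  stopifnot(all(c("name", "a", "nsr") %in% names(classes)),
            all(c("name", "fs", "f0") %in% names(channels)),
            duration_s > 0, recordings_per_class >= 1,
            all(channels$fs > 0))
  structure(list(classes = classes, channels = channels,
                 duration_s = duration_s,
                 recordings_per_class = as.integer(recordings_per_class),
                 seed = as.integer(seed), label_mode = label_mode),
            class = "synth_spec")
}

# Four emotion classes with monotone complexity: sadness (calmest dynamics)
# -> pleasure -> anger -> joy (most chaotic and noisiest).
default_classes <- function(names = c("joy", "anger", "sadness", "pleasure")) {
  data.frame(name = names,
             a = c(4.0, 3.9, 3.5, 3.7),
             nsr = c(0.50, 0.30, 0.05, 0.15),
             stringsAsFactors = FALSE)
}

#' Music-protocol-shaped synthetic preset
#'
#' Emulates the structure of the single-subject music-induced corpus: four
#' discrete emotions, 25 recordings each (100 total), 120 s long, with an
#' ECG-like channel at 256 Hz and EMG/RSP/SC-like channels at 32 Hz.
#' Segmenting at 12 s yields exactly 1000 samples.
#'
#' @param seed integer seed.
#' @export
synth_spec_augsburg <- function(seed = 1L) {
  synth_spec(
    classes = default_classes(),
    channels = data.frame(
      name = c("ecg", "emg", "rsp", "sc"),
      fs = c(256, 32, 32, 32),
      f0 = c(1.1, 6, 0.3, 0.08), stringsAsFactors = FALSE),
    duration_s = 120, recordings_per_class = 25, seed = seed,
    label_mode = "discrete")
}

#' Video-protocol-shaped synthetic preset (one subject)
#'
#' Emulates one subject of the video-induced corpus: 40 trials of 63 s
#' (3 s baseline + 60 s stimulus) at 128 Hz with GSR/RSP/BVP/EMG-like
#' channels, labelled by valence/arousal ratings whose quadrants are
#' balanced (10 trials per quadrant). Dropping the 3 s baseline and
#' segmenting at 6 s yields exactly 400 samples.
#'
#' @param seed integer seed.
#' @export
synth_spec_deap <- function(seed = 1L) {
  synth_spec(
    classes = default_classes(c("HVHA", "LVHA", "LVLA", "HVLA")),
    channels = data.frame(
      name = c("gsr", "rsp", "bvp", "emg"),
      fs = c(128, 128, 128, 128),
      f0 = c(0.08, 0.3, 1.2, 6), stringsAsFactors = FALSE),
    duration_s = 63, recordings_per_class = 10, seed = seed,
    label_mode = "rating")
}

#' Small synthetic preset for fast end-to-end runs
#'
#' Same four-class complexity structure as the full presets, shrunk for
#' quick pipelines: 8 recordings per class, 30 s, four channels all at
#' 32 Hz. Segmenting at 6 s gives 160 samples of 192 points per channel.
#'
#' @param seed integer seed.
#' @param recordings_per_class,duration_s override the preset size.
#' @export
synth_spec_demo <- function(seed = 1L, recordings_per_class = 8,
                            duration_s = 30) {
  synth_spec(
    classes = default_classes(),
    channels = data.frame(
      name = c("ecg", "emg", "rsp", "sc"),
      fs = c(32, 32, 32, 32),
      f0 = c(1.1, 6, 0.3, 0.08), stringsAsFactors = FALSE),
    duration_s = duration_s, recordings_per_class = recordings_per_class,
    seed = seed, label_mode = "discrete")
}

# Logistic map x_{n+1} = a x_n (1 - x_n), burn-in discarded, centred to
# roughly unit scale.
logistic_series <- function(a, n, burn = 1000L) {
  x <- runif(1, 0.2, 0.8)
  for (i in seq_len(burn)) x <- a * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- a * x * (1 - x)
    out[i] <- x
  }
  (out - 0.5) * 2
}

#' Generate one synthetic recording
#'
#' @param cls class name (must appear in `spec$classes$name`).
#' @param spec a [synth_spec()].
#' @param seed integer seed; same seed, same samples.
#' @param id recording identifier.
#' @return a [recording()].
#' @export
generate_recording <- function(cls, spec, seed = spec$seed,
                               id = paste0(cls, "_", seed)) {
  row <- match(cls, spec$classes$name)
  if (is.na(row)) stop("unknown class: ", cls)
  a <- spec$classes$a[row]; nsr <- spec$classes$nsr[row]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  label <- if (spec$label_mode == "rating") rating_for_quadrant(cls) else cls
  # one logistic source per recording, generated at 32 Hz and resampled
  t32 <- seq(0, spec$duration_s, by = 1 / 32)
  chaos32 <- logistic_series(a, length(t32))
  chans <- list(); fs <- numeric()
  for (k in seq_len(nrow(spec$channels))) {
    ch <- spec$channels$name[k]
    f_s <- spec$channels$fs[k]
    n <- round(spec$duration_s * f_s)
    t <- (seq_len(n) - 1) / f_s
    base <- sin(2 * pi * spec$channels$f0[k] * t + runif(1, 0, 2 * pi))
    chaos <- if (f_s == 32) chaos32[seq_len(n)]
             else approx(t32, chaos32, xout = t)$y
    clean <- base + chaos
    noise <- rnorm(n, sd = nsr * sd(clean))
    amp <- runif(1, 0.5, 2)
    chans[[ch]] <- amp * (clean + noise)
    fs[[ch]] <- f_s
  }
  recording(id, chans, fs, label, duration_s = spec$duration_s,
            meta = list(class = cls, seed = seed))
}

# Uniform rating pair inside a quadrant (High side drawn from (5.5, 9),
# Low side from (1, 5)).
rating_for_quadrant <- function(q) {
  hv <- substr(q, 1, 2) == "HV"; ha <- substr(q, 3, 4) == "HA"
  c(valence = if (hv) runif(1, 5.5, 9) else runif(1, 1, 5),
    arousal = if (ha) runif(1, 5.5, 9) else runif(1, 1, 5))
}

#' Generate a full synthetic dataset (optionally on disk)
#'
#' Produces `recordings_per_class` recordings for each class, class-balanced
#' and deterministic in `spec$seed`. With `out_dir` set, per-channel series
#' are written as single-column CSV files plus a JSON manifest readable by
#' [load_manifest()].
#'
#' @param spec a [synth_spec()].
#' @param out_dir directory for channel files and `manifest.json`, or
#'   `NULL` (default) to keep everything in memory.
#' @return list with `recordings` and `manifest` (path or `NULL`).
#' @export
generate_dataset <- function(spec, out_dir = NULL) {
  recs <- list()
  for (ci in seq_len(nrow(spec$classes))) {
    cls <- spec$classes$name[ci]
    for (ri in seq_len(spec$recordings_per_class)) {
      sd_i <- rep_seed(spec$seed, ci * 1000L + ri)
      recs[[length(recs) + 1L]] <-
        generate_recording(cls, spec, seed = sd_i,
                           id = sprintf("%s_%02d", cls, ri))
    }
  }
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    entries <- lapply(recs, function(rec) {
      chandefs <- lapply(names(rec$channels), function(ch) {
        fn <- sprintf("%s_%s.csv", rec$id, ch)
        writeLines(formatC(rec$channels[[ch]], format = "g", digits = 12),
                   file.path(out_dir, fn))
        list(name = ch, fs = rec$fs[[ch]], file = fn)
      })
      label <- if (is.numeric(rec$label))
        list(valence = rec$label[["valence"]], arousal = rec$label[["arousal"]])
      else rec$label
      list(id = rec$id, label = label, duration_s = rec$duration_s,
           class = rec$meta$class, channels = chandefs)
    })
    manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(list(recordings = entries), manifest,
                         auto_unbox = TRUE, digits = NA)
  }
  list(recordings = recs, manifest = manifest)
}
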