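#' Generate a synthetic audiovisual stimulus with a known event script
#'
#' Produces a short video of moving high-contrast blobs plus an
#' amplitude-modulated tone, with scripted salient events (a global
#' luminance step, a colour change, an onset flicker, loud audio moments)
#' whose ground-truth seconds are returned alongside — so feature
#' extraction can be validated against what was actually put in.
#'
#' Disabling everything (`n_blobs = 0`, all event vectors `integer(0)`,
#' `base_amp = 0`) yields uniform gray frames and silence: every
#' conspicuity channel and the RMS volume are then exactly zero.
#'
#' @param duration_s Stimulus length in whole seconds.
#' @param frame_rate Frames per second (>= 1; small rates keep fixtures
#'   cheap).
#' @param audio_rate Audio samples per second (>= 1000).
#' @param seed Integer seed (blob trajectories, default event times).
#' @param width,height Frame size in pixels.
#' @param n_blobs Number of moving bright blobs (0 disables).
#' @param luminance_steps,colour_changes,flicker_onsets,loud_events Integer
#'   vectors of event seconds, `NULL` for an automatic script, `integer(0)`
#'   to disable.
#' @param base_amp Baseline audio amplitude in \[0, 1\] (0 = silence
#'   outside loud events).
#' @param loud_amp Amplitude during loud events.
#' @return List: `frames` (list of `height x width x 3` arrays in \[0, 1\]),
#'   `frame_rate`, `audio` (numeric vector in \[-1, 1\]), `audio_rate`,
#'   `events` (data.frame `t_s`, `type`).
#' @export
generate_stimulus <- function(duration_s, frame_rate = 4, audio_rate = 2000,
                              seed = 1L, width = 64, height = 48,
                              n_blobs = 2, luminance_steps = NULL,
                              colour_changes = NULL, flicker_onsets = NULL,
                              loud_events = NULL, base_amp = 0.1,
                              loud_amp = 0.8) {
  stopifnot(duration_s >= 1, frame_rate >= 1, audio_rate >= 1000,
            base_amp >= 0, base_amp <= 1, loud_amp >= 0, loud_amp <= 1)
  set.seed(seed)
  auto_times <- function(k) if (duration_s < 10) integer(0) else
    sort(sample(5:(duration_s - 3), k))
  if (is.null(luminance_steps)) luminance_steps <- auto_times(1)
  if (is.null(colour_changes)) colour_changes <- auto_times(1)
  if (is.null(flicker_onsets)) flicker_onsets <- auto_times(1)
  if (is.null(loud_events)) loud_events <- auto_times(1)

  n_frames <- duration_s * frame_rate
  xg <- matrix(rep(seq_len(width), each = height), height, width)
  yg <- matrix(rep(seq_len(height), width), height, width)
  # smooth sinusoidal blob trajectories
  traj <- lapply(seq_len(n_blobs), function(b) {
    list(fx = stats::runif(1, 0.02, 0.08), fy = stats::runif(1, 0.02, 0.08),
         px = stats::runif(1, 0, 2 * pi), py = stats::runif(1, 0, 2 * pi),
         sigma = stats::runif(1, 2, 4))
  })
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    t_now <- (f - 1) / frame_rate
    sec <- floor(t_now)
    base <- 0.5
    if (sec %in% luminance_steps) base <- 0.7
    if (sec %in% flicker_onsets && (f %% 2 == 0)) base <- base + 0.25
    L <- matrix(base, height, width)
    for (b in traj) {
      cx <- width * (0.5 + 0.35 * sin(2 * pi * b$fx * t_now + b$px))
      cy <- height * (0.5 + 0.35 * sin(2 * pi * b$fy * t_now + b$py))
      L <- L + 0.45 * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * b$sigma^2))
    }
    L <- pmin(pmax(L, 0), 1)
    fr <- array(0, c(height, width, 3))
    if (sec %in% colour_changes) {
      fr[, , 1] <- pmin(L * 1.3, 1); fr[, , 2] <- L * 0.5; fr[, , 3] <- L * 0.5
    } else {
      fr[, , 1] <- L; fr[, , 2] <- L; fr[, , 3] <- L
    }
    frames[[f]] <- fr
  }

  n_samp <- duration_s * audio_rate
  tt <- (seq_len(n_samp) - 1) / audio_rate
  amp <- rep(base_amp, n_samp)
  if (base_amp > 0)                       # gentle AM so volume varies
    amp <- amp * (1 + 0.3 * sin(2 * pi * 0.05 * tt))
  for (ev in loud_events) amp[tt >= ev & tt < ev + 1] <- loud_amp
  audio <- amp * sin(2 * pi * 440 * tt)

  events <- rbind(
    if (length(luminance_steps))
      data.frame(t_s = luminance_steps, type = "luminance_step"),
    if (length(colour_changes))
      data.frame(t_s = colour_changes, type = "colour_change"),
    if (length(flicker_onsets))
      data.frame(t_s = flicker_onsets, type = "flicker_onset"),
    if (length(loud_events))
      data.frame(t_s = loud_events, type = "loud_event"))
  if (is.null(events)) events <- data.frame(t_s = integer(0),
                                            type = character(0))
  list(frames = frames, frame_rate = frame_rate,
       audio = audio, audio_rate = audio_rate, events = events)
}

#' Write stimulus frames as a PNG sequence
#'
#' Requires the `png` package. Files are named `frame_000001.png`, ... in
#' `dir`.
#'
#' @param frames List of RGB arrays.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_frames_png <- function(frames, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write frame sequences")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames))
    png::writePNG(frames[[i]], file.path(dir, sprintf("frame_%06d.png", i)))
  invisible(dir)
}

#' Read a PNG frame sequence
#'
#' @param dir Directory of PNG files (read in lexicographic order).
#' @return List of RGB arrays in \[0, 1\].
#' @export
read_frames_png <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read frame sequences")
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames in ", dir)
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  })
}
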