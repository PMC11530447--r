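#' Convert R-peak event times to a 1 Hz heart-rate series
#'
#' The instantaneous rate 60/RR (bpm) is assigned over each inter-peak
#' interval, giving a step function of time; each 1 s bin \[t, t+1) then
#' receives the time-average of that step function over the bin. Bins
#' entirely before the first peak or after the last carry the nearest
#' defined value.
#'
#' @param peak_times_s Strictly increasing numeric vector of R-peak times,
#'   seconds from stimulus onset.
#' @param duration_s Recording length in whole seconds (>= last peak time).
#' @param participant_id,group Metadata passed to [signal_series()].
#' @return A 1 Hz heart-rate [signal_series()] of length `duration_s`.
#' @export
#' @examples
#' rr_to_heart_rate(seq(0, 10, by = 0.5), 10, "p01")$values  # all 120 bpm
rr_to_heart_rate <- function(peak_times_s, duration_s,
                             participant_id = "unknown",
                             group = "audiovisual") {
  p <- as.numeric(peak_times_s)
  if (length(p) < 2)
    stop("fewer than 2 R-peaks: recording unusable for participant ",
         participant_id)
  if (any(diff(p) <= 0)) stop("R-peak times must be strictly increasing")
  duration_s <- as.integer(duration_s)
  if (duration_s < ceiling(p[length(p)]))
    stop("duration_s must cover the last R-peak")

  rate <- 60 / diff(p)             # bpm on [p_k, p_{k+1})
  vals <- rep(NA_real_, duration_s)
  for (t in seq_len(duration_s) - 1L) {
    lo <- t; hi <- t + 1
    a <- pmax(p[-length(p)], lo)
    b <- pmin(p[-1], hi)
    w <- pmax(b - a, 0)
    if (sum(w) > 0) vals[t + 1L] <- sum(rate * w) / sum(w)
  }
  # bins outside [first, last] peak carry the nearest defined value
  if (anyNA(vals)) {
    def <- which(!is.na(vals))
    if (!length(def)) stop("no bin overlaps the R-peak train")
    first <- def[1]; last <- def[length(def)]
    if (first > 1) vals[seq_len(first - 1)] <- vals[first]
    if (last < duration_s) vals[(last + 1):duration_s] <- vals[last]
  }
  signal_series(vals, participant_id, group, "heart_rate")
}

#' Flag implausible heart-rate samples
#'
#' Automatic replacement for manual artifact marking: a sample is flagged
#' when it falls outside the physiological plausibility band or jumps too
#' far from its predecessor. Artifactual beats produce artificially low or
#' high instantaneous heart rate, which both rules capture.
#'
#' @param series A heart-rate [signal_series()].
#' @param band Plausibility band in bpm (default `c(40, 180)`).
#' @param max_jump Maximum allowed absolute change between consecutive
#'   samples, bpm (default 20).
#' @return Logical mask, same length as the series.
#' @export
detect_artifacts <- function(series, band = c(40, 180), max_jump = 20) {
  stopifnot(is_signal_series(series), series$signal_kind == "heart_rate",
            length(band) == 2, band[1] < band[2], max_jump > 0)
  x <- series$values
  mask <- x < band[1] | x > band[2]
  jump <- c(FALSE, abs(diff(x)) > max_jump)
  mask | jump
}

#' Correct flagged samples by neighbor-mean bridging
#'
#' Each flagged sample is replaced by the mean of the nearest preceding and
#' nearest subsequent unflagged values. A run of consecutive flagged samples
#' receives that same bridging mean throughout; flagged samples at either
#' boundary copy the single nearest unflagged value.
#'
#' @param series A [signal_series()].
#' @param mask Logical vector, same length as the series; `TRUE` = artifact.
#' @return The corrected [signal_series()].
#' @export
#' @examples
#' s <- signal_series(c(70, 200, 80), "p", signal_kind = "heart_rate")
#' correct_artifacts(s, c(FALSE, TRUE, FALSE))$values  # 70 75 80
correct_artifacts <- function(series, mask) {
  stopifnot(is_signal_series(series), is.logical(mask),
            length(mask) == length(series$values))
  if (all(mask))
    stop("all samples flagged for participant ", series$participant_id,
         ": nothing to bridge from")
  x <- series$values
  clean <- which(!mask)
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    lo <- starts[k]; hi <- ends[k]
    prev <- clean[clean < lo]
    nxt <- clean[clean > hi]
    repl <- if (length(prev) && length(nxt))
      (x[max(prev)] + x[min(nxt)]) / 2
    else if (length(prev)) x[max(prev)] else x[min(nxt)]
    x[lo:hi] <- repl
  }
  out <- series
  out$values <- x
  out
}

#' Z-score a signal series
#'
#' Standardizes one participant's full recording to mean 0, sample SD 1,
#' the convention used to make skin-conductance and movement comparable
#' across participants.
#'
#' @param series A [signal_series()].
#' @return The standardized [signal_series()].
#' @export
standardize <- function(series) {
  stopifnot(is_signal_series(series))
  s <- stats::sd(series$values)
  if (!is.finite(s) || s == 0)
    stop("zero variance: cannot standardize participant ",
         series$participant_id)
  out <- series
  out$values <- (series$values - mean(series$values)) / s
  out
}

#' Combine triaxial accelerometry into a 1 Hz movement magnitude series
#'
#' Per sample, the three axes are combined (rectified sum by default:
#' |ax| + |ay| + |az|), then averaged within each 1 s bin.
#'
#' @param ax,ay,az Numeric vectors of equal length, acceleration in g-units.
#' @param sample_rate_hz Sampling rate of the input axes.
#' @param method `"rectified"` (default), `"signed"` (ax + ay + az) or
#'   `"norm"` (Euclidean).
#' @param participant_id,group Metadata for the output series.
#' @return A 1 Hz movement [signal_series()].
#' @export
movement_magnitude <- function(ax, ay, az, sample_rate_hz = 1,
                               method = c("rectified", "signed", "norm"),
                               participant_id = "unknown",
                               group = "audiovisual") {
  method <- match.arg(method)
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("axis vectors must have equal length")
  m <- switch(method,
              rectified = abs(ax) + abs(ay) + abs(az),
              signed = ax + ay + az,
              norm = sqrt(ax^2 + ay^2 + az^2))
  bin <- floor((seq_along(m) - 1) / sample_rate_hz)
  v <- as.numeric(tapply(m, bin, mean))
  signal_series(v, participant_id, group, "movement")
}

#' Preprocess a raw heart-rate series
#'
#' Convenience wrapper: detect artifacts, bridge them, and (optionally)
#' iterate once more so jump-rule flags created next to a bridge are also
#' cleaned.
#'
#' @param series A heart-rate [signal_series()].
#' @param band,max_jump Passed to [detect_artifacts()].
#' @return The cleaned series, with attribute `"n_corrected"`.
#' @export
clean_heart_rate <- function(series, band = c(40, 180), max_jump = 20) {
  mask <- detect_artifacts(series, band, max_jump)
  out <- correct_artifacts(series, mask)
  attr(out, "n_corrected") <- sum(mask)
  out
}
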