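# Low-level audiovisual salience features: five conspicuity channels
# (intensity, colour, orientation, flicker, motion) from a center-surround
# Gaussian-pyramid model, and per-second RMS volume from the soundtrack.
# The channel maps follow the classic biologically-inspired architecture:
# feature contrast is the rectified difference between a fine ("center")
# and a coarse ("surround") pyramid level, maps are combined after an
# iterative peak-promotion normalization that boosts maps with one
# dominant peak over maps with many comparable peaks.

luminance <- function(frame) {
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# 2x2 mean pooling with edge replication for odd sizes; constant inputs
# stay exactly constant (EBImage::resize pads borders with zeros, which
# would leave spurious contrast on uniform frames).
halve <- function(m) {
  if (nrow(m) %% 2) m <- rbind(m, m[nrow(m), ])
  if (ncol(m) %% 2) m <- cbind(m, m[, ncol(m)])
  oi <- seq(1, nrow(m), by = 2)
  oj <- seq(1, ncol(m), by = 2)
  (m[oi, oj, drop = FALSE] + m[oi + 1, oj, drop = FALSE] +
     m[oi, oj + 1, drop = FALSE] + m[oi + 1, oj + 1, drop = FALSE]) / 4
}

gaussian_pyramid <- function(img, n_levels) {
  out <- vector("list", n_levels)
  out[[1]] <- img
  for (k in seq_len(n_levels - 1)) {
    # blur before halving so decimation aliasing stays small (keeps the
    # maps approximately shift-invariant)
    out[[k + 1]] <- halve(EBImage::gblur(out[[k]], sigma = 1.4))
  }
  out
}

# bilinear interpolation to `dims`, clamped at the borders
upsample_to <- function(img, dims) {
  if (all(dim(img) == dims)) return(img)
  src_r <- nrow(img); src_c <- ncol(img)
  ri <- (seq_len(dims[1]) - 0.5) * src_r / dims[1] + 0.5
  cj <- (seq_len(dims[2]) - 0.5) * src_c / dims[2] + 0.5
  r0 <- pmin(pmax(floor(ri), 1), src_r); r1 <- pmin(r0 + 1, src_r)
  c0 <- pmin(pmax(floor(cj), 1), src_c); c1 <- pmin(c0 + 1, src_c)
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(cj - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc)
  b <- img[r1, c0, drop = FALSE] * outer(fr, 1 - fc)
  d <- img[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  e <- img[r1, c1, drop = FALSE] * outer(fr, fc)
  a + b + d + e
}

# Peak-promotion normalization: multiply the map by (M - mbar)^2 computed
# on its unit-max rescaling, where M = 1 is the global maximum and mbar
# the mean of the other local maxima. Maps with a single dominant peak
# keep their energy; maps with many similar peaks are suppressed. The
# absolute scale of the input is preserved (featureless maps stay tiny).
promote_peaks <- function(map) {
  M <- max(map)
  if (M <= 0) return(map * 0)
  m <- map / M
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(map)
  # locate maxima on a lightly smoothed copy, and only above a tenth of
  # the global peak: resampling ripple must not drag the maxima mean
  ms <- EBImage::gblur(m, sigma = 3)
  ctr <- ms[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr > 0.1
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (ctr >= ms[2:(nr - 1) + di, 2:(nc - 1) + dj])
  }
  peaks <- ctr[is_max]
  mbar <- if (length(peaks) > 1) mean(peaks[-which.max(peaks)]) else 0
  map * (1 - mbar)^2
}

# Rectified center-surround contrast across pyramid scales, returned at
# base resolution. `pyr` may be a list of pyramids (one per sub-feature,
# e.g. orientations); contributions are summed after normalization.
center_surround <- function(pyrs, centers, deltas, dims) {
  if (!is.list(pyrs[[1]])) pyrs <- list(pyrs)
  acc <- matrix(0, dims[1], dims[2])
  n_levels <- length(pyrs[[1]])
  for (pyr in pyrs) {
    for (cl in centers) {
      for (dl in deltas) {
        sl <- cl + dl
        if (sl > n_levels - 1) next
        d <- abs(upsample_to(pyr[[cl + 1]], dims) -
                   upsample_to(pyr[[sl + 1]], dims))
        acc <- acc + promote_peaks(d)
      }
    }
  }
  acc[acc < 1e-10] <- 0          # numerical floor (FFT/resampling roundoff)
  acc
}

# Zero-DC oriented (Gabor cosine) kernel; zero response on uniform input.
gabor_kernel <- function(theta, size = 7, sigma = 2, lambda = 4) {
  half <- (size - 1) / 2
  g <- outer(-half:half, -half:half, function(x, y) {
    xr <- x * cos(theta) + y * sin(theta)
    yr <- -x * sin(theta) + y * cos(theta)
    exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda)
  })
  g - mean(g)
}

shift_img <- function(img, di, dj) {
  nr <- nrow(img); nc <- ncol(img)
  img[((seq_len(nr) - 1 - di) %% nr) + 1, ((seq_len(nc) - 1 - dj) %% nc) + 1,
      drop = FALSE]
}

default_pyramid_depth <- function(dims) {
  max(2L, floor(log2(min(dims) / 8)) + 1L)
}

#' Conspicuity maps for one video frame
#'
#' Computes the five channel maps (intensity, colour, orientation, flicker,
#' motion) of a center-surround salience model for frame t given frame
#' t-1. Intensity is the across-scale contrast of luminance; colour the
#' same operator on red-green and blue-yellow opponency; orientation uses
#' four oriented zero-DC Gabor responses (0, 45, 90, 135 degrees) combined
#' across scales; flicker is the contrast of the absolute luminance change
#' between frames; motion uses direction-shifted opponent products of the
#' consecutive luminance pyramids (zero for a static scene). Each
#' intermediate map passes through peak-promotion normalization before
#' summation.
#'
#' The pyramid depth and the center/surround level pairs adapt to the frame
#' size by default (small synthetic frames support fewer octaves); for
#' full-resolution video the classic setting is `centers = 2:4`,
#' `deltas = 3:4` with a deep pyramid.
#'
#' @param frame Array `h x w x 3`, RGB in \[0, 1\].
#' @param frame_prev Previous frame (same shape) or `NULL` (first frame:
#'   flicker and motion are identically 0).
#' @param n_levels Pyramid depth; default adapts to frame size.
#' @param centers Center pyramid levels (0-based); default adapts.
#' @param deltas Surround offsets (surround level = center + delta).
#' @return Named list of five non-negative base-resolution matrices:
#'   `intensity`, `colour`, `orientation`, `flicker`, `motion`.
#' @export
conspicuity_maps <- function(frame, frame_prev = NULL, n_levels = NULL,
                             centers = NULL, deltas = NULL) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3,
            min(frame) >= 0, max(frame) <= 1)
  dims <- dim(frame)[1:2]
  if (!is.null(frame_prev)) stopifnot(all(dim(frame_prev) == dim(frame)))
  if (is.null(n_levels)) n_levels <- default_pyramid_depth(dims)
  if (is.null(centers)) centers <- 0:max(0, n_levels - 3)
  if (is.null(deltas)) deltas <- 1:2
  zero <- matrix(0, dims[1], dims[2])

  L <- luminance(frame)
  pL <- gaussian_pyramid(L, n_levels)
  intensity <- center_surround(pL, centers, deltas, dims)

  rg <- frame[, , 1] - frame[, , 2]
  by <- frame[, , 3] - (frame[, , 1] + frame[, , 2]) / 2
  colour <- center_surround(list(gaussian_pyramid(rg, n_levels),
                                 gaussian_pyramid(by, n_levels)),
                            centers, deltas, dims)

  thetas <- c(0, 45, 90, 135) * pi / 180
  opyrs <- lapply(thetas, function(th) {
    k <- gabor_kernel(th)
    lapply(pL, function(lv) {
      if (min(dim(lv)) < nrow(k)) return(lv * 0)
      abs(EBImage::filter2(lv, k, boundary = "circular"))
    })
  })
  orientation <- center_surround(opyrs, centers, deltas, dims)

  if (is.null(frame_prev)) {
    flicker <- zero
    motion <- zero
  } else {
    Lp <- luminance(frame_prev)
    pLp <- gaussian_pyramid(Lp, n_levels)
    fpyr <- mapply(function(a, b) abs(a - b), pL, pLp, SIMPLIFY = FALSE)
    flicker <- center_surround(fpyr, centers, deltas, dims)

    dirs <- list(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
    mpyrs <- lapply(dirs, function(d) {
      mapply(function(a, b) {
        abs(a * shift_img(b, d[1], d[2]) - b * shift_img(a, d[1], d[2]))
      }, pL, pLp, SIMPLIFY = FALSE)
    })
    motion <- center_surround(mpyrs, centers, deltas, dims)
  }
  list(intensity = intensity, colour = colour, orientation = orientation,
       flicker = flicker, motion = motion)
}

frame_rms <- function(map) sqrt(mean(map^2))

#' Per-second RMS of conspicuity maps
#'
#' For each frame, the root mean square over pixels of each channel map;
#' per second, the mean of the frame RMS values within \[t, t+1).
#'
#' @param maps List (one element per frame) of named map lists as returned
#'   by [conspicuity_maps()].
#' @param frame_rate Frames per second (>= 1).
#' @return Data.frame: `t_s` plus one column per channel.
#' @export
channel_rms_per_second <- function(maps, frame_rate) {
  stopifnot(frame_rate >= 1, length(maps) >= 1)
  channels <- names(maps[[1]])
  per_frame <- t(vapply(maps, function(m) vapply(m, frame_rms, numeric(1)),
                        numeric(length(channels))))
  sec <- floor((seq_along(maps) - 1) / frame_rate)
  keep <- sec < floor(length(maps) / frame_rate)
  agg <- apply(per_frame[keep, , drop = FALSE], 2,
               function(col) tapply(col, sec[keep], mean))
  agg <- matrix(agg, ncol = length(channels),
                dimnames = list(NULL, channels))
  data.frame(t_s = sort(unique(sec[keep])), agg)
}

#' Per-second RMS volume of an audio waveform
#'
#' sqrt(mean(x^2)) over the samples in each second bin \[t, t+1); stereo is
#' averaged to mono first. A proxy for loudness / auditory salience.
#'
#' @param waveform Numeric vector (mono) or matrix (one column per
#'   channel).
#' @param sample_rate Samples per second.
#' @return Data.frame: `t_s`, `rms_volume` (one row per whole second).
#' @export
#' @examples
#' sr <- 1000
#' w <- 0.5 * sin(2 * pi * 100 * seq(0, 3 - 1 / sr, by = 1 / sr))
#' audio_rms_per_second(w, sr)$rms_volume  # ~0.5 / sqrt(2) each second
audio_rms_per_second <- function(waveform, sample_rate) {
  if (!is.null(dim(waveform))) waveform <- rowMeans(waveform)
  n_sec <- floor(length(waveform) / sample_rate)
  if (n_sec < 1) stop("waveform shorter than one second")
  idx <- seq_len(n_sec * sample_rate)
  sec <- floor((idx - 1) / sample_rate)
  rms <- as.numeric(tapply(waveform[idx]^2, sec, function(v) sqrt(mean(v))))
  data.frame(t_s = 0:(n_sec - 1), rms_volume = rms)
}

#' Full per-second feature table for a stimulus
#'
#' Runs [conspicuity_maps()] over every frame and [audio_rms_per_second()]
#' over the soundtrack, and joins the results into the canonical
#' FeatureTable used by the modeling stage.
#'
#' @param frames List of RGB arrays (`h x w x 3`, values in \[0, 1\]).
#' @param frame_rate Frames per second.
#' @param waveform,audio_rate Soundtrack and its sample rate (optional; the
#'   `rms_volume` column is omitted when absent).
#' @param ... Passed to [conspicuity_maps()].
#' @return Data.frame with `t_s`, the five channel columns, and
#'   `rms_volume` when audio is given.
#' @export
stimulus_features <- function(frames, frame_rate, waveform = NULL,
                              audio_rate = NULL, ...) {
  maps <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    prev <- if (i > 1) frames[[i - 1]] else NULL
    maps[[i]] <- conspicuity_maps(frames[[i]], prev, ...)
  }
  vis <- channel_rms_per_second(maps, frame_rate)
  if (is.null(waveform)) return(vis)
  aud <- audio_rms_per_second(waveform, audio_rate)
  merge(vis, aud, by = "t_s")
}

#' Write / read a feature table as delimited text
#'
#' @param features Data.frame keyed by `t_s`.
#' @param path File path (tab-separated).
#' @return `path` (write) or the data.frame (read).
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
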