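# Independent brute-force reference implementations. Deliberately naive
# (explicit loops, stats::cor) so they share no code with the package's
# rolling-sum / C++ paths.

oracle_windowed_r <- function(x, y, window = 15, step = 1) {
  starts <- seq(1, length(x) - window + 1, by = step)
  vapply(starts, function(t0) {
    xs <- x[t0:(t0 + window - 1)]
    ys <- y[t0:(t0 + window - 1)]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
}

# participant ISC by triple loop: pair windows -> pair mean -> row median
oracle_participant_isc <- function(values_list, ids, pair_set, window = 15) {
  pair_scalar <- setNames(
    vapply(seq_len(nrow(pair_set)), function(k) {
      r <- oracle_windowed_r(values_list[[match(pair_set$id_i[k], ids)]],
                             values_list[[match(pair_set$id_j[k], ids)]],
                             window)
      mean(r[!is.na(r)])
    }, numeric(1)),
    paste(pair_set$id_i, pair_set$id_j))
  vapply(ids, function(id) {
    sel <- pair_set$id_i == id | pair_set$id_j == id
    if (!any(sel)) return(NA_real_)
    stats::median(pair_scalar[sel])
  }, numeric(1))
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= (seq_len(n)) * q / n)
  k <- if (length(below)) max(below) else 0
  dec <- rep(FALSE, n)
  if (k > 0) dec[o[seq_len(k)]] <- TRUE
  dec
}

# Welch statistic from the textbook formula
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df)
}

# step-function heart rate integrated over 1 s bins on a fine grid
oracle_rr_hr <- function(peaks, duration_s, dt = 1 / 2000) {
  tt <- seq(0, duration_s - dt, by = dt) + dt / 2
  rate <- rep(NA_real_, length(tt))
  for (k in seq_len(length(peaks) - 1)) {
    sel <- tt >= peaks[k] & tt < peaks[k + 1]
    rate[sel] <- 60 / (peaks[k + 1] - peaks[k])
  }
  bins <- floor(tt)
  out <- vapply(0:(duration_s - 1), function(b) {
    v <- rate[bins == b]
    mean(v[!is.na(v)])
  }, numeric(1))
  # edge bins carry the nearest defined value
  if (anyNA(out)) {
    def <- which(!is.na(out))
    out[seq_len(def[1] - 1)] <- out[def[1]]
    last <- def[length(def)]
    if (last < length(out)) out[(last + 1):length(out)] <- out[last]
  }
  out
}

values_of <- function(series) lapply(series, function(s) s$values)
ids_of <- function(series) vapply(series, function(s) s$participant_id,
                                  character(1))

small_audience <- function(n = 4, dur = 60, seed = 1, lambda = 0.5, ...) {
  generate_audience(audience_spec(n_subjects_per_group = n, duration_s = dur,
                                  shared_loading = lambda, seed = seed,
                                  artifact_rate = 0, ...))
}
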