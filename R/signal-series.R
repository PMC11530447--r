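#' A uniformly sampled physiological signal for one participant
#'
#' `signal_series()` is the package's basic container: one participant's
#' uniformly sampled recording together with the metadata every downstream
#' stage needs (who, which stimulus-modality group, which physiological
#' channel, at what rate, aligned how).
#'
#' @param values Numeric vector of samples. Units depend on `signal_kind`:
#'   beats per minute for `"heart_rate"`, microsiemens or z-units for
#'   `"skin_conductance"`, g-units (1 g = 9.81 m/s^2) for `"movement"`.
#' @param participant_id Character scalar identifying the participant.
#' @param group Stimulus-modality group: `"audio"`, `"visual"` or
#'   `"audiovisual"`.
#' @param signal_kind One of `"heart_rate"`, `"skin_conductance"`,
#'   `"movement"`.
#' @param sample_rate_hz Sampling rate in Hz (default 1, the canonical
#'   post-preprocessing rate).
#' @param t0_s Time of the first sample in seconds from stimulus onset.
#'
#' @return An object of class `"signal_series"`: a list with the fields
#'   above.
#' @export
#' @examples
#' s <- signal_series(rnorm(60, 70, 2), "p01", "audio", "heart_rate")
#' print(s)
signal_series <- function(values, participant_id, group = "audiovisual",
                          signal_kind = c("heart_rate", "skin_conductance",
                                          "movement"),
                          sample_rate_hz = 1, t0_s = 0) {
  signal_kind <- match.arg(signal_kind)
  group <- match.arg(group, c("audio", "visual", "audiovisual"))
  stopifnot(is.numeric(values), length(values) >= 1,
            is.character(participant_id), length(participant_id) == 1,
            is.numeric(sample_rate_hz), sample_rate_hz > 0)
  structure(
    list(participant_id = participant_id,
         group = group,
         signal_kind = signal_kind,
         sample_rate_hz = as.numeric(sample_rate_hz),
         t0_s = as.numeric(t0_s),
         values = as.numeric(values)),
    class = "signal_series")
}

#' @export
print.signal_series <- function(x, ...) {
  cat(sprintf("<signal_series> %s [%s, %s] %d samples @ %g Hz, t0 = %g s\n",
              x$participant_id, x$group, x$signal_kind,
              length(x$values), x$sample_rate_hz, x$t0_s))
  cat(sprintf("  range [%.3g, %.3g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
length.signal_series <- function(x) length(x$values)

#' @export
as.data.frame.signal_series <- function(x, ...) {
  data.frame(participant_id = x$participant_id,
             group = x$group,
             signal_kind = x$signal_kind,
             t_s = x$t0_s + seq_along(x$values) - 1L,
             value = x$values,
             stringsAsFactors = FALSE)
}

is_signal_series <- function(x) inherits(x, "signal_series")

# Assert a homogeneous list of 1 Hz series sharing a common span; returns the
# common length.
check_series_list <- function(series) {
  stopifnot(is.list(series), length(series) >= 1,
            all(vapply(series, is_signal_series, logical(1))))
  rates <- vapply(series, function(s) s$sample_rate_hz, numeric(1))
  if (length(unique(rates)) != 1L)
    stop("all series must share one sample rate")
  lens <- vapply(series, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all series must share a common time span (equal lengths)")
  lens[1]
}

#' Write 1 Hz signal series to the canonical delimited table
#'
#' Long format with columns `participant_id`, `group`, `signal_kind`, `t_s`
#' (integer seconds from stimulus onset, 0-based) and `value`.
#'
#' @param series A `signal_series` or a list of them.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(series, path) {
  if (is_signal_series(series)) series <- list(series)
  tab <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read signal series from the canonical delimited table
#'
#' @param path A tab-separated file as written by [write_signal_table()].
#' @return A list of `signal_series`, one per participant x signal kind.
#' @export
read_signal_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "signal_kind", "t_s", "value")
  if (!all(need %in% names(tab)))
    stop("signal table must have columns: ", paste(need, collapse = ", "))
  keys <- interaction(tab$participant_id, tab$signal_kind, drop = TRUE)
  out <- lapply(split(tab, keys), function(d) {
    d <- d[order(d$t_s), ]
    signal_series(d$value, d$participant_id[1], d$group[1], d$signal_kind[1],
                  sample_rate_hz = 1, t0_s = d$t_s[1])
  })
  unname(out)
}

#' Read R-peak event times from a text file
#'
#' One event time (seconds from stimulus onset) per line, ascending.
#'
#' @param path File path.
#' @return Numeric vector of strictly increasing peak times.
#' @export
read_rpeaks <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  if (any(diff(x) <= 0)) stop("R-peak times must be strictly increasing")
  x
}
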