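#' Generate a synthetic interval-probed rating cohort
#'
#' Emulates the continuous-immersion paradigm: every `probe_interval_s`
#' seconds a probe tone sounds and each rater reports agreement with
#' "I feel very immersed" on a 1-7 scale. Each rater's latent response is
#' the (standardized) immersion signal summarized over the trailing probe
#' bin, plus rater-specific Gaussian noise, mapped onto the 7-point scale
#' and discretized. A stated fraction of responses are missing, and a
#' stated fraction carry a slow reaction time (> 5 s), so the downstream
#' exclusion rules have known targets.
#'
#' Under this model the expected correlation between two raters'
#' (pre-discretization) series is 1 / (1 + noise_sd^2).
#'
#' @param n_raters Number of raters.
#' @param duration_s Stimulus length, a multiple of `probe_interval_s`.
#' @param probe_interval_s Seconds between probes (default 30).
#' @param immersion_signal Numeric vector of length `duration_s`: the
#'   ground-truth immersion time course.
#' @param noise_sd Rater noise SD on the standardized latent scale.
#' @param missing_rate Probability a response is missing; scalar or one
#'   value per rater.
#' @param slow_rt_rate Probability a given response has reaction time
#'   above 5 s.
#' @param seed Integer seed.
#' @param probe_summary `"mean"` (default): the latent value at probe p
#'   summarizes the trailing bin \[p - interval, p); `"instant"`: the
#'   signal value at second p.
#' @param discretize Round and clamp to the integer 1-7 scale (default
#'   `TRUE`).
#' @return A data.frame of class `"rating_table"`: `rater_id`, `probe_t_s`,
#'   `rating`, `rt_s`.
#' @export
generate_rating_cohort <- function(n_raters, duration_s,
                                   probe_interval_s = 30,
                                   immersion_signal, noise_sd = 1,
                                   missing_rate = 0, slow_rt_rate = 0,
                                   seed = 1L,
                                   probe_summary = c("mean", "instant"),
                                   discretize = TRUE) {
  probe_summary <- match.arg(probe_summary)
  stopifnot(n_raters >= 1, duration_s %% probe_interval_s == 0,
            length(immersion_signal) == duration_s, noise_sd >= 0)
  if (length(missing_rate) == 1) missing_rate <- rep(missing_rate, n_raters)
  stopifnot(length(missing_rate) == n_raters,
            all(missing_rate >= 0 & missing_rate < 1))
  set.seed(seed)
  probes <- seq(probe_interval_s, duration_s, by = probe_interval_s)
  latent <- vapply(probes, function(p) {
    if (probe_summary == "mean")
      mean(immersion_signal[(p - probe_interval_s + 1):p])
    else immersion_signal[p]
  }, numeric(1))
  if (stats::sd(latent) > 0) latent <- as.numeric(scale(latent))
  else latent <- latent - mean(latent)

  rows <- lapply(seq_len(n_raters), function(r) {
    z <- latent + stats::rnorm(length(probes), 0, noise_sd)
    rating <- 4 + z
    if (discretize) rating <- pmin(pmax(round(rating), 1), 7)
    rt <- stats::runif(length(probes), 0.5, 3)
    slow <- stats::runif(length(probes)) < slow_rt_rate
    rt[slow] <- stats::runif(sum(slow), 5.05, 9)
    rating[stats::runif(length(probes)) < missing_rate[r]] <- NA
    data.frame(rater_id = sprintf("r%03d", r), probe_t_s = probes,
               rating = rating, rt_s = rt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rating_table", "data.frame")
  out
}

#' Write / read a rating table as delimited text
#'
#' Columns `rater_id`, `probe_t_s`, `rating`, `rt_s`, tab-separated.
#'
#' @param table A rating table data.frame.
#' @param path File path.
#' @return `path` (write) or the rating table (read).
#' @export
write_rating_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_rating_table
#' @export
read_rating_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("rater_id", "probe_t_s", "rating", "rt_s")
  if (!all(need %in% names(out)))
    stop("rating table must have columns: ", paste(need, collapse = ", "))
  class(out) <- c("rating_table", "data.frame")
  out
}
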