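#' Clean an interval-probed rating table
#'
#' Applies the exclusion rules for probed ratings: responses with a
#' reaction time over `rt_max` seconds are set missing, and raters whose
#' overall missing fraction (after the RT exclusion) exceeds `missing_max`
#' are dropped entirely.
#'
#' @param table A rating table (`rater_id`, `probe_t_s`, `rating`, `rt_s`).
#' @param rt_max Reaction-time cutoff in seconds (default 5).
#' @param missing_max Maximum tolerated missing fraction per rater
#'   (default 0.20).
#' @return The cleaned table, with attribute `"exclusions"`: a list with
#'   `n_slow_rt` (responses blanked), `dropped_raters`, `n_retained`.
#' @export
clean_ratings <- function(table, rt_max = 5, missing_max = 0.20) {
  stopifnot(all(c("rater_id", "probe_t_s", "rating", "rt_s") %in%
                  names(table)))
  slow <- !is.na(table$rt_s) & table$rt_s > rt_max & !is.na(table$rating)
  table$rating[slow] <- NA
  miss_frac <- tapply(is.na(table$rating), table$rater_id, mean)
  dropped <- names(miss_frac)[miss_frac > missing_max]
  out <- table[!(table$rater_id %in% dropped), , drop = FALSE]
  if (!nrow(out)) stop("all raters excluded by the missingness rule")
  rownames(out) <- NULL
  class(out) <- c("rating_table", "data.frame")
  attr(out, "exclusions") <- list(
    n_slow_rt = sum(slow), dropped_raters = dropped,
    n_retained = length(unique(out$rater_id)))
  out
}

rating_matrix <- function(table) {
  probes <- sort(unique(table$probe_t_s))
  raters <- sort(unique(table$rater_id))
  M <- matrix(NA_real_, length(probes), length(raters),
              dimnames = list(probes, raters))
  M[cbind(match(table$probe_t_s, probes), match(table$rater_id, raters))] <-
    table$rating
  M
}

#' Inter-rater reliability of probed ratings
#'
#' Mean over all rater pairs of the Pearson correlation between their
#' rating time series (pairwise-complete probes). Pairs sharing fewer than
#' 3 probes, or with zero variance on the shared probes, are skipped.
#'
#' @param table A (cleaned) rating table with >= 2 raters.
#' @param method `"pairwise"` (default) or `"pooled"`: the pooled variant
#'   correlates each rater's series with the mean of the others',
#'   long-format.
#' @return The mean correlation (numeric scalar), with attribute
#'   `"n_pairs"`.
#' @export
rating_reliability <- function(table, method = c("pairwise", "pooled")) {
  method <- match.arg(method)
  M <- rating_matrix(table)
  if (ncol(M) < 2) stop("need at least 2 retained raters")
  if (method == "pooled") {
    rs <- vapply(seq_len(ncol(M)), function(j) {
      others <- rowMeans(M[, -j, drop = FALSE], na.rm = TRUE)
      ok <- !is.na(M[, j]) & !is.na(others)
      if (sum(ok) < 3) return(NA_real_)
      suppressWarnings(stats::cor(M[ok, j], others[ok]))
    }, numeric(1))
    out <- mean(rs, na.rm = TRUE)
    attr(out, "n_pairs") <- sum(!is.na(rs))
    return(out)
  }
  pairs <- utils::combn(ncol(M), 2)
  rs <- apply(pairs, 2, function(ij) {
    ok <- !is.na(M[, ij[1]]) & !is.na(M[, ij[2]])
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(stats::cor(M[ok, ij[1]], M[ok, ij[2]]))
  })
  out <- mean(rs, na.rm = TRUE)
  attr(out, "n_pairs") <- sum(!is.na(rs))
  out
}

#' Correlate an ISC time course with probed immersion ratings
#'
#' The ISC time course is averaged within each probe's trailing bin
#' \[p - interval, p) (the rating reflects the just-experienced content;
#' `bin = "centered"` uses \[p - interval/2, p + interval/2) instead), and
#' Pearson-correlated with the across-rater mean rating over probes.
#'
#' @param isc_tc Data.frame `t_s`, `isc` (window-start-indexed ISC time
#'   course, as from [isc_timecourse()]).
#' @param table A (cleaned) rating table.
#' @param bin `"trailing"` (default) or `"centered"`.
#' @return List: `r`, `p` (two-sided), `n_probes`, `binned` (data.frame
#'   `probe_t_s`, `isc`, `rating`). `r` is `NA` with a message when either
#'   side has zero variance.
#' @export
correlate_isc_ratings <- function(isc_tc, table,
                                  bin = c("trailing", "centered")) {
  bin <- match.arg(bin)
  probes <- sort(unique(table$probe_t_s))
  if (length(probes) < 2) stop("need at least 2 probes")
  interval <- min(diff(probes))
  mean_rating <- tapply(table$rating, table$probe_t_s,
                        function(v) mean(v, na.rm = TRUE))
  mean_rating <- as.numeric(mean_rating[as.character(probes)])
  binned_isc <- vapply(probes, function(p) {
    lo <- if (bin == "trailing") p - interval else p - interval / 2
    hi <- if (bin == "trailing") p else p + interval / 2
    sel <- isc_tc$t_s >= lo & isc_tc$t_s < hi
    if (!any(sel)) return(NA_real_)
    mean(isc_tc$isc[sel], na.rm = TRUE)
  }, numeric(1))
  ok <- !is.na(binned_isc) & !is.na(mean_rating)
  if (sum(ok) < 3) stop("fewer than 3 usable probes")
  binned <- data.frame(probe_t_s = probes[ok], isc = binned_isc[ok],
                       rating = mean_rating[ok])
  if (stats::sd(binned$rating) == 0 || stats::sd(binned$isc) == 0) {
    message("zero variance on one side: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n_probes = nrow(binned),
                binned = binned))
  }
  ct <- stats::cor.test(binned$isc, binned$rating)
  list(r = unname(ct$estimate), p = ct$p.value, n_probes = nrow(binned),
       binned = binned)
}

#' Detect high-synchrony peaks in an ISC time course
#'
#' Maximal runs of consecutive seconds where the ISC exceeds
#' mean + k * SD (mean and SD over the whole time course) — the moments an
#' audience is most strongly in sync.
#'
#' @param isc_tc Data.frame `t_s`, `isc`.
#' @param k Threshold in SD units (default 3).
#' @return Data.frame `start_s`, `end_s`, `peak_isc` (one row per run;
#'   zero rows when nothing exceeds the threshold).
#' @export
detect_peaks <- function(isc_tc, k = 3) {
  stopifnot(nrow(isc_tc) >= 30)
  v <- isc_tc$isc
  ok <- !is.na(v)
  thr <- mean(v[ok]) + k * stats::sd(v[ok])
  above <- ok & v > thr
  if (!any(above))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_isc = numeric(0)))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- which(runs$values)
  data.frame(start_s = isc_tc$t_s[starts[sel]],
             end_s = isc_tc$t_s[ends[sel]],
             peak_isc = vapply(sel, function(j)
               max(v[starts[j]:ends[j]]), numeric(1)))
}
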