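#' Enumerate between-group participant pairs
#'
#' Between-group (narrative) ISC correlates each participant only with
#' participants who received the other sensory modality of the same content,
#' isolating synchrony attributable to shared story processing.
#'
#' @param ids_a,ids_b Character vectors of participant ids, disjoint.
#' @return A data.frame with columns `id_i`, `id_j`, one row per pair.
#' @export
#' @examples
#' nrow(between_group_pairs(sprintf("a%d", 1:30), sprintf("v%d", 1:30))) # 900
between_group_pairs <- function(ids_a, ids_b) {
  if (length(intersect(ids_a, ids_b)))
    stop("groups overlap: ", paste(intersect(ids_a, ids_b), collapse = ", "))
  if (!length(ids_a) || !length(ids_b)) stop("both groups must be non-empty")
  expand.grid(id_i = ids_a, id_j = ids_b, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Enumerate within-group participant pairs
#'
#' All C(n, 2) unordered pairs within one group.
#'
#' @param ids Character vector of participant ids.
#' @return A data.frame with columns `id_i`, `id_j`.
#' @export
within_group_pairs <- function(ids) {
  if (length(ids) < 2) stop("need at least 2 participants")
  if (anyDuplicated(ids)) stop("duplicated participant ids")
  idx <- utils::combn(length(ids), 2)
  data.frame(id_i = ids[idx[1, ]], id_j = ids[idx[2, ]],
             stringsAsFactors = FALSE)
}

# Rolling-window sums of x over windows of length w (starts 1..n-w+1),
# via prefix sums; inputs are demeaned upstream so cancellation is benign.
roll_sum <- function(x, w) {
  cs <- cumsum(x)
  cs[w:length(x)] - c(0, cs[seq_len(length(x) - w)])
}

# Windowed Pearson r between two equal-length vectors for all window starts.
# Windows where either side has (near-)zero variance are NA.
windowed_r <- function(x, y, w) {
  x <- x - mean(x); y <- y - mean(y)
  sx <- roll_sum(x, w);  sy <- roll_sum(y, w)
  sxx <- roll_sum(x * x, w); syy <- roll_sum(y * y, w)
  sxy <- roll_sum(x * y, w)
  vx <- sxx - sx^2 / w
  vy <- syy - sy^2 / w
  eps <- 1e-12 * w
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- (sxy - sx * sy / w) / den
  r[vx <= eps | vy <= eps] <- NA_real_
  pmin(pmax(r, -1), 1)
}

#' Sliding-window pairwise inter-subject correlations
#'
#' For every pair in `pair_set`, computes the Pearson correlation over a
#' rolling window (default 15 s, shifted at 1 s steps) across the common
#' time span. Windows in which either participant's signal has zero
#' variance are undefined (NA) and are excluded from all downstream
#' medians.
#'
#' @param series List of 1 Hz [signal_series()] sharing a common span.
#' @param pair_set Data.frame with columns `id_i`, `id_j` (see
#'   [between_group_pairs()], [within_group_pairs()]).
#' @param window Window length in seconds (default 15).
#' @param step Window step in seconds (default 1).
#' @return An object of class `"pair_windows"`: list with `r` (pairs x
#'   windows matrix), `pairs` (the pair table), `window_starts_s`, `window`,
#'   `participants`.
#' @export
windowed_pairwise_isc <- function(series, pair_set, window = 15, step = 1) {
  n <- check_series_list(series)
  stopifnot(window >= 2, step >= 1, nrow(pair_set) >= 1)
  if (n < window)
    stop("common span (", n, " s) shorter than the ", window, " s window")
  ids <- vapply(series, function(s) s$participant_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated participant ids in series")
  miss <- setdiff(unique(c(pair_set$id_i, pair_set$id_j)), ids)
  if (length(miss))
    stop("pair_set names unknown participants: ", paste(miss, collapse = ", "))

  X <- vapply(series, function(s) s$values, numeric(n))
  colnames(X) <- ids
  starts <- seq(1L, n - window + 1L, by = step)
  R <- matrix(NA_real_, nrow(pair_set), length(starts))
  for (k in seq_len(nrow(pair_set))) {
    r <- windowed_r(X[, pair_set$id_i[k]], X[, pair_set$id_j[k]], window)
    R[k, ] <- r[starts]
  }
  t0 <- series[[1]]$t0_s
  structure(list(r = R, pairs = pair_set,
                 window_starts_s = t0 + starts - 1L,
                 window = window, step = step,
                 participants = ids),
            class = "pair_windows")
}

#' @export
print.pair_windows <- function(x, ...) {
  cat(sprintf("<pair_windows> %d pairs x %d windows (%d s window, %d s step)\n",
              nrow(x$r), ncol(x$r), x$window, x$step))
  cat(sprintf("  defined windows: %.1f%%; r range [%.3f, %.3f]\n",
              100 * mean(!is.na(x$r)),
              min(x$r, na.rm = TRUE), max(x$r, na.rm = TRUE)))
  invisible(x)
}

# Collapse one pair's window correlations to a scalar.
collapse_pair <- function(r, agg) {
  r <- r[!is.na(r)]
  if (!length(r)) return(NA_real_)
  switch(agg,
         mean = mean(r),
         median = stats::median(r),
         fisherz = tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)))))
}

#' Participant-level ISC summaries
#'
#' Each pair's windowed correlations are first collapsed to a scalar (the
#' arithmetic mean of its defined windows by default), giving a symmetric
#' participant-by-participant matrix; each participant's ISC is then the
#' median of their row — the row-median is robust to the skew of pairwise
#' correlation values.
#'
#' @param pairs A `"pair_windows"` object from [windowed_pairwise_isc()].
#' @param agg Per-pair collapse: `"mean"` (default), `"median"` or
#'   `"fisherz"`.
#' @return List with `matrix` (participants x participants, diagonal NA)
#'   and `participant` (data.frame: `participant_id`, `isc`, `n_pairs`).
#' @export
participant_isc <- function(pairs, agg = c("mean", "median", "fisherz")) {
  stopifnot(inherits(pairs, "pair_windows"))
  agg <- match.arg(agg)
  ids <- sort(unique(c(pairs$pairs$id_i, pairs$pairs$id_j)))
  M <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(pairs$pairs))) {
    v <- collapse_pair(pairs$r[k, ], agg)
    M[pairs$pairs$id_i[k], pairs$pairs$id_j[k]] <- v
    M[pairs$pairs$id_j[k], pairs$pairs$id_i[k]] <- v
  }
  isc <- apply(M, 1, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) NA_real_ else stats::median(row)
  })
  undef <- names(isc)[is.na(isc)]
  if (length(undef))
    warning("participants with no defined pairs: ",
            paste(undef, collapse = ", "))
  list(matrix = M,
       participant = data.frame(participant_id = ids,
                                isc = unname(isc),
                                n_pairs = rowSums(!is.na(M)),
                                stringsAsFactors = FALSE,
                                row.names = NULL))
}

#' Median ISC time course
#'
#' For each rolling window, the median correlation across all defined
#' pairs.
#'
#' @param pairs A `"pair_windows"` object.
#' @return Data.frame with columns `t_s` (window start second) and `isc`.
#' @export
isc_timecourse <- function(pairs) {
  stopifnot(inherits(pairs, "pair_windows"))
  med <- apply(pairs$r, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) NA_real_ else stats::median(col)
  })
  data.frame(t_s = pairs$window_starts_s, isc = med)
}

#' Inter-subject correlation analysis of an audience
#'
#' The package's central estimator. Given a list of 1 Hz physiological
#' series carrying group labels, computes sliding-window pairwise
#' correlations under the requested design, per-participant ISC summaries,
#' the median time course, and the group-level one-tailed t-test against
#' zero.
#'
#' @param series List of [signal_series()] sharing a common 1 Hz span.
#' @param design `"between"` (cross-modality, narrative) or `"within"`
#'   (pairs inside one group; requires `group` when several are present).
#' @param group For `design = "within"`, which group to analyse.
#' @param window,step Rolling-window length and shift, seconds.
#' @param agg Per-pair collapse passed to [participant_isc()].
#' @return An object of class `"isc"`; see [print.isc()], [summary.isc()],
#'   [coef.isc()], [plot.isc()].
#' @export
#' @examples
#' aud <- generate_audience(audience_spec(n_subjects_per_group = 5,
#'                                        duration_s = 120, seed = 1))
#' fit <- isc(aud$series, design = "between")
#' fit
#' head(coef(fit))
isc <- function(series, design = c("between", "within"), group = NULL,
                window = 15, step = 1,
                agg = c("mean", "median", "fisherz")) {
  design <- match.arg(design)
  agg <- match.arg(agg)
  check_series_list(series)
  ids <- vapply(series, function(s) s$participant_id, character(1))
  grp <- vapply(series, function(s) s$group, character(1))

  if (design == "between") {
    gs <- unique(grp)
    if (length(gs) != 2)
      stop("between-group design needs exactly 2 groups, found: ",
           paste(gs, collapse = ", "))
    pair_set <- between_group_pairs(ids[grp == gs[1]], ids[grp == gs[2]])
  } else {
    if (is.null(group)) {
      gs <- unique(grp)
      if (length(gs) != 1)
        stop("within-group design with several groups: give `group`")
      group <- gs
    }
    pair_set <- within_group_pairs(ids[grp == group])
    series <- series[grp == group]
  }
  pw <- windowed_pairwise_isc(series, pair_set, window, step)
  pisc <- participant_isc(pw, agg)
  tc <- isc_timecourse(pw)
  part <- merge(pisc$participant,
                data.frame(participant_id = ids, group = grp,
                           stringsAsFactors = FALSE),
                by = "participant_id", sort = TRUE)
  gt <- tryCatch(group_isc_test(part$isc[!is.na(part$isc)]),
                 error = function(e) NULL)
  structure(list(pair_windows = pw, matrix = pisc$matrix,
                 participant = part, timecourse = tc,
                 group_test = gt, design = design,
                 window = window, step = step, agg = agg,
                 call = match.call()),
            class = "isc")
}

#' @describeIn isc Compact display: design, mean participant ISC, group test.
#' @param x,object An `"isc"` object.
#' @param ... Unused.
#' @export
print.isc <- function(x, ...) {
  cat(sprintf("Inter-subject correlation (%s-group design)\n", x$design))
  cat(sprintf("  %d participants, %d pairs, %d windows (%d s window, %d s step, pair agg = %s)\n",
              nrow(x$participant), nrow(x$pair_windows$r),
              ncol(x$pair_windows$r), x$window, x$step, x$agg))
  cat(sprintf("  mean participant ISC r = %.4f (median %.4f)\n",
              mean(x$participant$isc, na.rm = TRUE),
              stats::median(x$participant$isc, na.rm = TRUE)))
  if (!is.null(x$group_test))
    cat(sprintf("  one-tailed t vs 0: t(%d) = %.2f, p = %.3g, d = %.2f (95%% CI %.2f, %.2f)\n",
                x$group_test$df, x$group_test$t, x$group_test$p,
                x$group_test$d, x$group_test$d_ci[1], x$group_test$d_ci[2]))
  invisible(x)
}

#' @describeIn isc Participant table plus group-level test.
#' @export
summary.isc <- function(object, ...) {
  out <- list(participant = object$participant,
              group_test = object$group_test,
              timecourse_range = range(object$timecourse$isc, na.rm = TRUE),
              design = object$design)
  class(out) <- "summary.isc"
  out
}

#' @export
print.summary.isc <- function(x, ...) {
  cat(sprintf("ISC summary (%s-group)\n", x$design))
  print(utils::head(x$participant, 10))
  if (nrow(x$participant) > 10)
    cat("  ... (", nrow(x$participant), "participants )\n")
  cat(sprintf("time course range: [%.3f, %.3f]\n",
              x$timecourse_range[1], x$timecourse_range[2]))
  if (!is.null(x$group_test))
    cat(sprintf("group test: t(%d) = %.2f, p = %.3g, d = %.2f\n",
                x$group_test$df, x$group_test$t, x$group_test$p,
                x$group_test$d))
  invisible(x)
}

#' @describeIn isc Named vector of per-participant ISC values.
#' @export
coef.isc <- function(object, ...) {
  stats::setNames(object$participant$isc, object$participant$participant_id)
}

#' @describeIn isc Two-panel base-graphics display: per-participant ISC by
#'   group, and the median ISC time course.
#' @export
plot.isc <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::boxplot(isc ~ group, data = x$participant,
                    ylab = "participant ISC (r)", xlab = "",
                    main = sprintf("%s-group ISC", x$design))
  graphics::abline(h = 0, lty = 2)
  graphics::plot(x$timecourse$t_s, x$timecourse$isc, type = "l",
                 xlab = "time (s)", ylab = "median windowed r",
                 main = "ISC time course")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
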