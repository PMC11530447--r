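#' Circularly shift a time series
#'
#' Rotates the series forward by `offset` samples, wrapping the tail to the
#' front. Circular shifting preserves the series' autocorrelation structure
#' (up to wraparound) while destroying its alignment with the stimulus,
#' which makes it the natural permutation scheme for ISC nulls.
#'
#' @param values Numeric vector.
#' @param offset Integer shift, `0 <= offset < length(values)` (taken
#'   modulo the length).
#' @return The rotated vector.
#' @export
#' @examples
#' circular_shift(1:4, 1)  # 4 1 2 3
circular_shift <- function(values, offset) {
  n <- length(values)
  off <- as.integer(offset) %% n
  if (off == 0) return(values)
  c(values[(n - off + 1):n], values[seq_len(n - off)])
}

#' Circular-shuffle permutation test for one participant's ISC
#'
#' The target's series is circularly shifted by a random offset `n_iter`
#' times; after each shift the participant's ISC (median over partners of
#' the mean windowed correlation) is recomputed against the unshifted
#' partners, building a null distribution that shares the autoregressive
#' structure of the data. Offsets are drawn uniformly from
#' `[window, length - window]` so a shifted series never nearly re-aligns
#' with itself. The p-value uses the add-one exceedance convention
#' p = (1 + #\{null >= observed\}) / (1 + n_iter), so it is never exactly 0.
#'
#' @param target A [signal_series()] (the participant under test).
#' @param partners List of [signal_series()] the target is correlated with.
#' @param n_iter Number of shuffle iterations (>= 100; 10,000 in full runs,
#'   a few hundred suffices for testing).
#' @param window Rolling-window length, seconds (default 15).
#' @param rng_seed Optional integer seed for the offset draws.
#' @return An object of class `"perm_result"`: list with `participant_id`,
#'   `observed_isc`, `null_iscs`, `p_value`, `n_iter`.
#' @export
participant_permutation_test <- function(target, partners, n_iter = 10000,
                                         window = 15, rng_seed = NULL) {
  stopifnot(is_signal_series(target), n_iter >= 100)
  n <- check_series_list(c(list(target), partners))
  if (n < 2 * window)
    stop("series shorter than twice the window: no room for shift offsets")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  Y <- vapply(partners, function(s) s$values, numeric(n))
  offsets <- sample(window:(n - window), n_iter, replace = TRUE)
  observed <- perm_isc_null_cpp(target$values, Y, 0L, window)
  nulls <- perm_isc_null_cpp(target$values, Y, as.integer(offsets), window)
  p <- (1 + sum(nulls >= observed)) / (1 + n_iter)
  structure(list(participant_id = target$participant_id,
                 observed_isc = observed, null_iscs = nulls,
                 p_value = p, n_iter = n_iter),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s: observed ISC %.4f, p = %.4g (%d shuffles)\n",
              x$participant_id, x$observed_isc, x$p_value, x$n_iter))
  invisible(x)
}

#' Cohort-level circular-shuffle significance with FDR control
#'
#' Runs [participant_permutation_test()] for every participant (between- or
#' within-group partner sets) and applies Benjamini-Hochberg FDR at level
#' `q` across participants, mirroring the per-participant significance
#' marks of an ISC audience analysis.
#'
#' @param series List of [signal_series()] with group labels.
#' @param design `"between"` or `"within"` (as in [isc()]).
#' @param n_iter Shuffle iterations per participant.
#' @param q FDR level (default 0.05).
#' @param window Rolling-window length, seconds.
#' @param seed Integer seed governing all offset draws.
#' @return An object of class `"isc_perm"`: data.frame with columns
#'   `participant_id`, `group`, `observed_isc`, `p_value`, `significant`.
#' @export
cohort_permutation_test <- function(series, design = c("between", "within"),
                                    n_iter = 10000, q = 0.05, window = 15,
                                    seed = 1L) {
  design <- match.arg(design)
  n <- check_series_list(series)
  ids <- vapply(series, function(s) s$participant_id, character(1))
  grp <- vapply(series, function(s) s$group, character(1))
  set.seed(seed)
  res <- vector("list", length(series))
  for (k in seq_along(series)) {
    partner_idx <- if (design == "between") which(grp != grp[k])
                   else which(grp == grp[k] & seq_along(series) != k)
    if (!length(partner_idx)) stop("participant ", ids[k], " has no partners")
    Y <- vapply(series[partner_idx], function(s) s$values, numeric(n))
    offsets <- sample(window:(n - window), n_iter, replace = TRUE)
    observed <- perm_isc_null_cpp(series[[k]]$values, Y, 0L, window)
    nulls <- perm_isc_null_cpp(series[[k]]$values, Y, as.integer(offsets),
                               window)
    res[[k]] <- data.frame(participant_id = ids[k], group = grp[k],
                           observed_isc = observed,
                           p_value = (1 + sum(nulls >= observed)) /
                             (1 + n_iter),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$significant <- bh_fdr(out$p_value, q)
  class(out) <- c("isc_perm", "data.frame")
  attr(out, "q") <- q
  attr(out, "n_iter") <- n_iter
  out
}

#' @export
print.isc_perm <- function(x, ...) {
  cat(sprintf("Circular-shuffle ISC significance: %d / %d participants at q = %g (%d shuffles)\n",
              sum(x$significant), nrow(x), attr(x, "q"), attr(x, "n_iter")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up decisions controlling the false discovery rate at level `q`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical vector: `TRUE` = rejected (significant).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values > 0 & p_values <= 1), q > 0, q < 1)
  stats::p.adjust(p_values, method = "BH") <= q
}

# 95% CI for Cohen's d by inverting the noncentral-t distribution of the
# observed statistic; scale_fn maps ncp back to d.
d_ci_noncentral <- function(t_obs, df, scale, level = 0.95) {
  a <- (1 - level) / 2
  # pt() warns about precision deep in the noncentral tail; harmless here
  f <- function(ncp, target)
    suppressWarnings(stats::pt(t_obs, df, ncp = ncp)) - target
  lim <- max(abs(t_obs) + 10, 20)
  lo <- tryCatch(stats::uniroot(f, c(-lim, lim), target = 1 - a)$root,
                 error = function(e) NA_real_)
  hi <- tryCatch(stats::uniroot(f, c(-lim, lim), target = a)$root,
                 error = function(e) NA_real_)
  c(lo, hi) * scale
}

#' Group-level one-tailed t-test of participant ISCs against zero
#'
#' Tests whether the distribution of per-participant ISC values exceeds
#' zero, the interpretable companion to the permutation test. Cohen's
#' d = mean/SD with a 95 percent CI from noncentral-t inversion.
#'
#' @param participant_iscs Numeric vector of per-participant ISC values.
#' @param tails 1 (default; H1: mean > 0) or 2.
#' @return List of class `"group_test"`: `mean_r`, `t`, `df`, `p`, `d`,
#'   `d_ci`, `n`.
#' @export
group_isc_test <- function(participant_iscs, tails = 1) {
  x <- participant_iscs[!is.na(participant_iscs)]
  n <- length(x)
  if (n < 3) stop("need at least 3 participants")
  s <- stats::sd(x)
  if (s == 0) {
    if (mean(x) != 0) stop("zero variance with nonzero mean: t undefined")
    out <- list(mean_r = 0, t = 0, df = n - 1L, p = if (tails == 1) 0.5 else 1,
                d = 0, d_ci = c(NA_real_, NA_real_), n = n)
    class(out) <- "group_test"
    return(out)
  }
  t_obs <- mean(x) / (s / sqrt(n))
  p <- if (tails == 1) stats::pt(t_obs, n - 1, lower.tail = FALSE)
       else 2 * stats::pt(abs(t_obs), n - 1, lower.tail = FALSE)
  out <- list(mean_r = mean(x), t = t_obs, df = n - 1L, p = p,
              d = mean(x) / s,
              d_ci = d_ci_noncentral(t_obs, n - 1, 1 / sqrt(n)),
              n = n)
  class(out) <- "group_test"
  out
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("mean r = %.4g, t(%.4g) = %.3f, p = %.3g, d (95%% CI) = %.2f (%.2f, %.2f)\n",
              x$mean_r, x$df, x$t, x$p, x$d, x$d_ci[1], x$d_ci[2]))
  invisible(x)
}

# Power of a t-test from the noncentral-t distribution.
t_power <- function(d, n, test, tails, alpha) {
  df <- switch(test, one_sample_t = n - 1, two_sample_t = 2 * n - 2,
               welch_t = 2 * n - 2)
  ncp <- switch(test, one_sample_t = d * sqrt(n),
                two_sample_t = d * sqrt(n / 2),
                welch_t = d * sqrt(n / 2))
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Power analysis for t-tests via the noncentral-t distribution
#'
#' Completes a power specification: exactly one of `d`, `power`, `n` must
#' be `NULL` and is solved for (bisection on the noncentral-t power
#' equation). `n` is per group for two-sample tests. Covers the usual
#' sensitivity questions: the minimal detectable effect at given n and
#' power, or the achieved power at given d and n.
#'
#' @param test `"one_sample_t"`, `"two_sample_t"` or `"welch_t"` (the last
#'   treated as the two-sample equal-n case for planning purposes).
#' @param tails 1 or 2.
#' @param alpha Significance level (default 0.05).
#' @param n Sample size (per group for two-sample), or `NULL` to solve.
#' @param d Cohen's d, or `NULL` to solve.
#' @param power Target power in (0, 1), or `NULL` to solve.
#' @return List of class `"power_spec"` with all five fields completed and
#'   `solved` naming the solved quantity.
#' @export
#' @examples
#' power_t("one_sample_t", tails = 1, n = 870, power = 0.95)$d   # ~0.11
#' power_t("two_sample_t", tails = 2, n = 30, d = 0.52)$power    # ~0.51
power_t <- function(test = c("one_sample_t", "two_sample_t", "welch_t"),
                    tails = 1, alpha = 0.05, n = NULL, d = NULL,
                    power = NULL) {
  test <- match.arg(test)
  stopifnot(tails %in% c(1, 2), alpha > 0, alpha < 1)
  unknown <- c(d = is.null(d), power = is.null(power), n = is.null(n))
  if (sum(unknown) != 1)
    stop("exactly one of d, power, n must be NULL (the solved-for unknown)")
  if (!is.null(power) && power <= alpha)
    stop("infeasible: requested power must exceed alpha")

  solved <- names(unknown)[unknown]
  if (solved == "power") {
    power <- t_power(d, n, test, tails, alpha)
  } else if (solved == "d") {
    f <- function(dd) t_power(dd, n, test, tails, alpha) - power
    d <- stats::uniroot(f, c(1e-8, 20), tol = 1e-10)$root
  } else {
    f <- function(nn) t_power(d, nn, test, tails, alpha) - power
    if (f(2) > 0) n <- 2
    else n <- stats::uniroot(f, c(2, 1e7), tol = 1e-8)$root
  }
  structure(list(test = test, tails = tails, alpha = alpha,
                 n = n, d = d, power = power, solved = solved),
            class = "power_spec")
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf("%s, %d-tailed, alpha = %g: n = %.4g, d = %.4g, power = %.4g  (solved: %s)\n",
              x$test, x$tails, x$alpha, x$n, x$d, x$power, x$solved))
  invisible(x)
}

#' Welch's two-sample t-test with Cohen's d
#'
#' Unequal-variance t-test (Satterthwaite df) for comparing two groups,
#' e.g. questionnaire scores across stimulus modalities, with a pooled-SD
#' Cohen's d and its noncentral-t 95 percent CI.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List of class `"group_test"`: `mean_r` (mean difference a - b),
#'   `t`, `df` (Satterthwaite, real-valued), `p` (two-sided), `d`, `d_ci`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
welch_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  ht <- stats::t.test(group_a, group_b)
  na <- length(group_a); nb <- length(group_b)
  sp <- sqrt(((na - 1) * stats::var(group_a) +
                (nb - 1) * stats::var(group_b)) / (na + nb - 2))
  d <- if (sp == 0) 0 else (mean(group_a) - mean(group_b)) / sp
  scale <- sqrt(1 / na + 1 / nb)
  ci <- if (sp == 0) c(NA_real_, NA_real_)
        else d_ci_noncentral(d / scale, na + nb - 2, scale)
  out <- list(mean_r = mean(group_a) - mean(group_b),
              t = unname(ht$statistic), df = unname(ht$parameter),
              p = ht$p.value, d = d, d_ci = ci,
              n = c(na, nb))
  class(out) <- "group_test"
  out
}
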