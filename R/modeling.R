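#' Condition-level mean heart-rate series
#'
#' Z-scores each participant's series over the full recording, then takes
#' the per-second mean across the condition's participants. Averaging
#' standardized subjects suppresses idiosyncratic fluctuation and lifts
#' the stimulus-locked component, giving the single per-condition series
#' the nested-model comparison consumes.
#'
#' @param series List of [signal_series()] from one condition (>= 2,
#'   aligned).
#' @return Data.frame `t_s`, `hr` (standardized condition mean).
#' @export
condition_mean_hr <- function(series) {
  if (!length(series)) stop("empty condition")
  n <- check_series_list(series)
  if (length(series) < 2) stop("need at least 2 participants")
  Z <- vapply(series, function(s) standardize(s)$values, numeric(n))
  data.frame(t_s = series[[1]]$t0_s + seq_len(n) - 1, hr = rowMeans(Z))
}

# Gaussian profile BIC with k = coefficients (incl. intercept) + 1 for the
# error variance, matching the df convention of the nested comparison
# (null model: intercept + seconds + variance = 3).
bic_gaussian <- function(fit) {
  n <- length(fit$residuals)
  rss <- sum(fit$residuals^2)
  k <- length(stats::coef(fit)) + 1
  n * log(rss / n) + k * log(n)
}

#' Nested regression comparison: narrative vs low-level predictors
#'
#' Fits three nested OLS models of one condition's heart-rate series:
#' \describe{
#'   \item{null}{`hr ~ seconds` — a linear trend of time only.}
#'   \item{narrative}{adds the other condition's heart rate, the proxy for
#'     shared story processing (the two audiences share only the
#'     narrative).}
#'   \item{low-level}{adds the five conspicuity channels and RMS volume.}
#' }
#' Models are compared by R^2 and BIC (n log(RSS/n) + k log n, k counting
#' intercept, slopes and the error variance); the incremental R^2 of the
#' narrative predictor vs the low-level block measures their relative
#' predictive weight.
#'
#' @param target Data.frame `t_s`, `hr`: the condition to predict (see
#'   [condition_mean_hr()]).
#' @param other Data.frame `t_s`, `hr`: the other condition's series.
#' @param features FeatureTable keyed by `t_s` (five channels +
#'   `rms_volume` when present).
#' @param feature_cols Which feature columns to use (default: all except
#'   `t_s`).
#' @param lag Shift in seconds applied to the feature clock: features at
#'   second t predict heart rate at t + lag (default 0).
#' @return Object of class `"nested_hr_models"`: list with `fits` (named
#'   lm list), `table` (model, df, r2, bic), `delta_r2` (narrative,
#'   lowlevel), `n`.
#' @export
fit_nested_models <- function(target, other, features, feature_cols = NULL,
                              lag = 0) {
  stopifnot(all(c("t_s", "hr") %in% names(target)),
            all(c("t_s", "hr") %in% names(other)),
            "t_s" %in% names(features))
  if (is.null(feature_cols)) feature_cols <- setdiff(names(features), "t_s")
  if (length(feature_cols) < 1) stop("no feature columns")
  f <- features
  f$t_s <- f$t_s + lag
  d <- merge(merge(data.frame(t_s = target$t_s, y = target$hr),
                   data.frame(t_s = other$t_s, x_other = other$hr),
                   by = "t_s"),
             f[, c("t_s", feature_cols)], by = "t_s")
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  k_max <- 3 + length(feature_cols) + 1
  if (n <= k_max) stop("too few aligned seconds (n = ", n, ") for ",
                       k_max, " parameters")
  qx <- qr(as.matrix(cbind(1, d$t_s, d$x_other, d[feature_cols])))
  if (qx$rank < 3 + length(feature_cols)) {
    bad <- colnames(qx$qr)[-seq_len(qx$rank)]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fml <- function(rhs) stats::as.formula(paste("y ~", rhs))
  fits <- list(
    null = stats::lm(fml("t_s"), data = d),
    narrative = stats::lm(fml("t_s + x_other"), data = d),
    lowlevel = stats::lm(fml(paste(c("t_s", "x_other", feature_cols),
                                   collapse = " + ")), data = d))
  tss <- sum((d$y - mean(d$y))^2)
  r2 <- vapply(fits, function(m) 1 - sum(m$residuals^2) / tss, numeric(1))
  bic <- vapply(fits, bic_gaussian, numeric(1))
  k <- vapply(fits, function(m) length(stats::coef(m)) + 1, numeric(1))
  out <- list(fits = fits,
              table = data.frame(model = names(fits), df = k, r2 = r2,
                                 bic = bic, row.names = NULL),
              delta_r2 = c(narrative = unname(r2["narrative"] - r2["null"]),
                           lowlevel = unname(r2["lowlevel"] -
                                               r2["narrative"])),
              n = n)
  class(out) <- "nested_hr_models"
  out
}

#' @export
print.nested_hr_models <- function(x, ...) {
  cat(sprintf("Nested heart-rate models (n = %d aligned seconds)\n", x$n))
  tab <- x$table
  tab$r2 <- sprintf("%.3f", tab$r2)
  tab$bic <- sprintf("%.2f", tab$bic)
  print(tab, row.names = FALSE)
  cat(sprintf("best by BIC: %s\n",
              x$table$model[which.min(x$table$bic)]))
  cat(sprintf("delta R2: narrative %.4f, low-level %.4f\n",
              x$delta_r2["narrative"], x$delta_r2["lowlevel"]))
  invisible(x)
}

#' @export
coef.nested_hr_models <- function(object, model = "lowlevel", ...) {
  stats::coef(object$fits[[model]])
}

#' Audiovisual feature co-occurrence regression
#'
#' OLS of RMS volume on the visual conspicuity channels: do loud moments
#' co-occur with visually salient ones? Reports R^2 and the overall
#' F-test.
#'
#' @param features FeatureTable with `rms_volume` and the predictor
#'   columns.
#' @param predictors Predictor column names (default: the five conspicuity
#'   channels present).
#' @return List of class `"regression_summary"`: `r2`, `f_stat`, `df_num`,
#'   `df_den`, `p`, `coefficients`.
#' @export
features_to_volume <- function(features, predictors = NULL) {
  if (is.null(predictors))
    predictors <- intersect(c("intensity", "colour", "orientation",
                              "flicker", "motion"), names(features))
  stopifnot("rms_volume" %in% names(features), length(predictors) >= 2,
            nrow(features) > length(predictors) + 1)
  fml <- stats::as.formula(paste("rms_volume ~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = features)
  y <- features$rms_volume
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  df_num <- length(predictors)
  df_den <- nrow(features) - df_num - 1
  f_stat <- (r2 / df_num) / ((1 - r2) / df_den)
  out <- list(r2 = r2, f_stat = f_stat, df_num = df_num, df_den = df_den,
              p = stats::pf(f_stat, df_num, df_den, lower.tail = FALSE),
              coefficients = stats::coef(fit))
  class(out) <- "regression_summary"
  out
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("r2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$r2, x$df_num, x$df_den, x$f_stat, x$p))
  invisible(x)
}
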