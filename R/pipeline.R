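#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis. All
#' defaults are the canonical values of the analysis design: 15 s rolling
#' window shifted at 1 s, 10,000 shuffle iterations, FDR q = 0.05, 30 s
#' probe interval, 5 s reaction-time cutoff, 20 percent missingness cap,
#' and a 3-SD peak threshold.
#'
#' @param signals,features,ratings Optional input paths (canonical
#'   delimited tables). When `signals` is `NULL` the pipeline simulates a
#'   default audience instead.
#' @param out_dir Output directory for report tables and the manifest.
#' @param window,step ISC window length and shift, seconds.
#' @param agg Per-pair collapse (see [participant_isc()]).
#' @param n_iter Circular-shuffle iterations.
#' @param q FDR level.
#' @param seed Integer seed for every stochastic stage.
#' @param lag Feature lag for the nested models, seconds.
#' @param rt_max,missing_max Rating exclusion rules.
#' @param peak_k Peak threshold in SD units.
#' @param simulate Audience spec used when `signals` is `NULL`
#'   (default [audience_spec()] with this config's seed).
#' @return List of class `"run_config"`.
#' @export
pipeline_config <- function(signals = NULL, features = NULL, ratings = NULL,
                            out_dir = tempfile("audiencesync_run_"),
                            window = 15, step = 1, agg = "mean",
                            n_iter = 10000, q = 0.05, seed = 1L, lag = 0,
                            rt_max = 5, missing_max = 0.20, peak_k = 3,
                            simulate = NULL) {
  cfg <- list(signals = signals, features = features, ratings = ratings,
              out_dir = out_dir, window = window, step = step, agg = agg,
              n_iter = n_iter, q = q, seed = as.integer(seed), lag = lag,
              rt_max = rt_max, missing_max = missing_max, peak_k = peak_k,
              simulate = simulate)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return A `"run_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

log_stage <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full audience-synchrony analysis
#'
#' Orchestrates preprocessing, within- and between-group ISC, the
#' circular-shuffle significance test, group-level tests, stimulus feature
#' extraction, the nested narrative-vs-low-level model comparison, rating
#' cleaning/reliability, the ISC-immersion correlation and peak detection.
#' Input stages without data (no stimulus, no ratings) are skipped. Every
#' output is a delimited text table under `config$out_dir`; a YAML
#' manifest records the full configuration and package version so a run
#' can be reproduced exactly.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return Invisibly, a list with every stage result (`isc_between`,
#'   `isc_within`, `permutation`, `features`, `models`, `ratings`,
#'   `peaks`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  res <- list()

  # --- input / simulation ------------------------------------------------
  if (is.null(config$signals)) {
    spec <- if (is.null(config$simulate))
      audience_spec(seed = config$seed) else config$simulate
    log_stage(logf, "simulate", sprintf(
      "synthetic audience: %d + %d subjects, %d s, seed %d",
      spec$n_subjects_per_group, spec$n_subjects_per_group,
      spec$duration_s, spec$seed))
    aud <- generate_audience(spec)
    series <- aud$series
    res$truth <- aud$truth
  } else {
    log_stage(logf, "input", paste("reading", config$signals))
    series <- read_signal_table(config$signals)
  }

  # --- preprocess --------------------------------------------------------
  hr <- Filter(function(s) s$signal_kind == "heart_rate", series)
  if (!length(hr)) stop("preprocess: no heart-rate series in input")
  hr <- lapply(hr, clean_heart_rate)
  n_corr <- sum(vapply(hr, function(s) attr(s, "n_corrected"), numeric(1)))
  log_stage(logf, "preprocess", sprintf(
    "%d heart-rate series cleaned, %d samples bridged", length(hr), n_corr))
  write_signal_table(hr, file.path(config$out_dir, "heart_rate_clean.tsv"))

  # --- ISC ---------------------------------------------------------------
  groups <- unique(vapply(hr, function(s) s$group, character(1)))
  res$isc_within <- list()
  for (g in groups) {
    if (sum(vapply(hr, function(s) s$group, character(1)) == g) < 2) next
    res$isc_within[[g]] <- isc(hr, design = "within", group = g,
                               window = config$window, step = config$step,
                               agg = config$agg)
  }
  if (length(groups) == 2) {
    res$isc_between <- isc(hr, design = "between", window = config$window,
                           step = config$step, agg = config$agg)
    tc <- res$isc_between$timecourse
  } else {
    res$isc_between <- NULL
    tc <- res$isc_within[[1]]$timecourse
  }
  part_tabs <- c(lapply(names(res$isc_within), function(g)
    cbind(design = paste0("within_", g),
          res$isc_within[[g]]$participant)),
    if (!is.null(res$isc_between))
      list(cbind(design = "between", res$isc_between$participant)))
  part_all <- do.call(rbind, part_tabs)
  utils::write.table(part_all,
                     file.path(config$out_dir, "participant_isc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(tc, file.path(config$out_dir, "isc_timecourse.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage(logf, "isc", sprintf(
    "designs: %s; between mean r = %s",
    paste(c(paste0("within_", names(res$isc_within)),
            if (!is.null(res$isc_between)) "between"), collapse = ", "),
    if (!is.null(res$isc_between))
      sprintf("%.4f", mean(res$isc_between$participant$isc, na.rm = TRUE))
    else "NA"))

  # --- permutation significance -----------------------------------------
  design <- if (!is.null(res$isc_between)) "between" else "within"
  res$permutation <- cohort_permutation_test(
    hr, design = design, n_iter = config$n_iter, q = config$q,
    window = config$window, seed = config$seed)
  utils::write.table(as.data.frame(res$permutation),
                     file.path(config$out_dir, "permutation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage(logf, "permtest", sprintf(
    "%d / %d participants significant at q = %g (%d iterations)",
    sum(res$permutation$significant), nrow(res$permutation), config$q,
    config$n_iter))

  # --- features + modeling ----------------------------------------------
  if (!is.null(config$features)) {
    res$features <- read_feature_table(config$features)
    log_stage(logf, "features", sprintf("%d s of features read",
                                        nrow(res$features)))
    if (length(groups) == 2) {
      grp_of <- vapply(hr, function(s) s$group, character(1))
      hr_a <- condition_mean_hr(hr[grp_of == groups[1]])
      hr_b <- condition_mean_hr(hr[grp_of == groups[2]])
      res$models <- list()
      res$models[[groups[1]]] <-
        fit_nested_models(hr_a, hr_b, res$features, lag = config$lag)
      res$models[[groups[2]]] <-
        fit_nested_models(hr_b, hr_a, res$features, lag = config$lag)
      mt <- do.call(rbind, lapply(names(res$models), function(g)
        cbind(target = g, res$models[[g]]$table)))
      utils::write.table(mt,
                         file.path(config$out_dir, "model_comparison.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if ("rms_volume" %in% names(res$features))
        res$volume_regression <- features_to_volume(res$features)
      log_stage(logf, "model", "nested comparison written")
    }
  }

  # --- ratings -----------------------------------------------------------
  if (!is.null(config$ratings)) {
    tab <- read_rating_table(config$ratings)
    clean <- clean_ratings(tab, config$rt_max, config$missing_max)
    excl <- attr(clean, "exclusions")
    log_stage(logf, "ratings", sprintf(
      "%d raters retained (%d dropped, %d slow-RT responses blanked)",
      excl$n_retained, length(excl$dropped_raters), excl$n_slow_rt))
    res$ratings <- list(
      table = clean,
      reliability = rating_reliability(clean),
      isc_correlation = correlate_isc_ratings(tc, clean))
    utils::write.table(res$ratings$isc_correlation$binned,
                       file.path(config$out_dir, "isc_vs_ratings.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  # --- peaks -------------------------------------------------------------
  res$peaks <- detect_peaks(tc, k = config$peak_k)
  utils::write.table(res$peaks, file.path(config$out_dir, "peaks.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage(logf, "peaks", sprintf("%d high-synchrony runs (k = %g)",
                                   nrow(res$peaks), config$peak_k))

  # --- manifest ----------------------------------------------------------
  cfg_flat <- config[!vapply(config, is.null, logical(1))]
  cfg_flat$simulate <- NULL
  manifest <- list(
    package = "audiencesync",
    version = as.character(utils::packageVersion("audiencesync")),
    r_version = as.character(getRversion()),
    config = cfg_flat,
    config_hash = sum(utf8ToInt(paste(names(cfg_flat),
                                      vapply(cfg_flat, function(v)
                                        paste(format(v), collapse = ","),
                                        character(1)),
                                      collapse = ";"))))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  res$manifest <- manifest
  log_stage(logf, "done", config$out_dir)
  invisible(res)
}
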