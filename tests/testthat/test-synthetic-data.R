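test_that("generator rejects non-stationary AR coefficients", {
  expect_error(audience_spec(ar_coef = 1), "non-stationary")
  expect_error(audience_spec(ar_coef = 1.2), "non-stationary")
  expect_silent(audience_spec(ar_coef = 0.99))
})

test_that("identical spec and seed give bit-identical audiences", {
  spec <- audience_spec(n_subjects_per_group = 3, duration_s = 80, seed = 42)
  a <- generate_audience(spec)
  b <- generate_audience(spec)
  expect_identical(a, b)
})

test_that("narrative and modality components are standardized and orthogonal", {
  aud <- generate_audience(audience_spec(n_subjects_per_group = 2,
                                         duration_s = 400, seed = 9))
  s <- aud$truth$narrative_signal
  expect_lt(abs(mean(s)), 1e-10)
  expect_lt(abs(stats::sd(s) - 1), 1e-10)
  for (m in aud$truth$group_signals) {
    expect_lt(abs(stats::cor(s, m)), 1e-10)
    expect_lt(abs(stats::sd(m) - 1), 1e-10)
  }
  expect_lt(abs(stats::cor(aud$truth$group_signals[[1]],
                           aud$truth$group_signals[[2]])), 1e-10)
})

test_that("no shared signal means between-group ISC near zero", {
  aud <- generate_audience(audience_spec(n_subjects_per_group = 6,
                                         duration_s = 300,
                                         shared_loading = 0,
                                         modality_loading = 0,
                                         artifact_rate = 0, seed = 5))
  fit <- isc(aud$series, design = "between")
  n_windows <- ncol(fit$pair_windows$r)
  expect_lt(abs(mean(fit$participant$isc)), 3 / sqrt(n_windows))
})

test_that("pure shared signal gives perfect windowed correlations", {
  # noiseless: all subjects are baseline + s(t); every defined window r = 1
  spec <- audience_spec(n_subjects_per_group = 3, duration_s = 100,
                        shared_loading = 1, modality_loading = 0,
                        ar_coef = 0, noise_sd = 1e-12, artifact_rate = 0,
                        seed = 2)
  aud <- generate_audience(spec)
  pw <- windowed_pairwise_isc(aud$series,
                              between_group_pairs(ids_of(aud$series)[1:3],
                                                  ids_of(aud$series)[4:6]))
  expect_true(all(abs(pw$r[!is.na(pw$r)] - 1) < 1e-6))
})

test_that("mean between-group ISC matches a brute-force oracle", {
  aud <- generate_audience(audience_spec(n_subjects_per_group = 8,
                                         duration_s = 600,
                                         shared_loading = 0.6,
                                         ar_coef = 0.5, noise_sd = 1,
                                         seed = 7, artifact_rate = 0))
  ids <- ids_of(aud$series)
  pairs <- between_group_pairs(ids[1:8], ids[9:16])
  fit <- isc(aud$series, design = "between")
  vals <- values_of(aud$series)
  oracle_mean <- mean(vapply(seq_len(nrow(pairs)), function(k) {
    r <- oracle_windowed_r(vals[[match(pairs$id_i[k], ids)]],
                           vals[[match(pairs$id_j[k], ids)]])
    mean(r, na.rm = TRUE)
  }, numeric(1)))
  expect_lt(abs(mean(fit$participant$isc) - oracle_mean), 0.05)
})

test_that("between-group ISC is monotone in the shared loading", {
  grid <- c(0, 0.3, 0.6)
  mean_isc <- sapply(grid, function(lam) {
    mean(sapply(1:20, function(rep) {
      aud <- generate_audience(audience_spec(
        n_subjects_per_group = 8, duration_s = 300, shared_loading = lam,
        artifact_rate = 0, seed = 1000 + rep))
      mean(isc(aud$series, design = "between")$participant$isc)
    }))
  })
  expect_true(all(diff(mean_isc) > 0))
})

test_that("artifact spikes land strictly inside the recording, isolated", {
  aud <- generate_audience(audience_spec(n_subjects_per_group = 4,
                                         duration_s = 300,
                                         artifact_rate = 0.05, seed = 3))
  for (pos in aud$truth$artifacts) {
    if (!length(pos)) next
    expect_true(all(pos >= 2 & pos <= 299))
    if (length(pos) > 1) expect_true(all(diff(pos) > 1))
  }
})

test_that("synthetic stimulus honors its event script", {
  st <- generate_stimulus(40, frame_rate = 2, audio_rate = 1000, seed = 4,
                          loud_events = 30L, luminance_steps = integer(0),
                          colour_changes = integer(0),
                          flicker_onsets = integer(0))
  rms <- audio_rms_per_second(st$audio, st$audio_rate)
  expect_equal(rms$t_s[which.max(rms$rms_volume)], 30)
  expect_true("loud_event" %in% st$events$type)

  silent <- generate_stimulus(5, frame_rate = 2, audio_rate = 1000,
                              seed = 1, base_amp = 0,
                              loud_events = integer(0),
                              luminance_steps = integer(0),
                              colour_changes = integer(0),
                              flicker_onsets = integer(0))
  expect_true(all(audio_rms_per_second(silent$audio,
                                       silent$audio_rate)$rms_volume == 0))
})

test_that("uniform-gray stimulus yields all-zero conspicuity RMS", {
  st <- generate_stimulus(3, frame_rate = 2, audio_rate = 1000, seed = 1,
                          n_blobs = 0, base_amp = 0,
                          luminance_steps = integer(0),
                          colour_changes = integer(0),
                          flicker_onsets = integer(0),
                          loud_events = integer(0))
  ft <- stimulus_features(st$frames, st$frame_rate, st$audio, st$audio_rate)
  for (ch in c("intensity", "colour", "orientation", "flicker", "motion",
               "rms_volume"))
    expect_true(all(ft[[ch]] == 0), info = ch)
})

test_that("rating cohort: no noise means identical raters", {
  imm <- sin(2 * pi * (1:300) / 150)
  tab <- generate_rating_cohort(4, 300, 30, imm, noise_sd = 0,
                                missing_rate = 0, seed = 1)
  M <- split(tab$rating, tab$rater_id)
  for (k in 2:4) expect_identical(M[[1]], M[[k]])
  expect_equal(rating_reliability(tab), 1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("monotone immersion yields non-decreasing mean ratings", {
  imm <- seq(0, 1, length.out = 300)
  tab <- generate_rating_cohort(6, 300, 30, imm, noise_sd = 0,
                                discretize = FALSE, seed = 2)
  mr <- tapply(tab$rating, tab$probe_t_s, mean)
  expect_true(all(diff(mr[order(as.numeric(names(mr)))]) >= 0))
})

test_that("high-missingness raters are flagged downstream", {
  imm <- stats::rnorm(300)
  tab <- generate_rating_cohort(3, 300, 30, imm, noise_sd = 0.5,
                                missing_rate = c(0, 0, 0.5), seed = 8)
  clean <- clean_ratings(tab)
  excl <- attr(clean, "exclusions")
  expect_true("r003" %in% excl$dropped_raters)
})
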