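# Deterministic cohort for exclusion arithmetic: `missing_idx` marks the
# probes blanked for the given raters (exact fractions, not sampled).
build_cohort <- function(n_raters, n_probes, interval = 30,
                         rating_fn = function(p) 4, rt = 1) {
  do.call(rbind, lapply(seq_len(n_raters), function(r) {
    probes <- seq(interval, n_probes * interval, by = interval)
    data.frame(rater_id = sprintf("r%03d", r), probe_t_s = probes,
               rating = vapply(probes, rating_fn, numeric(1)), rt_s = rt,
               stringsAsFactors = FALSE)
  }))
}

test_that("rating exclusion reproduces the 50-to-35 cohort arithmetic", {
  tab <- build_cohort(50, 20)
  # 15 raters get exactly 25 percent of probes blanked (> 20 percent)
  for (r in sprintf("r%03d", 1:15)) {
    idx <- which(tab$rater_id == r)[1:5]
    tab$rating[idx] <- NA
  }
  clean <- clean_ratings(tab)
  excl <- attr(clean, "exclusions")
  expect_equal(excl$n_retained, 35)
  expect_equal(length(excl$dropped_raters), 15)
})

test_that("clean table passes through unchanged and cleaning is idempotent", {
  set.seed(3)
  tab <- build_cohort(6, 10, rating_fn = function(p) sample(1:7, 1))
  clean <- clean_ratings(tab)
  expect_equal(clean$rating, tab$rating)
  again <- clean_ratings(clean)
  expect_equal(again$rating, clean$rating)
  expect_equal(attr(again, "exclusions")$n_retained,
               attr(clean, "exclusions")$n_retained)
})

test_that("the reaction-time rule blanks exactly the slow response", {
  tab <- build_cohort(2, 10)
  tab$rt_s[7] <- 5.01
  clean <- clean_ratings(tab)
  expect_true(is.na(clean$rating[7]))
  expect_equal(sum(is.na(clean$rating)), 1)
  # rt exactly 5 s is kept (rule is strictly greater)
  tab$rt_s[7] <- 5
  expect_false(anyNA(clean_ratings(tab)$rating))
})

test_that("reliability is 1 for identical raters, ~0 for independent ones", {
  imm <- sin(2 * pi * (1:600) / 200)
  tab <- generate_rating_cohort(5, 600, 30, imm, noise_sd = 0, seed = 1)
  expect_equal(rating_reliability(tab), 1, tolerance = 1e-12,
               ignore_attr = TRUE)

  vals <- vapply(1:50, function(rep) {
    tab <- generate_rating_cohort(6, 600, 30, rep(0, 600), noise_sd = 1,
                                  seed = 2000 + rep, discretize = FALSE)
    rating_reliability(tab)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("reliability recovers the generative pairwise correlation", {
  # latent model: rating = z(t) + noise, so pair correlation = 1/(1+sd^2)
  sd_noise <- 1
  imm <- as.numeric(scale(stats::filter(rnorm(3000), rep(1, 80),
                                        circular = TRUE)))
  set.seed(41)
  vals <- vapply(1:10, function(rep) {
    tab <- generate_rating_cohort(20, 3000, 30, imm, noise_sd = sd_noise,
                                  seed = 3000 + rep, discretize = FALSE)
    rating_reliability(tab)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1 / (1 + sd_noise^2)), 0.05)
  # discretization to the 7-point scale attenuates only slightly
  tabd <- generate_rating_cohort(20, 3000, 30, imm, noise_sd = sd_noise,
                                 seed = 3100)
  expect_lt(abs(rating_reliability(tabd) - 1 / (1 + sd_noise^2)), 0.08)
})

test_that("reliability is invariant to rater relabeling", {
  imm <- cos(2 * pi * (1:600) / 150)
  tab <- generate_rating_cohort(6, 600, 30, imm, noise_sd = 0.8, seed = 7)
  rel1 <- rating_reliability(tab)
  tab2 <- tab
  tab2$rater_id <- sprintf("z%03d", as.integer(factor(tab$rater_id,
    levels = rev(sort(unique(tab$rater_id))))))
  expect_equal(rating_reliability(tab2), rel1, tolerance = 1e-12)
})

test_that("ISC-rating correlation handles exact and degenerate cases", {
  tc <- data.frame(t_s = 0:569, isc = sin(2 * pi * (0:569) / 300) * 0.1)
  probes <- seq(30, 570, by = 30)
  binned <- vapply(probes, function(p)
    mean(tc$isc[tc$t_s >= p - 30 & tc$t_s < p]), numeric(1))
  tab <- data.frame(rater_id = "r001", probe_t_s = probes, rating = binned,
                    rt_s = 1)
  out <- correlate_isc_ratings(tc, tab)
  expect_equal(out$r, 1, tolerance = 1e-12)

  tab$rating <- 4
  expect_message(out0 <- correlate_isc_ratings(tc, tab), "zero variance")
  expect_true(is.na(out0$r))
})

test_that("immersion-modulated audiences couple ratings to the ISC trace", {
  hits <- vapply(1:20, function(rep) {
    n <- 600
    set.seed(8200 + rep)
    env <- 0.5 + abs(as.numeric(scale(stats::filter(
      rnorm(n), rep(1, 120), circular = TRUE))))
    aud <- generate_audience(audience_spec(
      n_subjects_per_group = 8, duration_s = n, shared_loading = 0.8,
      artifact_rate = 0, seed = 8200 + rep), shared_envelope = env)
    tc <- isc(aud$series, design = "between")$timecourse
    tab <- generate_rating_cohort(10, n, 30, env, noise_sd = 0.5,
                                  seed = 8200 + rep)
    out <- correlate_isc_ratings(tc, tab)
    out$r > 0 && out$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("peak detection finds injected bursts and respects affine scaling", {
  tc0 <- data.frame(t_s = 0:299, isc = rep(0.05, 300))
  expect_equal(nrow(detect_peaks(tc0)), 0)

  hits <- vapply(1:20, function(rep) {
    env <- rep(0, 400); env[201:216] <- 1
    aud <- generate_audience(audience_spec(
      n_subjects_per_group = 6, duration_s = 400, shared_loading = 3,
      modality_loading = 0, artifact_rate = 0, seed = 600 + rep),
      shared_envelope = env)
    tc <- isc(aud$series, design = "between")$timecourse
    pk <- detect_peaks(tc, k = 3)
    nrow(pk) > 0 && any(pk$end_s >= 186 & pk$start_s <= 215)
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  set.seed(30)
  tc <- data.frame(t_s = 0:499, isc = rnorm(500))
  tc$isc[100:104] <- 6
  pk1 <- detect_peaks(tc, k = 3)
  tc_aff <- tc; tc_aff$isc <- 0.01 * tc$isc + 5
  pk2 <- detect_peaks(tc_aff, k = 3)
  expect_equal(pk1$start_s, pk2$start_s)
  expect_equal(pk1$end_s, pk2$end_s)
})

test_that("exceedances of a Gaussian trace follow the normal tail rate", {
  # expected seconds above mean + 3 SD: n * (1 - pnorm(3)) ~= 4 per 3000
  total <- 0
  for (rep in 1:20) {
    set.seed(9100 + rep)
    tc <- data.frame(t_s = 0:2999, isc = rnorm(3000))
    pk <- detect_peaks(tc, k = 3)
    if (nrow(pk)) total <- total + sum(pk$end_s - pk$start_s + 1)
  }
  lambda <- 20 * 3000 * stats::pnorm(3, lower.tail = FALSE)
  expect_gte(total, stats::qpois(0.0005, lambda))
  expect_lte(total, stats::qpois(0.9995, lambda))
})

test_that("rating tables round-trip through delimited text", {
  imm <- sin(2 * pi * (1:300) / 100)
  tab <- generate_rating_cohort(3, 300, 30, imm, noise_sd = 0.3,
                                missing_rate = 0.1, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rating_table(tab, path)
  back <- read_rating_table(path)
  expect_equal(back$rating, tab$rating)
  expect_equal(back$probe_t_s, tab$probe_t_s)
})
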