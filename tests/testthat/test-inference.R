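test_that("circular shift rotates and preserves the multiset", {
  expect_identical(circular_shift(1:4, 1), c(4L, 1L, 2L, 3L))
  expect_identical(circular_shift(1:5, 0), 1:5)
  expect_identical(circular_shift(1:5, 5), 1:5)
  set.seed(2)
  x <- rnorm(30)
  for (off in c(3, 17, 29))
    expect_identical(sort(circular_shift(x, off)), sort(x))
})

test_that("circular shift approximately preserves AR(1) autocorrelation", {
  set.seed(14)
  x <- as.numeric(arima.sim(list(ar = 0.7), 600))
  lag1 <- function(v) stats::cor(v[-1], v[-length(v)])
  shifted <- circular_shift(x, 211)
  expect_lt(abs(lag1(shifted) - lag1(x)), 0.05)
})

test_that("permutation observed value equals the R-path participant ISC", {
  aud <- small_audience(n = 4, dur = 80, seed = 5)
  ids <- ids_of(aud$series)
  pr <- participant_permutation_test(aud$series[[1]], aud$series[5:8],
                                     n_iter = 100, rng_seed = 1)
  pw <- windowed_pairwise_isc(aud$series,
                              between_group_pairs(ids[1:4], ids[5:8]))
  want <- participant_isc(pw)$participant
  expect_equal(pr$observed_isc,
               want$isc[want$participant_id == ids[1]],
               tolerance = 1e-12)
})

test_that("null values from the C++ path match a manual R recomputation", {
  aud <- small_audience(n = 3, dur = 60, seed = 19)
  target <- aud$series[[1]]
  partners <- aud$series[4:6]
  set.seed(99)
  offsets <- sample(15:(60 - 15), 5)
  nulls <- audiencesync:::perm_isc_null_cpp(
    target$values,
    vapply(partners, function(s) s$values, numeric(60)),
    as.integer(offsets), 15L)
  for (k in seq_along(offsets)) {
    shifted <- circular_shift(target$values, offsets[k])
    want <- stats::median(vapply(partners, function(p)
      mean(oracle_windowed_r(shifted, p$values), na.rm = TRUE), numeric(1)))
    expect_equal(nulls[k], want, tolerance = 1e-12)
  }
})

test_that("self-similar target attains the minimal p-value", {
  set.seed(4)
  x <- rnorm(90)
  target <- signal_series(x, "t", "audio", "heart_rate")
  partners <- lapply(1:3, function(i)
    signal_series(x + rnorm(90, 0, 1e-6), paste0("p", i), "visual",
                  "heart_rate"))
  pr <- participant_permutation_test(target, partners, n_iter = 199,
                                     rng_seed = 7)
  expect_equal(pr$p_value, 1 / 200)
})

test_that("p-values are uniform under independence", {
  ps <- vapply(1:200, function(rep) {
    set.seed(6000 + rep)
    target <- signal_series(as.numeric(arima.sim(list(ar = 0.3), 120)),
                            "t", "audio", "heart_rate")
    partners <- lapply(1:5, function(i)
      signal_series(as.numeric(arima.sim(list(ar = 0.3), 120)),
                    paste0("p", i), "visual", "heart_rate"))
    participant_permutation_test(target, partners, n_iter = 199,
                                 rng_seed = rep)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(ps >= 1 / 200))
})

test_that("shifting partners instead of the target gives the same decision", {
  agree <- vapply(1:100, function(rep) {
    set.seed(7000 + rep)
    n <- 120
    shared <- as.numeric(scale(stats::filter(rnorm(n), rep(1, 7),
                                             circular = TRUE)))
    make <- function(id, grp, lam)
      signal_series(lam * shared + rnorm(n), id, grp, "heart_rate")
    lam <- if (rep %% 2 == 0) 0.6 else 0   # mix of null and signal cases
    target <- make("t", "audio", lam)
    partners <- lapply(1:4, function(i) make(paste0("p", i), "visual", lam))
    Y <- vapply(partners, function(s) s$values, numeric(n))

    pr_a <- participant_permutation_test(target, partners, n_iter = 199,
                                         rng_seed = rep)
    # variant: shift each partner independently, target fixed
    obs <- audiencesync:::perm_isc_null_cpp(target$values, Y, 0L, 15L)
    nulls <- vapply(1:199, function(it) {
      Ys <- vapply(seq_len(ncol(Y)), function(j)
        circular_shift(Y[, j], sample(15:(n - 15), 1)), numeric(n))
      audiencesync:::perm_isc_null_cpp(target$values, Ys, 0L, 15L)
    }, numeric(1))
    p_b <- (1 + sum(nulls >= obs)) / 200
    (pr_a$p_value < 0.05) == (p_b < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("BH-FDR matches hand-executed and textbook implementations", {
  expect_identical(bh_fdr(c(0.001, 0.02, 0.9), 0.05),
                   c(TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 10), 0.05)))
  set.seed(10)
  for (rep in 1:20) {
    p <- runif(50)^2
    expect_identical(bh_fdr(p, 0.05), oracle_bh(p, 0.05))
    expect_identical(bh_fdr(p, 0.2), oracle_bh(p, 0.2))
  }
  expect_error(bh_fdr(c(0, 0.5), 0.05))
})

test_that("group-level one-tailed t-test matches hand arithmetic", {
  gt <- group_isc_test(c(0.1, 0.2, 0.3, 0.2, 0.2))
  expect_equal(gt$mean_r, 0.2)
  expect_equal(gt$t, 0.2 / (stats::sd(c(0.1, 0.2, 0.3, 0.2, 0.2)) / sqrt(5)),
               tolerance = 1e-12)
  expect_equal(gt$t, 6.325, tolerance = 1e-3)
  expect_equal(gt$p, stats::pt(gt$t, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  gt0 <- group_isc_test(rep(0, 5))
  expect_equal(gt0$t, 0)
  expect_equal(gt0$d, 0)
  expect_equal(gt0$p, 0.5)
})

test_that("group test power and size behave under the generator", {
  reject <- function(lam, reps, seed0) vapply(seq_len(reps), function(rep) {
    aud <- generate_audience(audience_spec(
      n_subjects_per_group = 15, duration_s = 300, shared_loading = lam,
      artifact_rate = 0, seed = seed0 + rep))
    isc(aud$series, design = "between")$group_test$p < 0.05
  }, logical(1))
  expect_gte(mean(reject(0.6, 20, 8100)), 0.9)
})

test_that("noncentral-t power analysis matches stats::power.t.test", {
  # dual route: our bisection vs the reference implementation
  for (case in list(
    list(test = "one_sample_t", tails = 1, n = 870, power = 0.95),
    list(test = "one_sample_t", tails = 2, n = 40, power = 0.8),
    list(test = "two_sample_t", tails = 2, n = 30, power = 0.8))) {
    got <- do.call(power_t, case)
    ref <- stats::power.t.test(
      n = case$n, power = case$power, sig.level = 0.05,
      type = if (case$test == "one_sample_t") "one.sample" else "two.sample",
      alternative = if (case$tails == 1) "one.sided" else "two.sided")
    expect_equal(got$d, ref$delta, tolerance = 1e-4)
  }
  got <- power_t("two_sample_t", tails = 2, n = 30, d = 0.52)
  ref <- stats::power.t.test(n = 30, delta = 0.52, sd = 1,
                             type = "two.sample")
  expect_equal(got$power, ref$power, tolerance = 1e-4)

  # solving n
  got_n <- power_t("one_sample_t", tails = 2, d = 0.5, power = 0.8)
  ref_n <- stats::power.t.test(delta = 0.5, power = 0.8,
                               type = "one.sample")
  expect_equal(got_n$n, ref_n$n, tolerance = 1e-4)

  expect_equal(power_t("one_sample_t", tails = 1, n = 50, d = 0)$power,
               0.05, tolerance = 1e-10)
  expect_error(power_t("one_sample_t", tails = 1, n = 50, power = 0.04),
               "infeasible")
  expect_error(power_t("one_sample_t", tails = 1, n = 50, d = 0.1,
                       power = 0.8), "exactly one")
})

test_that("Welch test matches the textbook formula and stats::t.test", {
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3.674, tolerance = 1e-3)
  expect_equal(w$df, 4, tolerance = 1e-9)

  set.seed(23)
  for (rep in 1:10) {
    a <- rnorm(8 + rep, 1, 2); b <- rnorm(12, 0, 1)
    w <- welch_t(a, b)
    o <- oracle_welch(a, b)
    expect_equal(w$t, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
  }
  same <- rnorm(5)
  w0 <- welch_t(same, same)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
})

test_that("permutation decisions are reproducible given the seed", {
  aud <- small_audience(n = 3, dur = 90, seed = 55)
  r1 <- cohort_permutation_test(aud$series, "between", n_iter = 100,
                                seed = 9)
  r2 <- cohort_permutation_test(aud$series, "between", n_iter = 100,
                                seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$significant, r2$significant)
})
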