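test_that("noise-free skeletons follow the documented closed forms", {
  # fast modulation: exponential return to baseline after the peak
  p1 <- archetype_params(1, baseline_mfi = 2000, peak_mfi = 16000,
                         peak_day = 13, peak_duration = 0,
                         decay_half_life = 5, noise_cv = 0)
  v <- make_trajectory(p1, grid = 0:50)
  expect_equal(v[18 + 1], 2000 + (16000 - 2000) * 2^(-(18 - 13 - 0) / 5))
  expect_equal(v[13 + 1], 16000)
  # with a peak plateau, decay is measured from its end
  p1b <- archetype_params(1, baseline_mfi = 2000, peak_mfi = 16000,
                          peak_day = 13, peak_duration = 3,
                          decay_half_life = 5, noise_cv = 0)
  vb <- make_trajectory(p1b, grid = 0:50)
  expect_equal(vb[15 + 1], 16000)
  expect_equal(vb[21 + 1], 2000 + 14000 * 2^(-(21 - 16) / 5))

  # no response: flat baseline, always below the gate
  v0 <- make_trajectory(archetype_params(0, baseline_mfi = 800,
                                         noise_cv = 0), grid = 0:50)
  expect_true(all(v0 == 800))
  expect_true(all(v0 < 1500))

  # slow modulation reaches exactly 30% of peak at day 50
  p2 <- archetype_params(2, peak_mfi = 10000, peak_day = 13, noise_cv = 0,
                         oscillation_amplitude = 0,
                         plateau_fraction_day50 = 0.30)
  v2 <- make_trajectory(p2, grid = 0:50)
  expect_equal(v2[50 + 1], 3000)

  # sustained rise: high levels persist after the later peak
  p3 <- archetype_params(3, noise_cv = 0)
  v3 <- make_trajectory(p3, grid = 0:50)
  expect_equal(v3[22 + 1], v3[50 + 1])
  expect_gt(v3[50 + 1], 1500)
})

test_that("trajectory generation validates its inputs", {
  expect_error(archetype_params(7), "unknown group_id")
  expect_error(archetype_params(1, peak_mfi = -5), "negative")
  expect_error(archetype_params(1, peak_mfi = 1000, baseline_mfi = 2000),
               "exceed")
  p <- archetype_params(1)
  expect_error(make_trajectory(p, grid = c(3, 2, 1)), "grid")
  expect_error(make_trajectory(p, grid = c(0, 60)), "grid")
})

test_that("gate-consistency invariants hold for every noise realisation", {
  for (s in 1:25) {
    v0 <- make_trajectory(archetype_params(0, noise_cv = 0.3), seed = s)
    expect_true(all(v0 < 1500))
    v4 <- make_trajectory(archetype_params(4, noise_cv = 0.3), seed = s)
    expect_true(all(v4 > 1500))
    expect_true(all(v0 >= 0) && all(v4 >= 0))
  }
})

test_that("archetype shapes separate beyond within-group noise spread", {
  # within-group spread is measured case to case (comparing a noisy
  # max-scaled draw to the unscaled skeleton would confound the shared
  # downward level bias that max-scaling induces)
  skel <- lapply(1:4, archetype_skeleton, grid = 1:50)
  q95 <- vapply(1:4, function(g) {
    draws <- lapply(1:25, function(s) {
      v <- make_trajectory(archetype_params(g, noise_cv = 0.1),
                           grid = 1:50, seed = 400 + 30 * g + s)
      v / max(v)
    })
    D <- dtw_matrix(draws)
    unname(quantile(D[upper.tri(D)], 0.95))
  }, 1.0)
  for (g in 1:3) for (h in (g + 1):4) {
    between <- dtw_distance(skel[[g]], skel[[h]])
    expect_gt(between, q95[g])
    expect_gt(between, q95[h])
  }
})

test_that("sampling schedules are dense early and obey their contracts", {
  # rate-1 dense window with dropout at its end gives every day exactly
  sch <- sampling_schedule(dense_rate = 1, late_rate = 0)
  expect_identical(make_schedule(sch, seed = 1, dropout_day = 20), 0:20)

  expect_error(sampling_schedule(dense_window_days = 60), "horizon")
  expect_error(sampling_schedule(dense_rate = 0), "positive")

  # default schedule: at least 80% of cases have >= 10 sampled days in
  # the first 20 days (Monte-Carlo over 1000 cases)
  sch <- sampling_schedule()
  early <- vapply(1:1000, function(s) {
    d <- make_schedule(sch, seed = s)
    sum(d >= 0 & d <= 20)
  }, 1.0)
  expect_gte(mean(early >= 10), 0.8)

  # late window: ~6 expected samples in days 21-50 at rate 0.2/day
  late <- vapply(1:2000, function(s) {
    d <- make_schedule(sampling_schedule(late_rate = 0.2), seed = s,
                       dropout_day = 50)
    sum(d >= 21 & d <= 50)
  }, 1.0)
  expect_lt(abs(mean(late) - 6), 1.5)
})

test_that("cohorts have requested sizes and are seed-deterministic", {
  co <- make_cohort(n_per_group = c(18L, 15L, 23L, 16L, 16L), seed = 42)
  expect_equal(nrow(co$cohort), 88L)
  expect_equal(as.integer(table(co$cohort$true_group)),
               c(18L, 15L, 23L, 16L, 16L))
  co2 <- make_cohort(n_per_group = c(18L, 15L, 23L, 16L, 16L), seed = 42)
  expect_identical(co, co2)
  co3 <- make_cohort(n_per_group = c(18L, 15L, 23L, 16L, 16L), seed = 43)
  expect_false(identical(co$mfi, co3$mfi))

  expect_error(make_cohort(n_per_group = rep(0L, 5)), "zero")
  expect_error(make_cohort(n_per_group = c(1L, 1L)), "5 non-negative")

  # between 1 and 7 specificities per case, summing to the tDSA
  n_spec <- tapply(co$mfi$specificity, co$mfi$case_id,
                   function(s) length(unique(s)))
  expect_true(all(n_spec >= 1 & n_spec <= 7))
})

test_that("covariate model validates probabilities and directions", {
  expect_error(covariate_model(p_female = c(0.5, 0.5, 0.5, 0.5, 1.5)),
               "probabilities")
  expect_error(covariate_model(p_rejection = c(0.2, 0.1, 0.1, 0.9, 0.9)),
               "direction")
})

test_that("noise-free daily-sampled cohorts are recovered perfectly", {
  co <- make_cohort(n_per_group = c(0L, 4L, 4L, 4L, 4L), noise_cv = 0,
                    schedule = sampling_schedule(dense_window_days = 50,
                                                 dense_rate = 1,
                                                 p_complete = 1),
                    param_jitter = FALSE, seed = 9)
  pr <- preprocess_cohort(co$mfi)
  trajs <- Filter(function(tr) identical(tr$length_class, "full_50"),
                  pr$trajectories)
  expect_length(trajs, 16L)
  cut <- cut_clusters(agglomerate(clustering_series(trajs)), 4)
  truth <- co$cohort$true_group[match(names(cut$labels),
                                      co$cohort$case_id)]
  expect_equal(length(unique(paste(cut$labels, truth))), 4L)
})
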