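make_records <- function(...) {
  # ... = named vectors day -> mfi per specificity
  specs <- list(...)
  do.call(rbind, lapply(names(specs), function(sp) {
    v <- specs[[sp]]
    data.frame(specificity = sp, day = as.integer(names(v)),
               mfi = unname(v), stringsAsFactors = FALSE)
  }))
}

test_that("tDSA aggregation sums specificities per observed day", {
  rec <- make_records(A2 = c(`3` = 1000), DR4 = c(`3` = 2000))
  agg <- aggregate_tdsa(rec)
  expect_equal(agg$tdsa[agg$day == 3], 3000)

  agg1 <- aggregate_tdsa(make_records(B7 = c(`0` = 500)))
  expect_equal(agg1, data.frame(day = 0L, tdsa = 500))

  # only observed days are emitted
  rec2 <- make_records(A2 = c(`0` = 1, `2` = 2), DR4 = c(`0` = 3, `2` = 4))
  expect_identical(aggregate_tdsa(rec2)$day, c(0L, 2L))

  expect_error(aggregate_tdsa(make_records(A2 = c(`1` = -5))), "negative")
  dup <- rbind(make_records(A2 = c(`1` = 5)), make_records(A2 = c(`1` = 6)))
  expect_error(aggregate_tdsa(dup), "A2@1")
})

test_that("daily interpolation is linear, capped, and non-extrapolating", {
  obs <- data.frame(day = c(0, 2, 25), tdsa = c(100, 300, 300))
  tr <- interpolate_daily(obs)
  expect_equal(tr$tdsa[tr$days == 1], 200)

  const <- interpolate_daily(data.frame(day = c(0, 50), tdsa = c(100, 100)))
  expect_true(all(const$tdsa == 100))
  expect_identical(const$days, 0:50)

  hand <- interpolate_daily(data.frame(day = c(0, 10, 13, 20, 50),
                                       tdsa = c(0, 1000, 16000, 1000, 500)))
  expect_equal(hand$tdsa[hand$days == 16],
               (16000 * (20 - 16) + 1000 * (16 - 13)) / 7)
  expect_equal(round(hand$tdsa[hand$days == 16], 2), 9571.43)

  # values at observed days are untouched
  expect_equal(hand$tdsa[hand$days %in% c(0, 10, 13, 20, 50)],
               c(0, 1000, 16000, 1000, 500))

  # 21-day inclusion rule
  expect_error(interpolate_daily(data.frame(day = c(0, 15),
                                            tdsa = c(1, 2))),
               "excluded")
  # grid capped at the horizon even for later samples
  late <- interpolate_daily(data.frame(day = c(0, 60), tdsa = c(0, 600)))
  expect_equal(max(late$days), 50)
})

test_that("interpolating an already-daily series is the identity", {
  set.seed(3)
  v <- runif(51, 0, 100)
  tr <- interpolate_daily(data.frame(day = 0:50, tdsa = v))
  expect_equal(tr$tdsa, v)
})

test_that("interpolated values never exceed bracketing observations", {
  set.seed(4)
  for (i in 1:20) {
    days <- sort(sample(0:50, sample(5:15, 1)))
    days <- unique(c(0, days, 50))
    vals <- runif(length(days), 0, 2e4)
    tr <- interpolate_daily(data.frame(day = days, tdsa = vals))
    expect_lte(max(tr$tdsa), max(vals) + 1e-9)
    expect_gte(min(tr$tdsa), min(vals) - 1e-9)
    # the max is attained at an observed day, so gating before or after
    # interpolation is identical
    expect_equal(max(tr$tdsa), max(vals))
  }
})

test_that("the 1500-MFI gate is strict and scaling normalises the max", {
  traj <- function(vals) {
    interpolate_daily(data.frame(day = seq(0, 50, length.out = length(vals)),
                                 tdsa = vals))
  }
  expect_equal(gate_no_response(traj(c(100, 1400, 100)))$gate,
               "no_response")
  expect_equal(gate_no_response(traj(c(100, 1500, 100)))$gate, "responder")
  expect_equal(gate_no_response(traj(c(100, 16263, 100)))$gate, "responder")

  tr <- scale_by_max(gate_no_response(traj(c(2000, 4000, 8000))))
  expect_equal(range(tr$scaled), c(0.25, 1))
  trc <- scale_by_max(gate_no_response(traj(c(3000, 3000, 3000))))
  expect_true(all(trc$scaled == 1))
  expect_error(scale_by_max(gate_no_response(traj(c(1, 2, 3)))),
               "responder")
})

test_that("length split and cohort conservation hold", {
  traj_to <- function(last) {
    tr <- interpolate_daily(data.frame(day = c(0, last), tdsa = c(0, 2000)),
                            case_id = paste0("c", last))
    scale_by_max(gate_no_response(tr))
  }
  sp <- split_by_length(list(traj_to(50), traj_to(35)))
  expect_equal(vapply(sp, function(x) x$length_class, ""),
               c("full_50", "short_20_50"))

  co <- make_cohort(n_per_group = c(4L, 3L, 3L, 3L, 3L), seed = 21)
  # add one case too short to include
  extra <- data.frame(case_id = "case_xxx", specificity = "DSA1",
                      day = c(0L, 10L), mfi = c(100, 200))
  pr <- preprocess_cohort(rbind(co$mfi, extra))
  s <- pr$summary
  expect_equal(unname(s["n_gated"] + s["n_full"] + s["n_short"] +
                        s["n_excluded"]),
               unname(s["n_input"]))
  expect_equal(unname(s["n_excluded"]), 1)
  expect_equal(pr$excluded$case_id, "case_xxx")
})

test_that("pre-transplant samples feed only the pre-treatment summary", {
  obs <- data.frame(day = c(-7, -1, 0, 25), tdsa = c(9000, 5000, 100, 200))
  tr <- interpolate_daily(obs)
  expect_equal(tr$pre_treatment_tdsa, 9000)
  expect_equal(min(tr$days), 0)
  expect_equal(max(tr$tdsa), 200)
})
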