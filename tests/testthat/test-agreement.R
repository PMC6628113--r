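test_that("threshold cleaning applies the boundary rules and is idempotent", {
  # staircase: untouched when pen 1 was identified (or never reached)
  expect_equal(clean_threshold(fake_run("staircase", 3.25, NA)), 3.25)
  expect_equal(clean_threshold(fake_run("staircase", 3.25, TRUE)), 3.25)
  # pen 1 presented but never identified: the run overestimates sensitivity
  expect_equal(clean_threshold(fake_run("staircase", 2.0, FALSE)), 1)
  # demanded pen 17: sentinel 16
  expect_equal(clean_threshold(fake_run("staircase", 16, TRUE,
                                        hit_pen17 = TRUE)), 16)
  # quest: clamp out-of-range posterior means
  expect_equal(clean_threshold(fake_run("quest", 0.42)), 1)
  expect_equal(clean_threshold(fake_run("quest", -9.3)), 1)
  expect_equal(clean_threshold(fake_run("quest", 17.8)), 16)
  expect_equal(clean_threshold(fake_run("quest", 7.31)), 7.31)
  # idempotence: a cleaned value is a fixed point of the rules
  for (run in list(fake_run("quest", 0.42), fake_run("staircase", 2, FALSE))) {
    once <- clean_threshold(run)
    run$raw_threshold <- once
    run$pen1_ever_correct <- TRUE
    expect_equal(clean_threshold(run), once)
  }
})

test_that("the TDI score is the sum of the three subtests", {
  expect_equal(tdi_score(7.5, 13, 13), 33.5)
  expect_equal(tdi_score(1, 0, 0), 1)
  expect_equal(tdi_score(16, 16, 16), 48)
  expect_error(tdi_score(0.5, 13, 13), "T")
  expect_error(tdi_score(7, 17, 13), "D")
  expect_error(tdi_score(7, 13, -1), "I")
})

test_that("repeatability summarises paired differences", {
  z <- repeatability(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(z$mean_diff, 0)
  expect_equal(z$rc, 0)
  # frozen from the definition: sd with n-1 denominator, RC = 1.96 sd
  r <- repeatability(c(4, 2, 6, 1), c(2, 4, 4, 3))   # differences 2,-2,2,-2
  expect_equal(r$mean_diff, 0)
  expect_equal(r$sd_diff, 2.3094011, tolerance = 1e-6)
  expect_equal(r$rc, 4.5264261, tolerance = 1e-6)
  expect_equal(r$loa_low, -r$loa_high)
  expect_error(repeatability(1:2, 2:3), "insufficient")
})

test_that("RC is half the width of the limits of agreement", {
  set.seed(601)
  for (i in 1:10) {
    m1 <- rnorm(15, 8, 3); m2 <- m1 + rnorm(15, -0.5, 1.5)
    r <- repeatability(m1, m2)
    expect_equal(r$rc, (r$loa_high - r$loa_low) / 2, tolerance = 1e-12)
    expect_equal(r$mean_diff, mean(m1 - m2))
  }
})

test_that("exact-paired CIs bracket the limits and approach the normal rule", {
  ci <- loa_exact_ci(0.5, 2, 20)
  expect_lt(ci$upper[1], 0.5 + 1.96 * 2)
  expect_gt(ci$upper[2], 0.5 + 1.96 * 2)
  expect_lt(ci$lower[1], 0.5 - 1.96 * 2)
  expect_gt(ci$lower[2], 0.5 - 1.96 * 2)
  # the two limits' intervals mirror each other around the mean difference
  expect_equal(ci$lower, 2 * 0.5 - rev(ci$upper), tolerance = 1e-12)
  # large n: half-width converges to the 1.96 sd sqrt(3/n) approximation
  for (n in c(30, 60, 120)) {
    ci <- loa_exact_ci(0, 1, n)
    hw <- diff(ci$upper) / 2
    approx <- 1.96 * 1 * sqrt(3 / n)
    expect_lt(abs(hw - approx) / approx, 0.1)
  }
  # the interval widens as n shrinks
  w <- vapply(c(40, 20, 10, 5), function(n) diff(loa_exact_ci(0, 1, n)$upper),
              numeric(1))
  expect_true(all(diff(w) > 0))
  expect_error(loa_exact_ci(0, 0, 10), "degenerate")
  expect_error(loa_exact_ci(0, 1, 2), "insufficient")
})

test_that("corrected limits restore within-participant variance", {
  # two participants, methods measured in two sessions each
  co <- corrected_loa(x_test = c(6, 7), x_retest = c(8, 9),
                      y_test = c(5, 6), y_retest = c(7, 8))
  expect_equal(co$mean_diff, 1)
  expect_equal(co$s_dbar_sq, 0)
  expect_equal(co$s_xw_sq, 2)
  expect_equal(co$s_yw_sq, 2)
  expect_equal(co$sigma_d_sq, 2)
  expect_equal(co$loa_low, 1 - 1.96 * sqrt(2), tolerance = 1e-6)   # -1.772
  expect_equal(co$loa_high, 1 + 1.96 * sqrt(2), tolerance = 1e-6)  #  3.772

  # no within-participant variance: reduces to the session-mean limits
  x <- c(5, 9, 7, 6); y <- c(4, 7, 8, 5)
  co2 <- corrected_loa(x, x, y, y)
  r <- repeatability(x, y)
  expect_equal(co2$loa_low, r$loa_low, tolerance = 1e-12)
  expect_equal(co2$loa_high, r$loa_high, tolerance = 1e-12)

  # positive within-variance always widens the limits
  set.seed(602)
  for (i in 1:10) {
    xt <- rnorm(12, 8, 2); xr <- xt + rnorm(12, 0, 1.5)
    yt <- rnorm(12, 7, 2); yr <- yt + rnorm(12, 0, 1.5)
    co3 <- corrected_loa(xt, xr, yt, yr)
    r3 <- repeatability((xt + xr) / 2, (yt + yr) / 2)
    expect_gte(co3$loa_high - co3$loa_low, r3$loa_high - r3$loa_low)
  }
  expect_error(corrected_loa(c(1, NA), c(1, 2), c(1, 2), c(1, 2)), "missing")
})

make_cohort_df <- function(stair_t, stair_r, quest_t, quest_r) {
  n <- length(stair_t)
  ids <- sprintf("P%02d", seq_len(n))
  out <- rbind(
    data.frame(participant_id = ids, session = "test", procedure = "staircase",
               cleaned_threshold = stair_t),
    data.frame(participant_id = ids, session = "retest", procedure = "staircase",
               cleaned_threshold = stair_r),
    data.frame(participant_id = ids, session = "test", procedure = "quest",
               cleaned_threshold = quest_t),
    data.frame(participant_id = ids, session = "retest", procedure = "quest",
               cleaned_threshold = quest_r))
  class(out) <- c("cohort", "data.frame")
  out
}

test_that("reliability reports assemble the paired statistics", {
  set.seed(603)
  st <- round(runif(20, 2, 14), 1)
  co <- make_cohort_df(st, st, pmax(1, st - 1.5), pmax(1, st - 1.2))
  rep1 <- reliability_report(co, "testretest", "staircase")
  expect_equal(rep1$spearman$rho, 1)            # identical test and retest
  expect_equal(rep1$agreement$mean_diff, 0)
  expect_equal(rep1$agreement$rc, 0)
  expect_equal(rep1$ols$slope, 1, tolerance = 1e-9)

  co2 <- make_cohort_df(st, st + rnorm(20, -0.4, 1), pmax(1, st - 1.5),
                        pmax(1, st - 1.5) + rnorm(20, -0.8, 1))
  rep2 <- reliability_report(co2, "testretest", "quest")
  expect_true(abs(rep2$spearman$rho) <= 1)
  expect_equal(rep2$n, 20)
  # the report's agreement must match a direct repeatability computation
  pairs_q <- with(co2[co2$procedure == "quest", ],
                  split(cleaned_threshold, session))
  direct <- repeatability(pairs_q$test, pairs_q$retest)
  expect_equal(rep2$agreement$mean_diff, direct$mean_diff)
  expect_equal(rep2$agreement$rc, direct$rc)

  cmp <- reliability_report(co2, "compare")
  expect_false(is.null(cmp$corrected))
  expect_gte(cmp$corrected$loa_high - cmp$corrected$loa_low,
             cmp$agreement$loa_high - cmp$agreement$loa_low)
  # inter-session interval correlation is attached when supplied
  rep3 <- reliability_report(co2, "testretest", "staircase",
                             intervals = runif(20, 1, 9))
  expect_true(!is.null(rep3$interval_correlation))

  expect_error(reliability_report(co2[co2$participant_id %in% c("P01", "P02"), ],
                                  "testretest", "staircase"), "insufficient")
  const <- make_cohort_df(rep(4, 5), rep(4, 5), rep(3, 5), rep(3, 5))
  expect_error(reliability_report(const, "testretest", "staircase"),
               "undefined statistic")
})

test_that("trial counts convert to minutes at 28.5 s per trial", {
  expect_equal(estimate_duration(20), 9.5)
  expect_equal(estimate_duration(0), 0)
  expect_equal(estimate_duration(23.6), 23.6 * 28.5 / 60)  # 11.21 min
  expect_error(estimate_duration(-1), "non-negative")
})
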