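point_mass_at <- function(state, value) {
  j <- which.min(abs(state$grid - value))
  lp <- rep(-1e6, length(state$grid))
  lp[j] <- 0
  state$log_posterior <- lp - log(sum(exp(lp)))
  state
}

test_that("the prior is centred on the start pen and near-flat", {
  st <- quest_init(quest_config())
  expect_equal(quest_estimate(st), 7, tolerance = 0.01)
  post <- exp(st$log_posterior)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  # SD 20 on a grid spanning +/- 1.5 SD: density ratio exp(1.5^2/2) ~ 3.1
  expect_lt(max(post) / min(post), 10)
  expect_error(quest_init(quest_config(grid_step = 100)), "degenerate grid")
  expect_error(quest_config(grid_lo = 2), "pen range")
  expect_error(quest_config(n_trials = 0), "n_trials")
})

test_that("proposals round to the nearest pen, ties toward stronger, and clamp", {
  st <- quest_init(quest_config())
  expect_equal(as.integer(quest_propose(point_mass_at(st, 11.4))), 11L)
  expect_equal(as.integer(quest_propose(point_mass_at(st, 11.6))), 12L)
  expect_equal(as.integer(quest_propose(point_mass_at(st, 9.5))), 9L)
  expect_equal(as.integer(quest_propose(point_mass_at(st, 0.3))), 1L)   # clamp low
  expect_equal(as.integer(quest_propose(point_mass_at(st, 24.9))), 16L) # clamp high
})

test_that("the consecutive-trial override moves off a repeated pen", {
  st <- quest_init(quest_config())
  st <- point_mass_at(st, 9.2)
  with_history <- function(state, pens, correct) {
    state$history <- data.frame(trial_index = seq_along(pens),
                                proposed_level = NA_real_,
                                presented_pen = pens, correct = correct)
    state
  }
  # two corrects at pen 9 -> weaker (10), two errors -> stronger (8)
  expect_equal(as.integer(quest_propose(with_history(st, c(9L, 9L), c(TRUE, TRUE)))), 10L)
  expect_equal(as.integer(quest_propose(with_history(st, c(9L, 9L), c(FALSE, FALSE)))), 8L)
  # mixed responses or different pens: no override
  expect_equal(as.integer(quest_propose(with_history(st, c(9L, 9L), c(TRUE, FALSE)))), 9L)
  expect_equal(as.integer(quest_propose(with_history(st, c(8L, 9L), c(TRUE, TRUE)))), 9L)
  # override result is clamped into the pen range
  st16 <- point_mass_at(st, 15.8)
  expect_equal(as.integer(quest_propose(with_history(st16, c(16L, 16L), c(TRUE, TRUE)))), 16L)
  st1 <- point_mass_at(st, 1.2)
  expect_equal(as.integer(quest_propose(with_history(st1, c(1L, 1L), c(FALSE, FALSE)))), 1L)
})

test_that("posterior updates are normalized, monotone and commutative", {
  st <- quest_init(quest_config())
  m0 <- quest_estimate(st)
  up <- quest_update(st, 8L, TRUE)
  expect_equal(sum(exp(up$log_posterior)), 1, tolerance = 1e-12)
  expect_gt(quest_estimate(up), m0)            # correct -> weaker (higher T)
  down <- quest_update(st, 8L, FALSE)
  expect_lt(quest_estimate(down), m0)          # incorrect -> stronger
  ab <- quest_update(quest_update(st, 5L, TRUE), 12L, FALSE)
  ba <- quest_update(quest_update(st, 12L, FALSE), 5L, TRUE)
  expect_equal(ab$log_posterior, ba$log_posterior, tolerance = 1e-12)
  expect_error(quest_update(st, 0L, TRUE), "presented_pen")
  expect_error(quest_update(st, 8L, NA), "correct")
})

test_that("short runs match an independent brute-force Bayes oracle", {
  cfg <- quest_config(grid_step = 0.5, grid_lo = -3, grid_hi = 20,
                      n_trials = 5L)
  set.seed(301)
  for (rep in 1:5) {
    st <- quest_init(cfg)
    trials <- data.frame(pen = integer(0), correct = logical(0))
    for (i in 1:5) {
      pen <- as.integer(quest_propose(st))
      correct <- runif(1) < 0.5
      st <- quest_update(st, pen, correct)
      trials <- rbind(trials, data.frame(pen = pen, correct = correct))
    }
    oracle <- brute_posterior(st$grid, trials, prior_mean = 7, prior_sd = 20)
    expect_equal(exp(st$log_posterior), oracle, tolerance = 1e-10)
    expect_equal(quest_estimate(st), sum(st$grid * oracle), tolerance = 1e-10)
  }
})

test_that("degenerate response streams drive the estimate off-range", {
  r1 <- quest_run(responder = function(pen) TRUE, seed = 1)
  expect_equal(nrow(r1$trials), 20L)
  expect_true(all(diff(r1$trials$presented_pen) >= 0))  # walks up, then clamps
  expect_gt(r1$raw_threshold, 16)
  expect_equal(r1$cleaned_threshold, 16)
  r2 <- quest_run(responder = function(pen) FALSE, seed = 1)
  expect_lt(r2$raw_threshold, 1)
  expect_equal(r2$cleaned_threshold, 1)
  expect_false(r2$pen1_ever_correct)
})

test_that("runs are reproducible from the seed", {
  obs <- make_responder(observer("guesser"))
  a <- quest_run(responder = obs, seed = 77)
  b <- quest_run(responder = obs, seed = 77)
  expect_identical(a$trials, b$trials)
  expect_identical(a$raw_threshold, b$raw_threshold)
  c <- quest_run(responder = obs, seed = 78)
  expect_false(identical(a$trials, c$trials))
})

test_that("proposals are refused once the trial budget is exhausted", {
  cfg <- quest_config(n_trials = 2L)
  st <- quest_init(cfg)
  st <- quest_update(st, 7L, TRUE)
  st <- quest_update(st, 8L, FALSE)
  expect_error(quest_propose(st), "complete")
})
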