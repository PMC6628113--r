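# Shared test helpers: scripted responders and independent oracles.

# A responder that replays a fixed TRUE/FALSE sequence, erroring when
# exhausted (so unexpected extra trials surface as failures).
scripted_responder <- function(responses) {
  i <- 0L
  function(pen) {
    i <<- i + 1L
    if (i > length(responses)) stop("scripted responder exhausted")
    responses[i]
  }
}

# Independent brute-force Bayes oracle for the adaptive engine: evaluates
# the Weibull likelihood directly from the formula (anchored so that the
# threshold parameter is the level of the target probability) and multiplies
# prior x likelihoods without any log-space bookkeeping.
brute_posterior <- function(grid, trials, prior_mean, prior_sd,
                            beta_pen = 3.5 * log10(2), guess = 1/3,
                            lapse = 0.01, target_p = 0.8) {
  offset <- log10(-log((1 - (target_p - lapse * guess) / (1 - lapse)) /
                         (1 - guess))) / beta_pen
  psi <- function(pen, T) {
    lapse * guess + (1 - lapse) *
      (1 - (1 - guess) * exp(-10^(beta_pen * (T + offset - pen))))
  }
  w <- dnorm(grid, prior_mean, prior_sd)
  for (k in seq_len(nrow(trials))) {
    p <- psi(trials$pen[k], grid)
    w <- w * if (trials$correct[k]) p else 1 - p
  }
  w / sum(w)
}

# Independent replay oracle for the one-up/two-down phase-B rules, written
# as a direct transcription of the protocol (no shared code with the
# engine).  Returns the reversal pens in order.
replay_phase_b <- function(start_pen, responses, n_reversals = 7) {
  pen <- start_pen
  cc <- 0L
  dir <- NA
  revs <- integer(0)
  for (r in responses) {
    if (r) {
      cc <- cc + 1L
      if (cc < 2L) next
      cc <- 0L
      newdir <- +1L
    } else {
      cc <- 0L
      newdir <- -1L
    }
    if (!is.na(dir) && newdir != dir) {
      revs <- c(revs, pen)
      if (length(revs) == n_reversals) return(revs)
    }
    dir <- newdir
    pen <- max(1L, min(16L, pen + newdir))
  }
  revs
}

# Minimal fabricated threshold_run for testing the cleaning rules without
# running an engine.
fake_run <- function(procedure, raw, pen1_ever_correct = NA,
                     hit_pen17 = FALSE) {
  trials <- data.frame(trial_index = 1L, phase = "B", proposed_level = NA,
                       presented_pen = 8L, target_position = 1L,
                       correct = TRUE)
  threshold_run(procedure = procedure, trials = trials, raw_threshold = raw,
                pen1_ever_correct = pen1_ever_correct,
                hit_pen17 = hit_pen17)
}
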