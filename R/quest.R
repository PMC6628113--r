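#' Configuration of the Bayesian adaptive (QUEST-style) procedure
#'
#' Holds the assumed psychometric function, the threshold grid, the prior,
#' and the stopping rule of the Bayesian adaptive threshold procedure.  The
#' procedure maintains a posterior over candidate thresholds on a fine grid,
#' presents the discrete pen closest to the current estimate (clamped into
#' the physical pen range), and reports the posterior mean after a fixed
#' number of trials.
#'
#' Defaults follow the protocol this package implements: assumed slope 3.5,
#' guess rate 1/3, lapse 0.01, threshold targeted at 80% correct, prior
#' normal with SD 20 pen units centred on pen 7, grid step 0.01, 20 trials.
#' The grid spans `start_pen` +/- 1.5 prior SDs by default, wide enough to
#' represent final estimates below pen 1 or above pen 16, which occur and
#' are handled by the data-cleaning rules.
#'
#' @param beta,guess,lapse,target_p,slope_unit,pen_step Assumed psychometric
#'   function; see [weibull_pf()].
#' @param start_pen Prior mean / starting concentration, pen units (default 7).
#' @param prior_sd Prior standard deviation, pen units (default 20).
#' @param grid_step Grid granularity, pen units (default 0.01).
#' @param grid_lo,grid_hi Grid range, pen units (defaults `start_pen` -/+
#'   `1.5 * prior_sd`, i.e. -23 and 37).
#' @param n_trials Fixed number of trials (default 20).
#' @param n_pens Number of physical pens (default 16).
#' @param placement Where to place the next stimulus: posterior `"mean"`
#'   (default), `"mode"`, or `"quantile"`.
#' @param placement_quantile Quantile used when `placement = "quantile"`.
#' @return An object of class `"quest_config"`.
#' @export
quest_config <- function(beta = 3.5, guess = 1/3, lapse = 0.01,
                         target_p = 0.80, slope_unit = c("log10", "pen"),
                         pen_step = log10(2), start_pen = 7, prior_sd = 20,
                         grid_step = 0.01,
                         grid_lo = start_pen - 1.5 * prior_sd,
                         grid_hi = start_pen + 1.5 * prior_sd,
                         n_trials = 20L, n_pens = 16L,
                         placement = c("mean", "mode", "quantile"),
                         placement_quantile = 0.5) {
  placement <- match.arg(placement)
  n_trials <- as.integer(n_trials)
  n_pens <- as.integer(n_pens)
  if (n_trials < 1L) stop("'n_trials' must be at least 1")
  if (grid_step <= 0) stop("'grid_step' must be positive")
  if (!(grid_lo < 1 && n_pens < grid_hi))
    stop("the grid must contain the physical pen range [1, n_pens]")
  if (prior_sd <= 0) stop("'prior_sd' must be positive")
  slope_unit <- match.arg(slope_unit)
  structure(list(beta = beta, guess = guess, lapse = lapse,
                 target_p = target_p, slope_unit = slope_unit,
                 pen_step = pen_step, start_pen = start_pen,
                 prior_sd = prior_sd, grid_step = grid_step,
                 grid_lo = grid_lo, grid_hi = grid_hi,
                 n_trials = n_trials, n_pens = n_pens,
                 placement = placement,
                 placement_quantile = placement_quantile),
            class = "quest_config")
}

#' Initialize a Bayesian adaptive run
#'
#' Builds the threshold grid, evaluates the normal prior on it (normalized),
#' and precomputes the per-pen likelihoods of a correct response for every
#' grid candidate under the assumed psychometric function.
#'
#' @param config A [quest_config()] object.
#' @return An object of class `"quest_state"` with elements `grid`,
#'   `log_posterior` (normalized so the posterior sums to 1), `history`
#'   (a data frame of trials), and `config`.
#' @export
quest_init <- function(config = quest_config()) {
  if (!inherits(config, "quest_config")) stop("'config' must be a quest_config")
  grid <- seq(config$grid_lo, config$grid_hi, by = config$grid_step)
  if (length(grid) < 2L) stop("degenerate grid: fewer than 2 candidate thresholds")
  lp <- stats::dnorm(grid, mean = config$start_pen, sd = config$prior_sd,
                     log = TRUE)
  lp <- lp - logsumexp(lp)
  ## likelihood of a correct response at pen i given candidate threshold j
  lik <- matrix(NA_real_, nrow = config$n_pens, ncol = length(grid))
  pf0 <- weibull_pf(0, beta = config$beta, guess = config$guess,
                    lapse = config$lapse, target_p = config$target_p,
                    slope_unit = config$slope_unit,
                    pen_step = config$pen_step)
  ## p_correct(pen; T_j) depends on T_j - pen only: evaluate the zero-
  ## threshold function at pen - T_j
  for (pen in seq_len(config$n_pens))
    lik[pen, ] <- p_correct(pen - grid, pf0)
  structure(list(config = config, grid = grid, log_posterior = lp,
                 lik_correct = lik, history = empty_quest_history()),
            class = "quest_state")
}

empty_quest_history <- function() {
  data.frame(trial_index = integer(), proposed_level = numeric(),
             presented_pen = integer(), correct = logical())
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## Invoke a responder; if it fails, abort the run but preserve the partial
## trial log on the error condition (field 'partial_log').
responder_call <- function(responder, pen, i, partial) {
  tryCatch(isTRUE(responder(pen)), error = function(e)
    stop(errorCondition(
      sprintf("responder failed at trial %d: %s", i, conditionMessage(e)),
      class = "olfquest_responder_error", partial_log = partial(i - 1L))))
}

#' Current threshold estimate of a Bayesian adaptive run
#'
#' The probability-weighted mean of the grid candidates under the current
#' posterior (the final estimate after the last trial).  May lie outside the
#' physical pen range `[1, 16]`; see [clean_threshold()].
#'
#' @param state A `"quest_state"`.
#' @param type `"mean"` (default), `"mode"`, or `"quantile"`.
#' @param prob Quantile level when `type = "quantile"`.
#' @return Threshold estimate, real-valued pen units.
#' @export
quest_estimate <- function(state, type = c("mean", "mode", "quantile"),
                           prob = 0.5) {
  if (!inherits(state, "quest_state")) stop("'state' must be a quest_state")
  type <- match.arg(type)
  post <- exp(state$log_posterior)
  switch(type,
         mean = sum(state$grid * post),
         mode = state$grid[which.max(post)],
         quantile = state$grid[which(cumsum(post) >= prob)[1L]])
}

#' Propose the next pen to present
#'
#' Computes the raw proposal (the current posterior estimate under the
#' configured placement rule), rounds it to the nearest integer pen (ties
#' toward the stronger, lower-numbered pen), clamps it into the physical pen
#' range, and applies the consecutive-trial override: if the two most recent
#' trials presented the same pen and both were correct, the next pen is one
#' step weaker (+1); if both were incorrect, one step stronger (-1).  The
#' override result is clamped again.
#'
#' @param state A `"quest_state"` with fewer than `n_trials` completed trials.
#' @return Integer pen number in `[1, n_pens]`, with the unrounded proposal
#'   attached as attribute `"proposed_level"`.
#' @export
quest_propose <- function(state) {
  if (!inherits(state, "quest_state")) stop("'state' must be a quest_state")
  cfg <- state$config
  if (nrow(state$history) >= cfg$n_trials)
    stop("run already complete: no further trials to propose")
  raw <- quest_estimate(state, type = cfg$placement,
                        prob = cfg$placement_quantile)
  ## ties (x.5) round toward the stronger (lower-numbered) pen
  pen <- as.integer(ceiling(raw - 0.5))
  pen <- min(max(pen, 1L), cfg$n_pens)
  h <- state$history
  n <- nrow(h)
  if (n >= 2L && h$presented_pen[n] == h$presented_pen[n - 1L]) {
    if (h$correct[n] && h$correct[n - 1L]) {
      pen <- h$presented_pen[n] + 1L        # both correct: go weaker
    } else if (!h$correct[n] && !h$correct[n - 1L]) {
      pen <- h$presented_pen[n] - 1L        # both incorrect: go stronger
    }
    pen <- min(max(pen, 1L), cfg$n_pens)
  }
  structure(pen, proposed_level = raw)
}

#' Update the posterior with an observed response
#'
#' Multiplies the posterior, candidate-wise, by the likelihood of the
#' observed response at the presented pen (the full response history is
#' thereby always taken into account), renormalizes, and appends the trial
#' to the history.
#'
#' @param state A `"quest_state"`.
#' @param presented_pen Integer pen in `[1, n_pens]` actually presented.
#' @param correct Logical response flag.
#' @param proposed_level Optional unrounded proposal to record in the history.
#' @return The updated `"quest_state"`.
#' @export
quest_update <- function(state, presented_pen, correct,
                         proposed_level = NA_real_) {
  if (!inherits(state, "quest_state")) stop("'state' must be a quest_state")
  cfg <- state$config
  presented_pen <- as.integer(presented_pen)
  if (length(presented_pen) != 1L || is.na(presented_pen) ||
      presented_pen < 1L || presented_pen > cfg$n_pens)
    stop(sprintf("'presented_pen' must be a single integer in [1, %d]",
                 cfg$n_pens))
  if (!is.logical(correct) || length(correct) != 1L || is.na(correct))
    stop("'correct' must be TRUE or FALSE")
  p <- state$lik_correct[presented_pen, ]
  lp <- state$log_posterior + log(if (correct) p else 1 - p)
  z <- logsumexp(lp)
  if (!is.finite(z)) stop("posterior lost all mass during update")
  state$log_posterior <- lp - z
  state$history <- rbind(state$history, data.frame(
    trial_index = nrow(state$history) + 1L,
    proposed_level = proposed_level,
    presented_pen = presented_pen,
    correct = correct))
  state
}

#' Run a complete Bayesian adaptive threshold measurement
#'
#' Executes exactly `n_trials` trials: each trial proposes a pen
#' ([quest_propose()]), draws the position of the odorant pen within the
#' triplet uniformly at random, obtains a response from `responder`, and
#' updates the posterior.  The final raw threshold is the posterior mean.
#'
#' @param config A [quest_config()].
#' @param responder A function `function(pen) -> logical`: whether the
#'   response at that pen was correct.  See [make_responder()].
#' @param seed Optional integer seed; when supplied the run is bit-for-bit
#'   reproducible.  When `NULL` the ambient RNG stream is used (so that
#'   callers such as [generate_cohort()] control seeding themselves).
#' @return A [threshold_run] object.
#' @export
quest_run <- function(config = quest_config(), responder, seed = NULL) {
  if (!is.function(responder)) stop("'responder' must be a function(pen)")
  if (!is.null(seed)) set.seed(seed)
  state <- quest_init(config)
  n <- config$n_trials
  pens <- integer(n); props <- numeric(n); pos <- integer(n); corr <- logical(n)
  for (i in seq_len(n)) {
    pen <- quest_propose(state)
    props[i] <- attr(pen, "proposed_level")
    pens[i] <- as.integer(pen)
    pos[i] <- sample.int(3L, 1L)
    corr[i] <- responder_call(responder, pens[i], i, function(k)
      data.frame(trial_index = seq_len(k), phase = NA_character_,
                 proposed_level = props[seq_len(k)],
                 presented_pen = pens[seq_len(k)],
                 target_position = pos[seq_len(k)],
                 correct = corr[seq_len(k)]))
    state <- quest_update(state, pens[i], corr[i], proposed_level = props[i])
  }
  trials <- data.frame(trial_index = seq_len(n), phase = NA_character_,
                       proposed_level = props, presented_pen = pens,
                       target_position = pos, correct = corr)
  threshold_run(procedure = "quest", trials = trials,
                raw_threshold = quest_estimate(state),
                pen1_ever_correct = any(pens == 1L & corr),
                hit_pen17 = FALSE, seed = seed, config = config,
                n_trials_phase_b = n)
}
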