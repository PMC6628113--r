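#' Configuration of the one-up/two-down staircase procedure
#'
#' The standard Sniffin' Sticks threshold protocol: a starting-concentration
#' phase ("phase A") beginning at the weakest pens and moving up in steps of
#' two until a pen is identified correctly twice in a row, followed by the
#' threshold staircase proper ("phase B"): one step stronger after each
#' incorrect response (one-up), one step weaker after two consecutive
#' correct responses at the same pen (two-down).  The run terminates after
#' `n_reversals` direction reversals; the raw threshold is the mean of the
#' last `n_average` reversal pens.  This rule converges, asymptotically, on
#' the stimulus level identified correctly in about 70.71% of trials
#' (\eqn{\sqrt{1/2}}).
#'
#' @param start_pen Starting pen of phase A, 16 or 15 (balanced across
#'   participants in cohort use).
#' @param step_a Phase-A step size in pens (default 2).
#' @param step_b Phase-B step size in pens (default 1).
#' @param n_reversals Reversals required to terminate (default 7).
#' @param n_average Reversals averaged into the threshold (default 4).
#' @param max_trials Global trial cap guarding against non-terminating runs
#'   of pure guessers (default 200).
#' @return An object of class `"staircase_config"`.
#' @export
staircase_config <- function(start_pen = 16L, step_a = 2L, step_b = 1L,
                             n_reversals = 7L, n_average = 4L,
                             max_trials = 200L) {
  start_pen <- as.integer(start_pen)
  if (!start_pen %in% c(15L, 16L)) stop("'start_pen' must be 15 or 16")
  if (n_average > n_reversals) stop("'n_average' cannot exceed 'n_reversals'")
  if (max_trials < 1L) stop("'max_trials' must be positive")
  structure(list(start_pen = start_pen, step_a = as.integer(step_a),
                 step_b = as.integer(step_b),
                 n_reversals = as.integer(n_reversals),
                 n_average = as.integer(n_average),
                 max_trials = as.integer(max_trials), n_pens = 16L),
            class = "staircase_config")
}

#' Initialize a staircase run
#'
#' @param config A [staircase_config()].
#' @return An object of class `"staircase_state"`.
#' @export
staircase_init <- function(config = staircase_config()) {
  if (!inherits(config, "staircase_config"))
    stop("'config' must be a staircase_config")
  structure(list(config = config, phase = "A",
                 current_pen = config$start_pen, consecutive_correct = 0L,
                 direction = NA_character_, reversal_pens = integer(),
                 pen1_presented = FALSE, pen1_ever_correct = FALSE,
                 hit_pen17 = FALSE, terminated = FALSE,
                 n_trials_a = 0L, n_trials_b = 0L),
            class = "staircase_state")
}

track_pen1 <- function(state, correct) {
  if (state$current_pen == 1L) {
    state$pen1_presented <- TRUE
    if (correct) state$pen1_ever_correct <- TRUE
  }
  state
}

#' Advance the starting-concentration phase by one response
#'
#' Phase A begins at the weakest pens and increases concentration in steps
#' of two (e.g. pen 16 to 14) after each incorrect response.  After a first
#' correct response the same pen is repeated; a second consecutive correct
#' response at that pen makes it the starting concentration and switches the
#' run to phase B.  A correct response followed by an incorrect one resets
#' the counter and moves two pens stronger.  Pen 1 is a hard floor: the run
#' keeps presenting pen 1 until it is identified.
#'
#' @param state A `"staircase_state"` in phase A.
#' @param correct Logical response flag for the current pen.
#' @return The updated state.
#' @export
phase_a_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$phase != "A") stop("'state' is not in phase A")
  state <- track_pen1(state, correct)
  state$n_trials_a <- state$n_trials_a + 1L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct == 2L) {
      state$phase <- "B"
      state$consecutive_correct <- 0L
      state$direction <- NA_character_
    }
  } else {
    state$consecutive_correct <- 0L
    state$current_pen <- max(1L, state$current_pen - state$config$step_a)
  }
  state
}

#' Advance the threshold staircase by one response
#'
#' One-up/two-down: an incorrect response demands a move one step stronger
#' (pen - 1, clamped at pen 1); two consecutive correct responses at the
#' same pen demand a move one step weaker (pen + 1).  A reversal is recorded
#' at the current pen (before moving) whenever the demanded direction
#' differs from the previously demanded direction; the starting
#' concentration itself is not counted as a reversal.  Reaching
#' `n_reversals` terminates the run.  A demanded move beyond the weakest pen
#' (a hypothetical pen 17) sets `hit_pen17` and terminates the run; a
#' demanded move below pen 1 is clamped (pen 1 is presented again).
#'
#' @param state A `"staircase_state"` in phase B.
#' @param correct Logical response flag for the current pen.
#' @return The updated state.
#' @export
phase_b_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$phase != "B") stop("'state' is not in phase B")
  if (state$terminated) stop("run already terminated")
  state <- track_pen1(state, correct)
  state$n_trials_b <- state$n_trials_b + 1L
  cfg <- state$config
  move <- 0L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct == 2L) {
      state$consecutive_correct <- 0L
      move <- +cfg$step_b                               # two-down: weaker
      new_dir <- "weaker"
    } else return(state)                                # repeat the same pen
  } else {
    state$consecutive_correct <- 0L
    move <- -cfg$step_b                                 # one-up: stronger
    new_dir <- "stronger"
  }
  if (!is.na(state$direction) && new_dir != state$direction) {
    state$reversal_pens <- c(state$reversal_pens, state$current_pen)
    if (length(state$reversal_pens) >= cfg$n_reversals) {
      state$direction <- new_dir
      state$terminated <- TRUE
      return(state)
    }
  }
  state$direction <- new_dir
  demanded <- state$current_pen + move
  if (demanded > cfg$n_pens) {
    state$hit_pen17 <- TRUE
    state$terminated <- TRUE
  } else {
    state$current_pen <- max(1L, demanded)
  }
  state
}

#' Raw threshold of a terminated staircase
#'
#' The arithmetic mean of the last `n_average` reversal pens.  If the run
#' terminated because it demanded a pen beyond the weakest one
#' (`hit_pen17`), the sentinel value 16 is returned.
#'
#' @param state A terminated `"staircase_state"`.
#' @return Raw threshold, pen units.
#' @export
staircase_finalize <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  if (!state$terminated)
    stop("staircase has not terminated: reversals or pen-17 demand required")
  if (state$hit_pen17) return(16)
  mean(utils::tail(state$reversal_pens, state$config$n_average))
}

#' Position of the odorant pen within a triplet
#'
#' During the staircase the position of the odorant pen cycles
#' deterministically through the triplet: first, middle, last, repeating
#' every three trials.  (The Bayesian adaptive procedure instead draws the
#' position uniformly at random.)
#'
#' @param trial_index 1-based trial number(s).
#' @return Position(s) in `{1, 2, 3}`.
#' @export
target_position <- function(trial_index) {
  if (any(trial_index < 1L)) stop("'trial_index' must be at least 1")
  ((as.integer(trial_index) - 1L) %% 3L) + 1L
}

#' Run a complete staircase threshold measurement
#'
#' Runs phase A (starting concentration) and then phase B (one-up/two-down
#' staircase) to termination against a responder callback.  Trial counts
#' are recorded separately per phase: reported trial counts for this
#' procedure conventionally cover phase B only.
#'
#' @param config A [staircase_config()].
#' @param responder A function `function(pen) -> logical`; see
#'   [make_responder()].
#' @param seed Optional integer seed (see [quest_run()] for the convention).
#' @return A [threshold_run] object.  If the trial cap is reached before
#'   termination the run is flagged `aborted` and the raw threshold is `NA`
#'   (the cleaning rules may still assign a value, e.g. pen 1 never
#'   identified).
#' @export
staircase_run <- function(config = staircase_config(), responder,
                          seed = NULL) {
  if (!is.function(responder)) stop("'responder' must be a function(pen)")
  if (!is.null(seed)) set.seed(seed)
  state <- staircase_init(config)
  idx <- pens <- pos <- integer(0); phase <- character(0); corr <- logical(0)
  i <- 0L
  while (!state$terminated && i < config$max_trials) {
    i <- i + 1L
    pen <- state$current_pen
    correct <- responder_call(responder, pen, i, function(k)
      data.frame(trial_index = idx, phase = phase, proposed_level = NA_real_,
                 presented_pen = pens, target_position = pos,
                 correct = corr))
    idx <- c(idx, i); pens <- c(pens, pen); phase <- c(phase, state$phase)
    pos <- c(pos, target_position(i)); corr <- c(corr, correct)
    state <- if (state$phase == "A") phase_a_step(state, correct)
             else phase_b_step(state, correct)
  }
  aborted <- !state$terminated
  trials <- data.frame(trial_index = idx, phase = phase,
                       proposed_level = NA_real_, presented_pen = pens,
                       target_position = pos, correct = corr)
  threshold_run(procedure = "staircase", trials = trials,
                raw_threshold = if (aborted) NA_real_
                                else staircase_finalize(state),
                pen1_ever_correct = if (state$pen1_presented)
                                      state$pen1_ever_correct else NA,
                hit_pen17 = state$hit_pen17, seed = seed, config = config,
                n_trials_phase_b = state$n_trials_b,
                reversals = state$reversal_pens, aborted = aborted)
}
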