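#' A simulated 3-AFC responder
#'
#' Two kinds of observer are available: a `"weibull"` observer that answers
#' correctly with probability given by its psychometric function
#' ([p_correct()]), and a `"guesser"` that answers correctly with the bare
#' chance probability of the 3-AFC task (1/3), modelling a participant who
#' never perceives the odorant.
#'
#' @param kind `"weibull"` or `"guesser"`.
#' @param pf A [weibull_pf()] (required for `kind = "weibull"`).
#' @return An object of class `"observer"`.
#' @export
observer <- function(kind = c("weibull", "guesser"), pf = NULL) {
  kind <- match.arg(kind)
  if (kind == "weibull") {
    if (!inherits(pf, "weibull_pf"))
      stop("a 'weibull' observer needs a weibull_pf in 'pf'")
  } else {
    pf <- NULL
  }
  structure(list(kind = kind, pf = pf), class = "observer")
}

#' Draw one response from a simulated observer
#'
#' Consumes exactly one uniform draw from the current RNG stream and returns
#' whether the simulated response at `pen` was correct.
#'
#' @param pen Pen number presented.
#' @param obs An [observer()].
#' @return Logical: correct response?
#' @export
observer_respond <- function(pen, obs) {
  if (!inherits(obs, "observer")) stop("'obs' must be an observer")
  p <- if (obs$kind == "guesser") 1 / 3 else p_correct(pen, obs$pf)
  stats::runif(1L) < p
}

#' Turn an observer into a responder callback
#'
#' @param obs An [observer()].
#' @return A function `function(pen) -> logical` suitable for
#'   [quest_run()] and [staircase_run()].
#' @export
make_responder <- function(obs) {
  force(obs)
  function(pen) observer_respond(pen, obs)
}

#' Specification of a synthetic test-retest cohort
#'
#' Defines the generative model for a synthetic cohort emulating a two-
#' session (test/retest), two-procedure (staircase/QUEST) threshold study:
#' per-participant true thresholds drawn on the pen axis, a systematic
#' sensitivity shift at retest, session-to-session within-participant
#' drift, and trial responses from a Weibull 3-AFC observer.  Defaults are
#' calibrated to the scale of reported threshold summaries in studies of
#' this design (mean near pen 7, between-participant SD near 3, roughly one
#' pen of retest gain); they are modelling conventions, not estimates.
#'
#' @param n_participants Cohort size (default 36).
#' @param true_threshold_mean,true_threshold_sd Normal distribution of true
#'   test-session thresholds, pen units (defaults 7 and 3); draws are
#'   clipped to `[1, 16]`.
#' @param within_sd Within-participant session-to-session drift SD, pen
#'   units (default 2).
#' @param retest_shift Systematic true-threshold shift at retest, pen units
#'   (default +1: higher pen number = greater sensitivity).
#' @param observer_beta,observer_guess,observer_lapse,target_p,observer_slope_unit
#'   Observer psychometric function parameters (defaults 3.5 per log10
#'   concentration unit, 1/3, 0.01, 0.80); see [weibull_pf()].
#' @param seed Integer seed controlling every random draw of the cohort.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_participants = 36L, true_threshold_mean = 7,
                        true_threshold_sd = 3, within_sd = 2,
                        retest_shift = 1, observer_beta = 3.5,
                        observer_guess = 1/3, observer_lapse = 0.01,
                        target_p = 0.80,
                        observer_slope_unit = c("log10", "pen"),
                        seed = 1L) {
  observer_slope_unit <- match.arg(observer_slope_unit)
  n_participants <- as.integer(n_participants)
  if (n_participants < 1L) stop("'n_participants' must be positive")
  if (true_threshold_sd < 0 || within_sd < 0)
    stop("standard deviations must be non-negative")
  structure(list(n_participants = n_participants,
                 true_threshold_mean = true_threshold_mean,
                 true_threshold_sd = true_threshold_sd,
                 within_sd = within_sd, retest_shift = retest_shift,
                 observer_beta = observer_beta,
                 observer_guess = observer_guess,
                 observer_lapse = observer_lapse, target_p = target_p,
                 observer_slope_unit = observer_slope_unit,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

clip_pen <- function(x, lo = 1, hi = 16) pmin(pmax(x, lo), hi)

#' Generate a synthetic test-retest cohort
#'
#' For each participant a true test-session threshold is drawn from
#' `N(true_threshold_mean, true_threshold_sd)` and clipped to `[1, 16]`;
#' the retest true threshold adds `retest_shift` plus `N(0, within_sd)`
#' drift (clipped again).  Both procedures are then run in both sessions
#' against the participant's Weibull observer.  Staircase starting pens
#' (16 or 15) are balanced across participants.  The whole cohort is a
#' deterministic function of `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param quest_cfg,staircase_cfg Engine configurations; staircase
#'   `start_pen` is overridden by the balancing scheme.
#' @return A data frame of class `"cohort"` with one row per participant x
#'   session x procedure: `participant_id`, `session` (`test`/`retest`),
#'   `procedure`, `true_threshold`, `raw_threshold`, `cleaned_threshold`,
#'   `n_trials`, `n_trials_phase_b`, `pen1_ever_correct`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            quest_cfg = quest_config(),
                            staircase_cfg = staircase_config()) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec")
  set.seed(spec$seed)
  n <- spec$n_participants
  true_test <- clip_pen(stats::rnorm(n, spec$true_threshold_mean,
                                     spec$true_threshold_sd))
  true_retest <- clip_pen(true_test + spec$retest_shift +
                          stats::rnorm(n, 0, spec$within_sd))
  rows <- vector("list", n * 4L)
  k <- 0L
  for (i in seq_len(n)) {
    sc_cfg <- staircase_cfg
    sc_cfg$start_pen <- if (i %% 2L == 1L) 16L else 15L
    for (session in c("test", "retest")) {
      tru <- if (session == "test") true_test[i] else true_retest[i]
      pf <- weibull_pf(tru, beta = spec$observer_beta,
                       guess = spec$observer_guess,
                       lapse = spec$observer_lapse,
                       target_p = spec$target_p,
                       slope_unit = spec$observer_slope_unit)
      resp <- make_responder(observer("weibull", pf))
      for (procedure in c("staircase", "quest")) {
        run <- if (procedure == "staircase")
                 staircase_run(sc_cfg, resp)
               else quest_run(quest_cfg, resp)
        k <- k + 1L
        rows[[k]] <- data.frame(
          participant_id = sprintf("P%03d", i), session = session,
          procedure = procedure, true_threshold = tru,
          raw_threshold = run$raw_threshold,
          cleaned_threshold = run$cleaned_threshold,
          n_trials = run$n_trials,
          n_trials_phase_b = run$n_trials_phase_b,
          pen1_ever_correct = run$pen1_ever_correct)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  class(out) <- c("cohort", "data.frame")
  out
}
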