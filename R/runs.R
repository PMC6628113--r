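#' A completed threshold measurement
#'
#' Container for one finished adaptive run: the procedure id, the full trial
#' log, the raw threshold estimate (real-valued; QUEST estimates may lie
#' outside the physical pen range), the cleaned threshold (see
#' [clean_threshold()]), the boundary flags needed by the cleaning rules,
#' the seed, and an echo of the configuration.
#'
#' @param procedure `"staircase"` or `"quest"`.
#' @param trials Data frame of trial records.
#' @param raw_threshold Raw threshold estimate, pen units (may be `NA` for
#'   aborted runs).
#' @param pen1_ever_correct Was pen 1 ever presented *and* correctly
#'   identified during the run?  (`NA` when pen 1 was never presented.)
#' @param hit_pen17 Did the staircase demand a (non-existent) pen beyond the
#'   weakest one?
#' @param seed Seed used for the run, or `NULL`.
#' @param config Configuration object echo.
#' @param n_trials_phase_b Number of trials in the threshold-estimation
#'   phase (the full run for QUEST; phase B only for the staircase, matching
#'   how trial counts are reported).
#' @param reversals Reversal pens of a staircase run (in order), or `NULL`.
#' @param aborted Was the run stopped by the trial cap before termination?
#' @return An object of class `"threshold_run"`.
#' @export
threshold_run <- function(procedure, trials, raw_threshold,
                          pen1_ever_correct, hit_pen17 = FALSE, seed = NULL,
                          config = NULL, n_trials_phase_b = nrow(trials),
                          reversals = NULL, aborted = FALSE) {
  procedure <- match.arg(procedure, c("staircase", "quest"))
  run <- structure(list(procedure = procedure, trials = trials,
                        raw_threshold = raw_threshold,
                        cleaned_threshold = NA_real_,
                        pen1_ever_correct = pen1_ever_correct,
                        hit_pen17 = isTRUE(hit_pen17), seed = seed,
                        config = config, reversals = reversals,
                        n_trials = nrow(trials),
                        n_trials_phase_b = n_trials_phase_b,
                        aborted = isTRUE(aborted), terminated = !isTRUE(aborted)),
                   class = "threshold_run")
  run$cleaned_threshold <- clean_threshold(run)
  run
}

#' @export
print.threshold_run <- function(x, ...) {
  cat(sprintf("<threshold_run> %s: %d trials, raw %.3f, cleaned %.3f\n",
              x$procedure, x$n_trials,
              if (is.na(x$raw_threshold)) NA_real_ else x$raw_threshold,
              x$cleaned_threshold))
  if (x$aborted) cat("  (aborted at trial cap)\n")
  invisible(x)
}
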