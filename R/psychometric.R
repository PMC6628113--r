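#' The Sniffin' Sticks pen dilution scale
#'
#' Describes the discrete dilution series of the threshold pen set: `n_pens`
#' odorant pens whose concentrations form a geometric sequence starting at
#' `top_dilution` percent v/v at pen 1 and dividing by `ratio` for each
#' subsequent pen. Pen 1 is the strongest stimulus, pen `n_pens` the weakest.
#'
#' @param n_pens Number of odorant pens in the set (default 16).
#' @param top_dilution Concentration at pen 1, percent v/v (default 4).
#' @param ratio Dilution factor between adjacent pens (default 2).
#' @return An object of class `"pen_scale"`.
#' @examples
#' sc <- pen_scale()
#' pen_concentration(1:3, sc)  # 4, 2, 1
#' @export
pen_scale <- function(n_pens = 16L, top_dilution = 4, ratio = 2) {
  n_pens <- as.integer(n_pens)
  if (n_pens < 2L) stop("'n_pens' must be at least 2")
  if (top_dilution <= 0) stop("'top_dilution' must be positive")
  if (ratio <= 1) stop("'ratio' must exceed 1 (concentration must decrease)")
  structure(list(n_pens = n_pens, top_dilution = top_dilution, ratio = ratio),
            class = "pen_scale")
}

#' Concentration of a pen
#'
#' Maps pen numbers to odorant concentration in percent v/v:
#' `top_dilution * ratio^-(pen - 1)`.
#'
#' @param pen Integer pen number(s) in `[1, n_pens]`.
#' @param scale A [pen_scale()] object.
#' @return Concentration(s), percent v/v.
#' @export
pen_concentration <- function(pen, scale = pen_scale()) {
  if (!inherits(scale, "pen_scale")) stop("'scale' must be a pen_scale object")
  if (length(pen) == 0L || anyNA(pen) || any(pen != as.integer(pen)))
    stop("'pen' must be integer-valued")
  if (any(pen < 1L | pen > scale$n_pens))
    stop(sprintf("'pen' must lie in [1, %d]", scale$n_pens))
  scale$top_dilution * scale$ratio^(-(pen - 1))
}

## Location (on the pen axis, relative to the exp-argument = -1 anchor) of the
## level where the Weibull 3-AFC function attains probability p.  Positive
## values are stronger than the anchor on the internal x = -pen axis, i.e. the
## returned offset is subtracted from the anchor pen to obtain the level.
## 'beta_pen' is the effective slope per pen step.
pf_offset <- function(p, beta_pen, guess, lapse) {
  inner <- (1 - (p - lapse * guess) / (1 - lapse)) / (1 - guess)
  log10(-log(inner)) / beta_pen
}

#' Weibull psychometric function parameters for a forced-choice task
#'
#' Bundles the parameters of the Weibull psychometric function used
#' throughout the package,
#' \deqn{\Psi(x) = \lambda\gamma + (1-\lambda)\left[1 - (1-\gamma)
#'   \exp\!\left(-10^{\beta (x + T)}\right)\right],}
#' with the stimulus intensity \eqn{x} oriented so that lower pen numbers
#' (stronger stimuli) give higher probabilities of a correct response.
#' \eqn{\gamma} is the chance level of the forced-choice task (1/3 for the
#' 3-AFC pen triplets), \eqn{\lambda} the lapse rate, and \eqn{\beta} the
#' slope.
#'
#' By convention (`slope_unit = "log10"`, the standard Weibull
#' parametrization in adaptive psychophysics) `beta` is expressed per unit
#' of \eqn{\log_{10}} concentration; the pens form a geometric dilution
#' series with ratio 2, so one pen step spans \eqn{\log_{10} 2 \approx
#' 0.301} of those units and the effective slope per pen is
#' \eqn{\beta \log_{10} 2}.  With `slope_unit = "pen"`, `beta` is taken
#' per pen step directly.
#'
#' The stored `threshold` is anchored at a target probability: it is the pen
#' level at which the function equals `target_p` (0.80 by default, the level
#' the Bayesian adaptive procedure is set to target).  The function's range
#' is the open interval \eqn{(\gamma,\; \lambda\gamma + 1 - \lambda)}; with
#' \eqn{\gamma = 1/3} and \eqn{\lambda = 0.01} it extends from 0.33 to 0.99.
#'
#' @param threshold Pen level at which the function equals `target_p`.
#' @param beta Slope (default 3.5 per log10 concentration unit).
#' @param guess Guess rate \eqn{\gamma} (default 1/3, 3-AFC).
#' @param lapse Lapse rate \eqn{\lambda} (default 0.01).
#' @param target_p Probability defining the threshold anchor (default 0.80).
#' @param slope_unit `"log10"` (per log10 concentration unit, default) or
#'   `"pen"` (per pen step).
#' @param pen_step Log10-concentration span of one pen step (default
#'   `log10(2)`; only used for `slope_unit = "log10"`).
#' @return An object of class `"weibull_pf"`.
#' @seealso [p_correct()], [level_at_p()]
#' @export
weibull_pf <- function(threshold, beta = 3.5, guess = 1/3, lapse = 0.01,
                       target_p = 0.80, slope_unit = c("log10", "pen"),
                       pen_step = log10(2)) {
  slope_unit <- match.arg(slope_unit)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a finite number (pen units)")
  if (beta <= 0) stop("'beta' must be positive")
  if (guess < 0 || guess >= 1) stop("'guess' must lie in [0, 1)")
  if (lapse < 0 || lapse >= 0.5) stop("'lapse' must lie in [0, 0.5)")
  if (pen_step <= 0) stop("'pen_step' must be positive")
  lo <- guess
  hi <- lapse * guess + (1 - lapse)
  if (target_p <= lo || target_p >= hi)
    stop(sprintf("'target_p' must lie strictly inside (%.4f, %.4f)", lo, hi))
  beta_pen <- if (slope_unit == "log10") beta * pen_step else beta
  ## pen level of the exp-argument = -1 point; the target_p level sits
  ## pf_offset(target_p) pen units *below* (stronger than) the anchor
  anchor <- threshold + pf_offset(target_p, beta_pen, guess, lapse)
  structure(list(threshold = threshold, beta = beta, guess = guess,
                 lapse = lapse, target_p = target_p,
                 slope_unit = slope_unit, pen_step = pen_step,
                 beta_pen = beta_pen, anchor = anchor),
            class = "weibull_pf")
}

#' @export
print.weibull_pf <- function(x, ...) {
  cat(sprintf(
    "Weibull psychometric function: threshold %.3f pens (at p = %.2f), beta %.2f per %s unit, guess %.3f, lapse %.3f\n",
    x$threshold, x$target_p, x$beta,
    if (x$slope_unit == "log10") "log10 concentration" else "pen",
    x$guess, x$lapse))
  invisible(x)
}

#' Probability of a correct response at a given pen level
#'
#' Evaluates the Weibull psychometric function at (possibly real-valued)
#' positions on the pen axis.  The function is strictly decreasing in pen
#' number: pen 1 is the strongest stimulus.
#'
#' @param pen Pen level(s); real values are allowed (threshold candidates and
#'   estimates live on the continuous pen axis).
#' @param pf A [weibull_pf()] object.
#' @return Probability (or vector of probabilities) of a correct response.
#' @examples
#' pf <- weibull_pf(threshold = 8)
#' p_correct(8, pf)       # 0.80 by construction
#' p_correct(1e6, pf)     # -> guess rate 1/3
#' @export
p_correct <- function(pen, pf) {
  if (!inherits(pf, "weibull_pf")) stop("'pf' must be a weibull_pf object")
  s <- pf$beta_pen * (pf$anchor - pen)
  pf$lapse * pf$guess +
    (1 - pf$lapse) * (1 - (1 - pf$guess) * exp(-10^s))
}

#' Pen level attaining a given probability correct
#'
#' Closed-form inverse of [p_correct()]: the unique pen level at which the
#' psychometric function equals `p`.  Defined only for `p` strictly inside
#' the function's open range \eqn{(\gamma, \lambda\gamma + 1 - \lambda)}.
#'
#' @param p Target probability (scalar or vector).
#' @param pf A [weibull_pf()] object.
#' @return Pen level(s), real-valued.
#' @export
level_at_p <- function(p, pf) {
  if (!inherits(pf, "weibull_pf")) stop("'pf' must be a weibull_pf object")
  lo <- pf$guess
  hi <- pf$lapse * pf$guess + (1 - pf$lapse)
  if (any(p <= lo | p >= hi))
    stop(sprintf("'p' must lie strictly inside the attainable range (%.6f, %.6f)",
                 lo, hi))
  pf$anchor - pf_offset(p, pf$beta_pen, pf$guess, pf$lapse)
}
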