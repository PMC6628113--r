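#' Clean a raw threshold estimate
#'
#' Applies the boundary rules used before any reliability statistic is
#' computed.  For the staircase: a run in which pen 1 was presented but
#' never correctly identified systematically overestimates sensitivity and
#' is set to `T = 1`; a run that demanded a pen beyond the weakest one is
#' set to `T = 16`.  For the Bayesian adaptive procedure, whose posterior-
#' mean estimate can leave the physical range, estimates below pen 1 are
#' set to 1 and above pen 16 to 16.  Cleaning is idempotent and always
#' yields a value in `[1, 16]` (or `NA` for an aborted run with no
#' applicable rule).
#'
#' @param run A [threshold_run] object.
#' @return Cleaned threshold in `[1, 16]` (possibly `NA`).
#' @export
clean_threshold <- function(run) {
  if (!inherits(run, "threshold_run")) stop("'run' must be a threshold_run")
  if (!run$terminated && !run$aborted)
    stop("run has not terminated")
  if (run$procedure == "staircase") {
    if (isFALSE(run$pen1_ever_correct)) return(1)
    if (run$hit_pen17) return(16)
    return(run$raw_threshold)
  }
  ## quest: clamp out-of-range posterior means
  if (is.na(run$raw_threshold)) return(NA_real_)
  min(max(run$raw_threshold, 1), 16)
}

#' Composite TDI score
#'
#' The sum of the three Sniffin' Sticks subtest results: threshold T (1-16),
#' discrimination D (0-16), and identification I (0-16); range 1-48.
#'
#' @param T Threshold score in `[1, 16]`.
#' @param D Discrimination score in `[0, 16]`.
#' @param I Identification score in `[0, 16]`.
#' @return The cumulative TDI score.
#' @export
tdi_score <- function(T, D, I) {
  if (any(T < 1 | T > 16)) stop("'T' must lie in [1, 16]")
  if (any(D < 0 | D > 16)) stop("'D' must lie in [0, 16]")
  if (any(I < 0 | I > 16)) stop("'I' must lie in [0, 16]")
  T + D + I
}

#' Exact-paired confidence intervals for limits of agreement
#'
#' Two-sided confidence intervals for the Bland-Altman limits of agreement
#' \eqn{\bar d \pm 1.96\,s_d} from the exact (noncentral-t) characterization:
#' \eqn{\sqrt{n}(\mu + 1.96\sigma - \bar d)/s_d} follows a noncentral t
#' distribution with \eqn{n - 1} degrees of freedom and noncentrality
#' \eqn{1.96\sqrt{n}}, so the CI for the upper limit is
#' \eqn{\bar d + t'_{\alpha/2, 1-\alpha/2}\, s_d/\sqrt{n}} with noncentral-t
#' quantiles \eqn{t'}; the lower limit's CI follows by symmetry.
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff Sample SD (n-1 denominator) of the differences.
#' @param n Number of pairs.
#' @param conf Two-sided confidence level (default 0.95).
#' @param z Multiplier defining the limits (default 1.96).
#' @return A list with `lower` and `upper`, each a length-2 numeric vector
#'   (CI bounds for that limit of agreement).
#' @export
loa_exact_ci <- function(mean_diff, sd_diff, n, conf = 0.95, z = 1.96) {
  if (n < 3L) stop("insufficient data: at least 3 pairs required")
  if (!is.finite(sd_diff) || sd_diff <= 0)
    stop("degenerate data: 'sd_diff' must be positive")
  alpha <- 1 - conf
  ## qt's noncentral algorithm reports its ~1e-8 accuracy as a warning;
  ## that is far below the precision meaningful for an agreement interval
  q <- suppressWarnings(
    stats::qt(c(alpha / 2, 1 - alpha / 2), df = n - 1L,
              ncp = z * sqrt(n))) / sqrt(n)
  list(lower = mean_diff - rev(q) * sd_diff,
       upper = mean_diff + q * sd_diff)
}

#' Repeatability and limits of agreement for paired measurements
#'
#' Computes the Bland-Altman summary of two paired measurements per
#' subject: the mean difference \eqn{\bar d = \mathrm{mean}(m_1 - m_2)},
#' the sample SD of the differences, the repeatability coefficient
#' \eqn{RC = 1.96\,SD} (95% of repeat differences are expected to fall
#' within it), the limits of agreement \eqn{\bar d \pm 1.96\,SD}, a
#' t-based CI for the mean difference, and exact-paired CIs for each limit
#' ([loa_exact_ci()]).
#'
#' @param m1,m2 Paired measurement vectors (differences are `m1 - m2`).
#' @param conf Confidence level for the CIs (default 0.95).
#' @param z Limit multiplier (default 1.96).
#' @return An object of class `"agreement"` with fields `mean_diff`,
#'   `sd_diff`, `rc`, `loa_low`, `loa_high`, `ci_mean`, `ci_low`,
#'   `ci_high`, `n`, and the means of the pairs (`pair_means`) and
#'   differences (`diffs`) for plotting.
#' @export
repeatability <- function(m1, m2, conf = 0.95, z = 1.96) {
  if (length(m1) != length(m2)) stop("'m1' and 'm2' must have equal length")
  ok <- is.finite(m1) & is.finite(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  n <- length(m1)
  if (n < 3L) stop("insufficient data: at least 3 complete pairs required")
  d <- m1 - m2
  dbar <- mean(d)
  s <- stats::sd(d)
  ci_mean <- dbar + c(-1, 1) * stats::qt(1 - (1 - conf) / 2, n - 1L) *
    s / sqrt(n)
  ci <- if (s > 0) loa_exact_ci(dbar, s, n, conf = conf, z = z)
        else list(lower = c(NA_real_, NA_real_), upper = c(NA_real_, NA_real_))
  structure(list(mean_diff = dbar, sd_diff = s, rc = z * s,
                 loa_low = dbar - z * s, loa_high = dbar + z * s,
                 ci_mean = ci_mean, ci_low = ci$lower, ci_high = ci$upper,
                 n = n, z = z, conf = conf,
                 pair_means = (m1 + m2) / 2, diffs = d),
            class = "agreement")
}

#' @export
print.agreement <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement of %d pairs\n", x$n))
  cat(sprintf("  mean difference: %.*f [%.*f, %.*f]\n", digits, x$mean_diff,
              digits, x$ci_mean[1], digits, x$ci_mean[2]))
  cat(sprintf("  SD of differences: %.*f   RC: %.*f\n", digits, x$sd_diff,
              digits, x$rc))
  cat(sprintf("  limits of agreement: %.*f [%.*f, %.*f] and %.*f [%.*f, %.*f]\n",
              digits, x$loa_low, digits, x$ci_low[1], digits, x$ci_low[2],
              digits, x$loa_high, digits, x$ci_high[1], digits, x$ci_high[2]))
  invisible(x)
}

#' Bland-Altman plot of an agreement object
#'
#' Differences against pair means, with the mean difference and the limits
#' of agreement as horizontal lines and their confidence intervals shaded.
#'
#' @param x An `"agreement"` object from [repeatability()].
#' @param xlab,ylab,main Plot annotation.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.agreement <- function(x, xlab = "Mean of measurements",
                           ylab = "Difference", main = "Bland-Altman plot",
                           ...) {
  rng <- range(c(x$diffs, x$ci_low, x$ci_high), na.rm = TRUE)
  graphics::plot(x$pair_means, x$diffs, xlab = xlab, ylab = ylab,
                 main = main, ylim = rng, pch = 19, ...)
  usr <- graphics::par("usr")
  shade <- function(ci) if (all(is.finite(ci)))
    graphics::rect(usr[1], ci[1], usr[2], ci[2],
                   col = grDevices::adjustcolor("grey", 0.4), border = NA)
  shade(x$ci_low); shade(x$ci_high); shade(x$ci_mean)
  graphics::abline(h = c(x$mean_diff, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Variance-corrected limits of agreement for two methods measured twice
#'
#' When two methods are compared through per-participant session means, the
#' averaging removes within-participant variability and the resulting
#' limits of agreement are too narrow.  The corrected between-method
#' variance restores it:
#' \deqn{\sigma_d^2 = s_{\bar d}^2 + \tfrac12 s_{xw}^2 + \tfrac12 s_{yw}^2,}
#' where \eqn{s_{\bar d}^2} is the variance of the per-participant
#' differences of session means and \eqn{s_{xw}^2, s_{yw}^2} are the
#' within-participant variances of each method, estimated from the two
#' sessions as \eqn{\sum_i (x_{i1} - x_{i2})^2 / (2n)}.  The corrected
#' limits are \eqn{\bar d \pm 1.96\,\sigma_d}.  Approximate delta-method
#' CIs for the limits combine the variance of \eqn{\bar d} with the
#' delta-method variance of \eqn{1.96\,\hat\sigma_d} from the three
#' variance components.
#'
#' @param x_test,x_retest Method x measurements, one pair per participant.
#' @param y_test,y_retest Method y measurements, aligned with method x.
#' @param conf Confidence level (default 0.95).
#' @param z Limit multiplier (default 1.96).
#' @return An object of class `"corrected_loa"` with fields `mean_diff`,
#'   `s_dbar_sq`, `s_xw_sq`, `s_yw_sq`, `sigma_d_sq`, `loa_low`,
#'   `loa_high`, `ci_low`, `ci_high`, `n`.
#' @export
corrected_loa <- function(x_test, x_retest, y_test, y_retest,
                          conf = 0.95, z = 1.96) {
  n <- length(x_test)
  if (any(lengths(list(x_retest, y_test, y_retest)) != n))
    stop("all four measurement vectors must have equal length")
  if (n < 2L) stop("insufficient data: at least 2 participants required")
  if (anyNA(c(x_test, x_retest, y_test, y_retest)))
    stop("missing cells: every participant needs both sessions for both methods")
  d <- (x_test + x_retest) / 2 - (y_test + y_retest) / 2
  dbar <- mean(d)
  s_dbar_sq <- stats::var(d)
  s_xw_sq <- sum((x_test - x_retest)^2) / (2 * n)
  s_yw_sq <- sum((y_test - y_retest)^2) / (2 * n)
  sigma_d_sq <- s_dbar_sq + 0.5 * s_xw_sq + 0.5 * s_yw_sq
  sigma_d <- sqrt(sigma_d_sq)
  ## delta-method variance of the limits: Var(dbar) + z^2 Var(sigma_d),
  ## with Var(sigma_d^2) from the chi-square variances of the components
  ## (n-1 df for s_dbar^2; n df for each within-method sum of squares)
  var_sig2 <- 2 * s_dbar_sq^2 / (n - 1) +
    0.25 * 2 * s_xw_sq^2 / n + 0.25 * 2 * s_yw_sq^2 / n
  se_limit <- sqrt(s_dbar_sq / n +
                   if (sigma_d_sq > 0) z^2 * var_sig2 / (4 * sigma_d_sq) else 0)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  loa <- dbar + c(-1, 1) * z * sigma_d
  structure(list(mean_diff = dbar, s_dbar_sq = s_dbar_sq,
                 s_xw_sq = s_xw_sq, s_yw_sq = s_yw_sq,
                 sigma_d_sq = sigma_d_sq,
                 loa_low = loa[1], loa_high = loa[2],
                 ci_low = loa[1] + c(-1, 1) * zq * se_limit,
                 ci_high = loa[2] + c(-1, 1) * zq * se_limit,
                 n = n, z = z, conf = conf),
            class = "corrected_loa")
}

#' @export
print.corrected_loa <- function(x, digits = 3, ...) {
  cat(sprintf("Corrected limits of agreement (%d participants)\n", x$n))
  cat(sprintf("  sigma_d^2 = %.*f (s_dbar^2 %.*f + 0.5 x %.*f + 0.5 x %.*f)\n",
              digits, x$sigma_d_sq, digits, x$s_dbar_sq, digits, x$s_xw_sq,
              digits, x$s_yw_sq))
  cat(sprintf("  limits: %.*f [%.*f, %.*f] and %.*f [%.*f, %.*f]\n",
              digits, x$loa_low, digits, x$ci_low[1], digits, x$ci_low[2],
              digits, x$loa_high, digits, x$ci_high[1], digits, x$ci_high[2]))
  invisible(x)
}

#' Test duration implied by a trial count
#'
#' Converts a number of trials to an approximate duration in minutes at
#' 28.5 s per trial (a 20-trial run lasts exactly 9.5 minutes).
#'
#' @param n_trials Trial count(s), possibly fractional (e.g. a mean).
#' @return Duration(s) in minutes.
#' @export
estimate_duration <- function(n_trials) {
  if (any(n_trials < 0)) stop("'n_trials' must be non-negative")
  n_trials * 28.5 / 60
}

cohort_pairs <- function(cohort, procedure) {
  x <- cohort[cohort$procedure == procedure, ]
  wide <- merge(x[x$session == "test",
                  c("participant_id", "cleaned_threshold")],
                x[x$session == "retest",
                  c("participant_id", "cleaned_threshold")],
                by = "participant_id", suffixes = c("_test", "_retest"))
  wide[order(wide$participant_id), ]
}

#' Test-retest or between-procedure reliability report
#'
#' Assembles the reliability analysis for a cohort: paired Wilcoxon
#' signed-rank test of the means, Spearman rank correlation, an OLS fit of
#' the second measurement on the first with a Shapiro-Wilk normality check
#' of the residuals, descriptive summaries, the repeatability/limits-of-
#' agreement analysis ([repeatability()]), and - for the between-procedure
#' mode - the variance-corrected limits ([corrected_loa()]).  Cleaning is
#' applied before every statistic: all analyses use `cleaned_threshold`.
#'
#' Pairings: `mode = "testretest"` compares test vs retest within
#' `procedure` (differences test - retest); `mode = "compare"` compares
#' per-participant session means, staircase - quest.
#'
#' @param cohort A `"cohort"` data frame (see [generate_cohort()],
#'   [read_cohort()]).
#' @param mode `"testretest"` or `"compare"`.
#' @param procedure Procedure analysed in `"testretest"` mode.
#' @param intervals Optional per-participant inter-session intervals (days),
#'   correlated (Spearman) against the test - retest differences.
#' @return An object of class `"reliability_report"`.
#' @export
reliability_report <- function(cohort,
                               mode = c("testretest", "compare"),
                               procedure = c("staircase", "quest"),
                               intervals = NULL) {
  mode <- match.arg(mode)
  procedure <- match.arg(procedure)
  if (!all(c("participant_id", "session", "procedure",
             "cleaned_threshold") %in% names(cohort)))
    stop("'cohort' lacks required columns")
  if (mode == "testretest") {
    wide <- cohort_pairs(cohort, procedure)
    a <- wide$cleaned_threshold_test
    b <- wide$cleaned_threshold_retest
    labels <- c("test", "retest")
  } else {
    ws <- cohort_pairs(cohort, "staircase")
    wq <- cohort_pairs(cohort, "quest")
    wide <- merge(ws, wq, by = "participant_id", suffixes = c("_s", "_q"))
    a <- (wide$cleaned_threshold_test_s + wide$cleaned_threshold_retest_s) / 2
    b <- (wide$cleaned_threshold_test_q + wide$cleaned_threshold_retest_q) / 2
    labels <- c("staircase", "quest")
  }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) stop("insufficient data: at least 3 complete participants required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined statistic: constant input to rank statistics")
  wil <- tryCatch(suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)),
                  error = function(e)   # e.g. all paired differences zero
                    list(statistic = NA_real_, p.value = NA_real_))
  sp <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  fit <- stats::lm(b ~ a)
  res_sw <- stats::shapiro.test(stats::residuals(fit))
  agr <- repeatability(a, b)
  interval_cor <- NULL
  if (!is.null(intervals)) {
    if (length(intervals) != n)
      stop("'intervals' must supply one value per complete participant")
    interval_cor <- suppressWarnings(
      stats::cor.test(intervals, a - b, method = "spearman"))
  }
  corrected <- NULL
  if (mode == "compare") {
    if (!all(ok))
      stop("missing cells: corrected limits need both sessions for both methods")
    corrected <- corrected_loa(wide$cleaned_threshold_test_s,
                               wide$cleaned_threshold_retest_s,
                               wide$cleaned_threshold_test_q,
                               wide$cleaned_threshold_retest_q)
  }
  structure(list(
    mode = mode, procedure = if (mode == "testretest") procedure else NA,
    labels = labels, n = n,
    means = c(mean(a), mean(b)), sds = c(stats::sd(a), stats::sd(b)),
    shapiro = list(first = stats::shapiro.test(a),
                   second = stats::shapiro.test(b)),
    wilcoxon = list(statistic = unname(wil$statistic), p = wil$p.value),
    spearman = list(rho = unname(sp$estimate), p = sp$p.value),
    ols = list(intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               residual_shapiro_w = unname(res_sw$statistic),
               residual_shapiro_p = res_sw$p.value),
    agreement = agr, corrected = corrected,
    interval_correlation = if (is.null(interval_cor)) NULL else
      list(rho = unname(interval_cor$estimate), p = interval_cor$p.value)),
    class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, digits = 3, ...) {
  cat(sprintf("Reliability report (%s%s), n = %d\n", x$mode,
              if (!is.na(x$procedure)) paste0(", ", x$procedure) else "",
              x$n))
  cat(sprintf("  %s: mean %.*f (SD %.*f); %s: mean %.*f (SD %.*f)\n",
              x$labels[1], digits, x$means[1], digits, x$sds[1],
              x$labels[2], digits, x$means[2], digits, x$sds[2]))
  cat(sprintf("  Wilcoxon V = %.1f, p = %.3g;  Spearman rho = %.*f, p = %.3g\n",
              x$wilcoxon$statistic, x$wilcoxon$p, digits, x$spearman$rho,
              x$spearman$p))
  cat(sprintf("  OLS: %s = %.*f + %.*f x %s (residual Shapiro-Wilk p = %.3g)\n",
              x$labels[2], digits, x$ols$intercept, digits, x$ols$slope,
              x$labels[1], x$ols$residual_shapiro_p))
  print(x$agreement, digits = digits)
  if (!is.null(x$corrected)) print(x$corrected, digits = digits)
  invisible(x)
}
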