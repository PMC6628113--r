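TRIAL_LOG_COLUMNS <- c("participant_id", "session", "procedure",
                       "trial_index", "phase", "proposed_level",
                       "presented_pen", "target_position", "correct")

#' Write a trial log to CSV
#'
#' Writes trial records with a fixed header (`participant_id`, `session`,
#' `procedure`, `trial_index`, `phase`, `proposed_level`, `presented_pen`,
#' `target_position`, `correct`), UTF-8, '.' decimal separator.  Numeric
#' columns are serialized with shortest round-trip representation, so
#' `read_trial_log(write_trial_log(x))` reproduces `x` exactly.
#'
#' @param records A data frame of trial records (e.g. the `trials` element
#'   of a [threshold_run], or [run_trial_records()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  for (col in setdiff(TRIAL_LOG_COLUMNS, names(records)))
    records[[col]] <- NA
  records <- records[TRIAL_LOG_COLUMNS]
  records$correct <- as.integer(records$correct)
  records$proposed_level <- as.character(records$proposed_level)
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(records, utf8, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trial log written by [write_trial_log()]
#'
#' @param path CSV file path.
#' @return A data frame of trial records.  Malformed rows (non-integer pen,
#'   pen outside `[1, 16]`, non-increasing trial index within a run) raise
#'   a parse error naming the offending line.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character",
                       na.strings = c("NA", ""), encoding = "UTF-8")
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(x))
  if (length(missing))
    stop(sprintf("trial log %s lacks columns: %s", path,
                 paste(missing, collapse = ", ")))
  x <- x[TRIAL_LOG_COLUMNS]
  x$trial_index <- suppressWarnings(as.integer(x$trial_index))
  x$target_position <- suppressWarnings(as.integer(x$target_position))
  pen <- suppressWarnings(as.numeric(x$presented_pen))
  bad <- which(!is.finite(pen) | pen != as.integer(pen) | pen < 1 | pen > 16)
  if (length(bad))
    stop(sprintf("parse error in %s, line %d: invalid presented_pen '%s'",
                 path, bad[1] + 1L, x$presented_pen[bad[1]]))
  if (nrow(x)) {
    runs <- interaction(x$participant_id, x$session, x$procedure, drop = TRUE)
    for (r in split(seq_len(nrow(x)), runs)) {
      ti <- x$trial_index[r]
      if (any(diff(ti) <= 0))
        stop(sprintf("parse error in %s, line %d: trial_index not increasing",
                     path, r[which(diff(ti) <= 0)[1] + 1L] + 1L))
    }
  }
  x$presented_pen <- as.integer(pen)
  x$proposed_level <- suppressWarnings(as.numeric(x$proposed_level))
  x$correct <- as.logical(as.integer(x$correct))
  x
}

#' Trial records of a run, annotated for logging
#'
#' @param run A [threshold_run].
#' @param participant_id,session Identifiers to stamp onto the records.
#' @return A data frame in the trial-log schema.
#' @export
run_trial_records <- function(run, participant_id = "sim",
                              session = "test") {
  tr <- run$trials
  tr$participant_id <- participant_id
  tr$session <- session
  tr$procedure <- run$procedure
  tr[TRIAL_LOG_COLUMNS]
}

COHORT_COLUMNS <- c("participant_id", "session", "procedure",
                    "raw_threshold", "cleaned_threshold", "n_trials",
                    "n_trials_phase_b", "pen1_ever_correct")

#' Write / read a cohort dataset as CSV
#'
#' The cohort schema has one row per participant x session x procedure;
#' optional columns (`true_threshold`, `D`, `I`,
#' `inter_session_interval_days`) are preserved when present.
#'
#' @param cohort A `"cohort"` data frame.
#' @param path CSV file path.
#' @return `path` invisibly (write); the cohort data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  keep <- c(COHORT_COLUMNS,
            intersect(c("true_threshold", "D", "I",
                        "inter_session_interval_days"), names(cohort)))
  x <- as.data.frame(cohort)[keep]
  for (col in c("raw_threshold", "cleaned_threshold", "true_threshold"))
    if (col %in% names(x)) x[[col]] <- as.character(x[[col]])
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(x, utf8, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(COHORT_COLUMNS, names(x))
  if (length(missing))
    stop(sprintf("cohort file %s lacks columns: %s", path,
                 paste(missing, collapse = ", ")))
  key <- paste(x$participant_id, x$session, x$procedure)
  if (anyDuplicated(key))
    stop(sprintf("cohort file %s has duplicate participant/session/procedure rows",
                 path))
  x$pen1_ever_correct <- as.logical(x$pen1_ever_correct)
  class(x) <- c("cohort", "data.frame")
  x
}

#' Load a deposited threshold dataset
#'
#' Adapter for externally deposited per-run threshold records (e.g. a
#' study archive downloaded by the user; nothing is ever downloaded
#' implicitly).  Accepts a CSV file, or a directory containing exactly one
#' CSV, with flexibly named columns, and maps them onto the cohort schema.
#' Recognized (case-insensitive) aliases:
#' participant: `participant_id`, `participant`, `subject`, `id`;
#' session: `session`, `visit` (values matched to test/retest);
#' procedure: `procedure`, `method`, `algorithm` (staircase/quest);
#' threshold: `cleaned_threshold`, `threshold`, `threshold_estimate`, `T`.
#'
#' @param path CSV file or directory holding the deposited records.
#' @return A `"cohort"` data frame.
#' @export
load_deposited <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (dir.exists(path)) {
    csvs <- list.files(path, pattern = "\\.csv$", full.names = TRUE,
                       recursive = TRUE)
    if (length(csvs) != 1L)
      stop(sprintf("expected exactly one CSV under %s, found %d",
                   path, length(csvs)))
    path <- csvs
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  nm <- tolower(names(x))
  pick <- function(aliases) {
    hit <- which(nm %in% aliases)
    if (length(hit)) hit[1] else NA_integer_
  }
  cols <- c(participant_id = pick(c("participant_id", "participant",
                                    "subject", "id")),
            session = pick(c("session", "visit")),
            procedure = pick(c("procedure", "method", "algorithm")),
            threshold = pick(c("cleaned_threshold", "threshold",
                               "threshold_estimate", "t")))
  if (anyNA(cols))
    stop(sprintf(
      "unrecognized deposited-data layout in %s: need %s; found columns: %s",
      path, paste(names(cols)[is.na(cols)], collapse = ", "),
      paste(names(x), collapse = ", ")))
  out <- data.frame(
    participant_id = as.character(x[[cols["participant_id"]]]),
    session = normalize_values(x[[cols["session"]]],
                               c(test = "test", t1 = "test", "1" = "test",
                                 retest = "retest", t2 = "retest",
                                 "2" = "retest")),
    procedure = normalize_values(x[[cols["procedure"]]],
                                 c(staircase = "staircase",
                                   quest = "quest")),
    raw_threshold = as.numeric(x[[cols["threshold"]]]),
    stringsAsFactors = FALSE)
  out$cleaned_threshold <- clip_pen(out$raw_threshold)
  out$n_trials <- if ("n_trials" %in% nm) x[[which(nm == "n_trials")[1]]]
                  else NA_integer_
  out$n_trials_phase_b <- if ("n_trials_phase_b" %in% nm)
    x[[which(nm == "n_trials_phase_b")[1]]] else NA_integer_
  out$pen1_ever_correct <- if ("pen1_ever_correct" %in% nm)
    as.logical(x[[which(nm == "pen1_ever_correct")[1]]]) else NA
  for (opt in c("d", "i", "inter_session_interval_days"))
    if (opt %in% nm) out[[toupper(substr(opt, 1, 1))]] <-
      x[[which(nm == opt)[1]]]
  class(out) <- c("cohort", "data.frame")
  out
}

normalize_values <- function(x, map) {
  v <- unname(map[tolower(trimws(as.character(x)))])
  if (anyNA(v))
    stop(sprintf("unrecognized values: %s (expected one of %s)",
                 paste(unique(x[is.na(v)]), collapse = ", "),
                 paste(unique(map), collapse = "/")))
  v
}

#' Serialize a reliability report to JSON
#'
#' @param report A `"reliability_report"`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  agr <- report$agreement
  x <- list(
    mode = report$mode, procedure = report$procedure, n = report$n,
    labels = report$labels, means = report$means, sds = report$sds,
    wilcoxon = report$wilcoxon, spearman = report$spearman,
    ols = report$ols,
    agreement = list(mean_diff = agr$mean_diff, sd_diff = agr$sd_diff,
                     rc = agr$rc, loa_low = agr$loa_low,
                     loa_high = agr$loa_high, ci_mean = agr$ci_mean,
                     ci_low = agr$ci_low, ci_high = agr$ci_high, n = agr$n))
  if (!is.null(report$corrected)) {
    co <- report$corrected
    x$corrected_loa <- list(sigma_d_sq = co$sigma_d_sq,
                            s_dbar_sq = co$s_dbar_sq, s_xw_sq = co$s_xw_sq,
                            s_yw_sq = co$s_yw_sq, loa_low = co$loa_low,
                            loa_high = co$loa_high, ci_low = co$ci_low,
                            ci_high = co$ci_high)
  }
  if (!is.null(report$interval_correlation))
    x$interval_correlation <- report$interval_correlation
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
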