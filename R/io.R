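# Trial-log TSV format (1-based trials, colors G/B, binaries 0/1):
#   trial  r_green  r_blue  advice  correct  choice  reward_outcome  advice_outcome
# `choice` is empty for unsimulated schedules. True generating probabilities
# are latent and are never written: a reader recovers exactly what a subject
# (or the fitter) can observe.

#' Write a schedule or choice record as a trial-log TSV
#'
#' @param x A `trial_schedule` or `choice_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(x, path) {
  choice <- if (!is.null(x$choice)) x$choice else rep("", nrow(x))
  choice[is.na(choice)] <- ""
  out <- data.frame(trial = x$trial,
                    r_green = x$r_green,
                    r_blue = x$r_blue,
                    advice = x$advice,
                    correct = x$correct,
                    choice = choice,
                    reward_outcome = as.integer(x$correct == "G"),
                    advice_outcome = as.integer(x$advice_correct),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

log_error <- function(line, msg) {
  stop("trial log line ", line, ": ", msg, call. = FALSE)
}

#' Read a trial-log TSV
#'
#' Parses and validates a trial log written by [write_trial_log()] (or
#' produced externally in the same format). Validation errors report the
#' offending line number. The returned data.frame carries the observable
#' task structure; if every `choice` cell is filled it has class
#' `choice_record`, otherwise `trial_schedule`.
#'
#' @param path Input file path.
#' @param magnitude_low,magnitude_high Accepted magnitude range (defaults
#'   1 and 100).
#' @return A data.frame with columns `trial`, `r_green`, `r_blue`, `advice`,
#'   `correct`, `advice_correct` and (if present) `choice`.
#' @export
read_trial_log <- function(path, magnitude_low = 1, magnitude_high = 100) {
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, na.strings = NULL)
  req <- c("trial", "r_green", "r_blue", "advice", "correct", "choice",
           "reward_outcome", "advice_outcome")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  lines <- seq_len(n) + 1L   # header is line 1
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) log_error(lines[bad[1]], paste0("non-numeric ", what))
    v
  }
  trial <- num("trial", "trial index")
  dup <- which(duplicated(trial))
  if (length(dup)) log_error(lines[dup[1]], "duplicated trial index")
  for (col in c("r_green", "r_blue")) {
    v <- num(col, col)
    bad <- which(v < magnitude_low | v > magnitude_high | v != round(v))
    if (length(bad)) {
      log_error(lines[bad[1]],
                paste0(col, " = ", v[bad[1]], " outside integer range [",
                       magnitude_low, ", ", magnitude_high, "]"))
    }
  }
  for (col in c("advice", "correct")) {
    bad <- which(!(raw[[col]] %in% c("G", "B")))
    if (length(bad)) {
      log_error(lines[bad[1]],
                paste0("malformed color code '", raw[[col]][bad[1]], "' in ",
                       col))
    }
  }
  for (col in c("reward_outcome", "advice_outcome")) {
    bad <- which(!(raw[[col]] %in% c("0", "1")))
    if (length(bad)) log_error(lines[bad[1]], paste0(col, " must be 0/1"))
  }
  ro <- as.integer(raw$reward_outcome)
  bad <- which(ro != as.integer(raw$correct == "G"))
  if (length(bad)) log_error(lines[bad[1]],
                             "reward_outcome inconsistent with correct")
  ao <- as.integer(raw$advice_outcome)
  bad <- which(ao != as.integer(raw$advice == raw$correct))
  if (length(bad)) log_error(lines[bad[1]],
                             "advice_outcome inconsistent with advice/correct")
  has_choice <- raw$choice != ""
  if (any(has_choice) && !all(has_choice)) {
    log_error(lines[which(!has_choice)[1]], "partially filled choice column")
  }
  if (any(has_choice)) {
    bad <- which(!(raw$choice %in% c("G", "B")))
    if (length(bad)) {
      log_error(lines[bad[1]],
                paste0("malformed color code '", raw$choice[bad[1]],
                       "' in choice"))
    }
  }
  out <- data.frame(trial = as.integer(trial),
                    r_green = as.integer(as.numeric(raw$r_green)),
                    r_blue = as.integer(as.numeric(raw$r_blue)),
                    correct = raw$correct,
                    advice = raw$advice,
                    advice_correct = ao,
                    stringsAsFactors = FALSE)
  if (any(has_choice)) {
    out$choice <- raw$choice
    class(out) <- c("choice_record", "trial_schedule", "data.frame")
  } else {
    class(out) <- c("trial_schedule", "data.frame")
  }
  out
}

#' Write / read a subject-by-trait score table
#'
#' TSV with a `subject` column followed by the eight named subscale columns.
#'
#' @param traits data.frame as produced by [generate_cohort()].
#' @param path File path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_traits_table <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_traits_table
#' @export
read_traits_table <- function(path) {
  out <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  miss <- setdiff(trait_names(), names(out))
  if (length(miss)) {
    stop("traits table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(out[trait_names()])) {
    stop("traits table contains missing cells", call. = FALSE)
  }
  out
}
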