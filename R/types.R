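#' Multi-channel EEG signal record
#'
#' Container for a referenced multi-channel EEG trace in microvolts.
#'
#' @param samples Numeric matrix, samples x channels, amplitudes in uV.
#'   Column names, if present, must match `channel_labels`.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel labels, one per
#'   column of `samples`.
#' @param start_time `POSIXct` start of the recording.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, sampling_rate,
                          channel_labels = colnames(samples),
                          start_time = as.POSIXct("2024-03-01 22:30:00", tz = "UTC")) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels)) stop("channel_labels required", call. = FALSE)
  if (ncol(samples) != length(channel_labels)) {
    stop("samples has ", ncol(samples), " columns but ", length(channel_labels),
         " channel labels", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0", call. = FALSE)
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = channel_labels, start_time = start_time),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channels x %d samples @ %g Hz (%.1f min)\n",
              length(x$channel_labels), nrow(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate / 60))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Hypnogram of 30-s scored sleep epochs
#'
#' @param stages Character vector over `c("W","N1","N2","N3","R")`, one
#'   entry per 30-s epoch, spanning lights-off to lights-on.
#' @param lights_off `POSIXct` lights-off time; lights-on is derived as
#'   `lights_off + 30 * length(stages)` seconds.
#' @return An object of class `hypnogram` with elements `stages`,
#'   `lights_off`, `lights_on`, `epoch_s` (always 30).
#' @export
hypnogram <- function(stages,
                      lights_off = as.POSIXct("2024-03-01 22:30:00", tz = "UTC")) {
  stages <- as.character(stages)
  if (length(stages) < 1) stop("hypnogram must contain at least one epoch", call. = FALSE)
  bad <- which(!stages %in% sleep_stages())
  if (length(bad)) {
    stop("invalid stage token '", stages[bad[1]], "' at epoch ", bad[1] - 1,
         call. = FALSE)
  }
  structure(
    list(stages = stages, lights_off = lights_off,
         lights_on = lights_off + 30 * length(stages), epoch_s = 30),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = sleep_stages()))
  cat(sprintf("<hypnogram> %d x 30-s epochs (%.1f min in bed)\n",
              length(x$stages), length(x$stages) / 2))
  cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Arousal event annotations
#'
#' @param onset_s Numeric vector of event onsets in seconds from lights-off.
#' @param duration_s Numeric vector of event durations in seconds (> 0).
#' @return Object of class `arousal_annotations` (a data.frame).
#' @export
arousal_annotations <- function(onset_s = numeric(), duration_s = numeric()) {
  if (length(onset_s) != length(duration_s)) {
    stop("onset_s and duration_s must have equal length", call. = FALSE)
  }
  if (any(onset_s < 0)) stop("arousal onsets must be non-negative", call. = FALSE)
  if (any(duration_s <= 0)) stop("arousal durations must be > 0", call. = FALSE)
  structure(
    data.frame(onset_s = as.numeric(onset_s), duration_s = as.numeric(duration_s)),
    class = c("arousal_annotations", "data.frame")
  )
}

#' Subjective morning sleep report
#'
#' Self-reported sleep-onset latency, wake after sleep onset and total sleep
#' time (minutes), plus a sleep-quality rating from 1 ("best sleep ever") to
#' 9 ("worst sleep ever").
#'
#' @param subj_sol,subj_waso,subj_tst Reported durations in minutes (>= 0).
#' @param sq Integer sleep-quality rating in 1..9.
#' @return Object of class `subjective_report` (a one-row data.frame).
#' @export
subjective_report <- function(subj_sol, subj_waso, subj_tst, sq) {
  if (any(c(subj_sol, subj_waso, subj_tst) < 0)) {
    stop("reported durations must be non-negative", call. = FALSE)
  }
  sq <- as.integer(round(sq))
  if (sq < 1 || sq > 9) stop("sq must be in 1..9", call. = FALSE)
  structure(
    data.frame(subj_sol = subj_sol, subj_waso = subj_waso,
               subj_tst = subj_tst, sq = sq),
    class = c("subjective_report", "data.frame")
  )
}
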