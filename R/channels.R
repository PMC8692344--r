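#' Canonical referenced EEG montage
#'
#' The six referenced EEG derivations used throughout the pipeline, in
#' canonical order: frontal, central and occipital electrodes referenced to
#' the contralateral mastoid.
#'
#' @return Character vector of channel labels.
#' @export
#' @examples
#' eeg_channels()
eeg_channels <- function() {
  c("F3-M2", "F4-M1", "C3-M2", "C4-M1", "O1-M2", "O2-M1")
}

#' @rdname eeg_channels
#' @export
left_channels <- function() c("F3-M2", "C3-M2", "O1-M2")

#' @rdname eeg_channels
#' @export
right_channels <- function() c("F4-M1", "C4-M1", "O2-M1")

#' Sleep stage labels
#'
#' AASM stage labels used in hypnograms: wake, NREM 1-3 and REM.
#'
#' @return Character vector `c("W","N1","N2","N3","R")`.
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")

# Normalize a channel label for matching: case-insensitive, tolerant of
# ':' '_' or ' ' separators and of an "EEG " prefix as written by some
# PSG exporters.
normalize_channel_label <- function(x) {
  up <- toupper(trimws(x))
  up <- sub("^EEG[ -]*", "", up)
  gsub("[:_ ]", "-", up)
}

# Map arbitrary labels onto the canonical montage. Returns an integer
# index into `labels` for each canonical channel, or stops naming every
# canonical channel that is absent.
match_channels <- function(labels) {
  norm <- normalize_channel_label(labels)
  idx <- match(eeg_channels(), norm)
  if (anyNA(idx)) {
    missing <- eeg_channels()[is.na(idx)]
    stop("required EEG channel(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx
}

# Deterministic sub-seed derivation so one user-facing seed governs all
# stochastic stages. Kept below 2^31 - 1.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629) + 1L
}
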