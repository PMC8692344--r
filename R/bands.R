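#' Standard EEG frequency bands
#'
#' The five-band partition of 0.5--32 Hz used for absolute power:
#' delta \[0.5, 4.5), theta \[4.5, 8), alpha \[8, 12), sigma \[12, 15) and
#' beta \[15, 32\]. Bands are contiguous and half-open on the right except
#' beta, which is closed at 32 Hz, so every frequency in \[0.5, 32\] belongs
#' to exactly one band.
#'
#' @return A data.frame with columns `band`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "sigma", "beta"),
    lo = c(0.5, 4.5, 8, 12, 15),
    hi = c(4.5, 8, 12, 15, 32),
    stringsAsFactors = FALSE
  )
}

#' Band membership of a frequency
#'
#' Assigns frequencies to bands under the half-open convention
#' (`lo <= f < hi`, beta closed at 32 Hz). A frequency sitting exactly on a
#' shared edge, e.g. 4.5 Hz, belongs to the higher band.
#'
#' @param freq Numeric vector of frequencies in Hz.
#' @param bands Band table as returned by [eeg_bands()].
#' @return Character vector of band names (`NA` outside 0.5--32 Hz).
#' @export
#' @examples
#' band_of(c(2, 4.5, 32))
band_of <- function(freq, bands = eeg_bands()) {
  out <- rep(NA_character_, length(freq))
  for (b in seq_len(nrow(bands))) {
    inb <- freq >= bands$lo[b] & freq < bands$hi[b]
    out[inb] <- bands$band[b]
  }
  out[freq == max(bands$hi)] <- bands$band[which.max(bands$hi)]
  out
}

# Validate a band table: contiguous, non-overlapping, positive widths.
check_bands <- function(bands) {
  stopifnot(all(c("band", "lo", "hi") %in% names(bands)))
  o <- order(bands$lo)
  bands <- bands[o, ]
  if (any(bands$hi <= bands$lo)) stop("band with non-positive width", call. = FALSE)
  if (nrow(bands) > 1 && any(abs(bands$hi[-nrow(bands)] - bands$lo[-1]) > 1e-12)) {
    stop("bands must be contiguous and non-overlapping", call. = FALSE)
  }
  bands
}
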