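# Spectral pipeline: 30-s staged epochs are split into 5-s sub-epochs,
# artifact-screened, Hann-windowed and Fourier-transformed to one-sided
# power spectral densities (0.2 Hz resolution), integrated over the five
# standard bands and averaged per sleep stage, channel and hemisphere.

#' Segment a recording into staged 5-s epochs
#'
#' Each 30-s staged hypnogram epoch yields exactly six consecutive
#' non-overlapping 5-s sub-epochs carrying its stage; a trailing partial
#' sub-epoch (impossible with 30-s staging) would be dropped.
#'
#' @param signal A [signal_record()] covering the hypnogram span.
#' @param hyp A [hypnogram()].
#' @return Object of class `epoch_set`: list with `samples` (array
#'   samples-per-epoch x n_epochs x n_channels), `stage` (per 5-s epoch),
#'   `channel_labels`, `sampling_rate`.
#' @export
segment_epochs <- function(signal, hyp) {
  fs <- signal$sampling_rate
  nseg <- fs * 5
  if (abs(nseg - round(nseg)) > 1e-9) {
    stop("sampling_rate x 5 s must be an integer sample count", call. = FALSE)
  }
  nseg <- round(nseg)
  need <- length(hyp$stages) * 6L * nseg
  if (nrow(signal$samples) < need) {
    stop("signal (", nrow(signal$samples), " samples) shorter than hypnogram span (",
         need, " samples)", call. = FALSE)
  }
  ne <- length(hyp$stages) * 6L
  nch <- ncol(signal$samples)
  arr <- array(signal$samples[seq_len(ne * nseg), , drop = FALSE],
               dim = c(nseg, ne, nch))
  structure(
    list(samples = arr, stage = rep(hyp$stages, each = 6L),
         channel_labels = signal$channel_labels, sampling_rate = fs),
    class = "epoch_set"
  )
}

#' Flag artifact-contaminated 5-s epochs
#'
#' An epoch is flagged on a channel when its RMS amplitude exceeds `k`
#' times the rolling median RMS of the surrounding `window` epochs (robust
#' to stage-related amplitude shifts), or when any sample exceeds the hard
#' amplitude ceiling.
#'
#' @param epochs An `epoch_set` from [segment_epochs()].
#' @param k Relative RMS threshold (default 3).
#' @param window Rolling-median window in 5-s epochs (odd; default 25,
#'   about two minutes of context).
#' @param ceiling_uv Hard absolute-amplitude ceiling in uV (default 500).
#' @return Logical matrix, epochs x channels; `TRUE` = artifact.
#' @export
detect_artifacts <- function(epochs, k = 3, window = 25, ceiling_uv = 500) {
  ne <- dim(epochs$samples)[2]
  nch <- dim(epochs$samples)[3]
  if (ne < 1) stop("no epochs to screen", call. = FALSE)
  window <- min(window, if (ne %% 2 == 1) ne else ne - 1)
  window <- max(window, 1)
  flags <- matrix(FALSE, ne, nch, dimnames = list(NULL, epochs$channel_labels))
  for (c in seq_len(nch)) {
    x <- epochs$samples[, , c, drop = FALSE]
    dim(x) <- dim(epochs$samples)[1:2]
    rms <- sqrt(colMeans(x^2))
    ref <- if (ne >= 3 && window >= 3) {
      as.numeric(stats::runmed(rms, window, endrule = "median"))
    } else rep(stats::median(rms), ne)
    peak <- apply(abs(x), 2, max)
    flags[, c] <- (rms > k * ref) | (peak > ceiling_uv)
  }
  flags
}

#' Per-channel trace quality from artifact flags
#'
#' A channel is usable when at most 25% of its 5-s epochs are flagged
#' ("poor quality for more than 25% of the recording" excludes it);
#' unusable channels are dropped from all downstream averages.
#'
#' @param flags Logical epochs x channels matrix from [detect_artifacts()].
#' @return data.frame with columns `channel`, `fraction_artifact`, `usable`,
#'   and attribute `analyzable` (FALSE when no channel is usable).
#' @export
assess_trace_quality <- function(flags) {
  frac <- colMeans(flags)
  out <- data.frame(channel = colnames(flags), fraction_artifact = as.numeric(frac),
                    usable = as.numeric(frac) <= 0.25, row.names = NULL)
  attr(out, "analyzable") <- any(out$usable)
  out
}

# Hann window (periodic) and its sum of squares.
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' One-sided power spectral density of a 5-s epoch
#'
#' Hann-windowed FFT with variance-preserving normalization: the integral
#' of the returned PSD over all frequencies equals the windowed mean power
#' `sum((x * w)^2) / sum(w^2)` exactly (Parseval), and equals the signal
#' variance in expectation for stationary noise. Frequency resolution is
#' `1 / 5 s = 0.2 Hz` for 5-s epochs.
#'
#' @param x Numeric vector, one epoch of samples (uV).
#' @param sampling_rate Sampling rate in Hz.
#' @return Object of class `epoch_spectrum`: list with `freqs` (Hz) and
#'   `psd` (uV^2/Hz), from 0 to Nyquist.
#' @export
#' @examples
#' sp <- compute_psd(10 * sin(2 * pi * 2 * (0:639) / 128), 128)
#' sum(sp$psd) * 0.2  # ~ A^2/2 = 50 uV^2
compute_psd <- function(x, sampling_rate) {
  if (any(!is.finite(x))) stop("non-finite samples in epoch", call. = FALSE)
  n <- length(x)
  w <- hann_window(n)
  xw <- x * w
  X <- stats::fft(xw)
  nf <- n %/% 2
  psd <- (2 / (sampling_rate * sum(w^2))) * Mod(X[1:(nf + 1)])^2
  psd[1] <- psd[1] / 2
  if (n %% 2 == 0) psd[nf + 1] <- psd[nf + 1] / 2
  structure(list(freqs = (0:nf) * sampling_rate / n, psd = psd),
            class = "epoch_spectrum")
}

# Trapezoidal integration weights of the piecewise-linear PSD interpolant
# over [lo, hi], on a fixed frequency grid; edges not on the grid get
# interpolated contributions. Returns a weight vector so that
# band power = sum(weights * psd).
band_weights <- function(freqs, lo, hi) {
  n <- length(freqs)
  wts <- numeric(n)
  pts <- sort(unique(c(lo, hi, freqs[freqs > lo & freqs < hi])))
  for (i in seq_len(length(pts) - 1)) {
    a <- pts[i]; b <- pts[i + 1]
    h <- b - a
    # linear interpolation of psd at a and b in terms of grid values
    for (p in c(a, b)) {
      j <- findInterval(p, freqs)
      if (j >= n) { wts[n] <- wts[n] + h / 2; next }
      t <- (p - freqs[j]) / (freqs[j + 1] - freqs[j])
      wts[j] <- wts[j] + (1 - t) * h / 2
      wts[j + 1] <- wts[j + 1] + t * h / 2
    }
  }
  wts
}

#' Integrate a spectrum over the standard bands
#'
#' Absolute band power (uV^2) as the trapezoidal integral of the PSD over
#' each band interval, interpolating at band edges that fall between grid
#' frequencies. Band powers are exactly additive: their sum equals the
#' integral over \[0.5, 32\] Hz.
#'
#' @param spectrum An `epoch_spectrum` from [compute_psd()].
#' @param bands Band table, default [eeg_bands()].
#' @return Named numeric vector of band powers in uV^2.
#' @export
integrate_bands <- function(spectrum, bands = eeg_bands()) {
  bands <- check_bands(bands)
  if (max(spectrum$freqs) < max(bands$hi)) {
    stop("spectrum does not cover [", min(bands$lo), ", ", max(bands$hi), "] Hz",
         call. = FALSE)
  }
  out <- vapply(seq_len(nrow(bands)), function(b) {
    sum(band_weights(spectrum$freqs, bands$lo[b], bands$hi[b]) * spectrum$psd)
  }, 0)
  names(out) <- bands$band
  out
}

# Vectorized band powers for a whole epoch_set: returns an array
# n_epochs x n_channels x n_bands. Same math as compute_psd +
# integrate_bands, applied via mvfft per channel.
epoch_band_powers <- function(epochs, bands = eeg_bands()) {
  bands <- check_bands(bands)
  fs <- epochs$sampling_rate
  n <- dim(epochs$samples)[1]
  ne <- dim(epochs$samples)[2]
  nch <- dim(epochs$samples)[3]
  w <- hann_window(n)
  nf <- n %/% 2
  freqs <- (0:nf) * fs / n
  W <- vapply(seq_len(nrow(bands)),
              function(b) band_weights(freqs, bands$lo[b], bands$hi[b]), numeric(nf + 1))
  colnames(W) <- bands$band
  scale_ <- 2 / (fs * sum(w^2))
  out <- array(0, dim = c(ne, nch, nrow(bands)),
               dimnames = list(NULL, epochs$channel_labels, bands$band))
  for (c in seq_len(nch)) {
    x <- epochs$samples[, , c, drop = FALSE]
    dim(x) <- c(n, ne)
    X <- stats::mvfft(x * w)
    psd <- scale_ * Mod(X[1:(nf + 1), , drop = FALSE])^2
    psd[1, ] <- psd[1, ] / 2
    if (n %% 2 == 0) psd[nf + 1, ] <- psd[nf + 1, ] / 2
    out[, c, ] <- crossprod(psd, W)
  }
  out
}

#' Average band power per sleep stage, channel and hemisphere
#'
#' Artifact-free 5-s epoch band powers are averaged per sleep stage and
#' channel (usable channels only), then across channels for the `global`
#' (all usable), `left` and `right` scopes. Aggregate rows are added for
#' `NREM` (all N1/N2/N3 epochs pooled, i.e. duration-weighted) and `ALL`
#' (all epochs pooled). Stages with no artifact-free epoch yield missing
#' cells (`NA`), never zero.
#'
#' @param powers Epoch band-power array from internal segmentation
#'   (epochs x channels x bands).
#' @param stage Stage label per 5-s epoch.
#' @param flags Logical artifact matrix (epochs x channels).
#' @param quality Quality table from [assess_trace_quality()].
#' @return Object of class `stage_band_power`: long data.frame with columns
#'   `stage`, `scope`, `band`, `power`, `n_epochs`.
#' @export
aggregate_stage_band_power <- function(powers, stage, flags, quality) {
  if (!isTRUE(attr(quality, "analyzable"))) {
    stop("no usable EEG channel; subject is unanalyzable", call. = FALSE)
  }
  usable <- quality$channel[quality$usable]
  bands <- dimnames(powers)[[3]]
  classes <- list(W = "W", N1 = "N1", N2 = "N2", N3 = "N3", R = "R",
                  NREM = c("N1", "N2", "N3"), ALL = sleep_stages())
  rows <- list()
  ri <- 0L
  for (sc in names(classes)) {
    inclass <- stage %in% classes[[sc]]
    chan_mean <- matrix(NA_real_, length(usable), length(bands),
                        dimnames = list(usable, bands))
    chan_n <- stats::setNames(integer(length(usable)), usable)
    for (ch in usable) {
      keep <- inclass & !flags[, ch]
      chan_n[ch] <- sum(keep)
      if (any(keep)) {
        chan_mean[ch, ] <- colMeans(powers[keep, ch, , drop = FALSE], dims = 1)
      }
    }
    scope_rows <- function(scope, chans) {
      chans <- intersect(chans, usable)
      ok <- chans[!is.na(chan_mean[chans, 1])]
      if (length(chans) == 0) return(NULL)
      val <- if (length(ok)) colMeans(chan_mean[ok, , drop = FALSE]) else
        stats::setNames(rep(NA_real_, length(bands)), bands)
      data.frame(stage = sc, scope = scope, band = bands, power = as.numeric(val),
                 n_epochs = if (length(ok)) as.integer(round(mean(chan_n[ok]))) else 0L)
    }
    for (ch in usable) {
      ri <- ri + 1L
      rows[[ri]] <- data.frame(stage = sc, scope = ch, band = bands,
                               power = as.numeric(chan_mean[ch, ]),
                               n_epochs = unname(chan_n[ch]))
    }
    for (sp in list(c("global", list(eeg_channels())),
                    c("left", list(left_channels())),
                    c("right", list(right_channels())))) {
      r <- scope_rows(sp[[1]], sp[[2]])
      if (!is.null(r)) { ri <- ri + 1L; rows[[ri]] <- r }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stage_band_power", "data.frame")
  out
}

#' Full spectral pipeline for one recording
#'
#' Segments, artifact-screens, transforms and aggregates a signal +
#' hypnogram pair into the per-stage band-power table.
#'
#' @inheritParams segment_epochs
#' @inheritParams detect_artifacts
#' @param bands Band table, default [eeg_bands()].
#' @return A `stage_band_power` table (see [aggregate_stage_band_power()]),
#'   with the quality table attached as attribute `quality`.
#' @export
stage_band_power <- function(signal, hyp, bands = eeg_bands(), k = 3,
                             window = 25, ceiling_uv = 500) {
  ep <- segment_epochs(signal, hyp)
  flags <- detect_artifacts(ep, k = k, window = window, ceiling_uv = ceiling_uv)
  qual <- assess_trace_quality(flags)
  pw <- epoch_band_powers(ep, bands)
  out <- aggregate_stage_band_power(pw, ep$stage, flags, qual)
  attr(out, "quality") <- qual
  out
}
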