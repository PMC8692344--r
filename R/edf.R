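# European Data Format (EDF) reader/writer.
#
# EDF stores a fixed-width ASCII header (256 bytes global + 256 per signal)
# followed by data records of 16-bit little-endian integers, mapped to
# physical units by per-signal linear scaling. Only the subset needed for
# referenced EEG is implemented: continuous recordings, one record per
# second, identical sampling rate expected across the six montage channels.

pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a signal record to an EDF file
#'
#' Amplitudes are quantized to 16 bits over a symmetric physical range
#' per channel (the smallest range covering the data), giving a worst-case
#' quantization error of half the physical resolution.
#'
#' @param signal A [signal_record()].
#' @param path Output file path.
#' @param patient_id,recording_id Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, path, patient_id = "X", recording_id = "Startdate X") {
  fs <- signal$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("integer sampling rate required", call. = FALSE)
  fs <- round(fs)
  x <- signal$samples
  n_rec <- floor(nrow(x) / fs)
  if (n_rec < 1) stop("signal shorter than one 1-s data record", call. = FALSE)
  x <- x[seq_len(n_rec * fs), , drop = FALSE]
  ns <- ncol(x)
  pmax_ <- apply(abs(x), 2, max)
  pmax_ <- ifelse(pmax_ <= 0, 1, pmax_ * 1.0001)   # avoid degenerate range
  con <- file(path, "wb")
  on.exit(close(con))
  st <- as.POSIXlt(signal$start_time, tz = "UTC")
  hdr <- paste0(
    pad("0", 8), pad(patient_id, 80), pad(recording_id, 80),
    pad(format(st, "%d.%m.%y"), 8), pad(format(st, "%H.%M.%S"), 8),
    pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8), pad("1", 8), pad(ns, 4)
  )
  field <- function(vals, width) paste(vapply(vals, pad, "", width = width),
                                       collapse = "")
  hdr <- paste0(
    hdr,
    field(signal$channel_labels, 16),
    field(rep("", ns), 80),                       # transducer
    field(rep("uV", ns), 8),                      # physical dimension
    field(formatC(-pmax_, digits = 6, format = "g"), 8),
    field(formatC(pmax_, digits = 6, format = "g"), 8),
    field(rep("-32768", ns), 8),
    field(rep("32767", ns), 8),
    field(rep("", ns), 80),                       # prefiltering
    field(rep(fs, ns), 8),
    field(rep("", ns), 32)
  )
  writeBin(charToRaw(hdr), con)
  # re-read the printed physical range so writer and reader use identical scaling
  pmin_chr <- as.numeric(vapply(-pmax_, function(v) pad(formatC(v, digits = 6, format = "g"), 8), ""))
  pmax_chr <- as.numeric(vapply(pmax_, function(v) pad(formatC(v, digits = 6, format = "g"), 8), ""))
  scale_ <- (pmax_chr - pmin_chr) / 65535
  dig <- matrix(0L, nrow(x), ns)
  for (c in seq_len(ns)) {
    d <- round((x[, c] - pmin_chr[c]) / scale_[c]) - 32768
    dig[, c] <- as.integer(pmin(pmax(d, -32768L), 32767L))
  }
  out <- integer(n_rec * ns * fs)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (c in seq_len(ns)) {
      out[(pos + 1):(pos + fs)] <- dig[rows, c]
      pos <- pos + fs
    }
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read the EEG montage from an EDF file
#'
#' Parses an EDF/EDF+ header, locates the six canonical referenced EEG
#' channels by label (case-insensitive; `-`, `:`, `_` and space separators
#' and an `EEG ` prefix are tolerated), converts to microvolts using the
#' file's physical scaling, and returns them in canonical order regardless
#' of their order in the file.
#'
#' @param path EDF file path.
#' @return A [signal_record()] with channels ordered as [eeg_channels()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(rawToChar(readBin(con, "raw", width)))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')",
                           call. = FALSE)
  rd(80); rd(80)
  date_s <- rd(8); time_s <- rd(8)
  rd(8)                                      # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16)
  fields(80)
  dims <- fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin_ <- as.numeric(fields(8)); dmax_ <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  idx <- match_channels(labels)
  if (length(unique(spr[idx])) != 1) {
    stop("mixed sampling rates across EEG channels: ",
         paste(unique(spr[idx] / rec_dur), collapse = ", "), " Hz", call. = FALSE)
  }
  fs <- spr[idx][1] / rec_dur
  raw_all <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                     endian = "little", signed = TRUE)
  offs <- c(0, cumsum(spr))
  rec_len <- sum(spr)
  out <- matrix(0, nrow = n_rec * spr[idx][1], ncol = length(idx))
  for (k in seq_along(idx)) {
    c <- idx[k]
    sc <- (pmax_[c] - pmin_[c]) / (dmax_[c] - dmin_[c])
    take <- as.vector(outer(seq_len(spr[c]) + offs[c],
                            (seq_len(n_rec) - 1) * rec_len, `+`))
    phys <- (raw_all[take] - dmin_[c]) * sc + pmin_[c]
    if (!identical(toupper(dims[c]), "UV") && nzchar(dims[c])) {
      if (toupper(dims[c]) == "MV") phys <- phys * 1000
    }
    out[, k] <- phys
  }
  start <- as.POSIXct(paste(date_s, time_s), format = "%d.%m.%y %H.%M.%S",
                      tz = "UTC")
  if (is.na(start)) start <- as.POSIXct("2024-03-01 22:30:00", tz = "UTC")
  signal_record(out, fs, eeg_channels(), start_time = start)
}
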