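# Plain-text readers/writers for hypnograms, arousals, reports and the
# clustering feature table. The hypnogram TSV dialect (epoch_index, stage)
# with a YAML sidecar carrying lights_off/lights_on is a pipeline
# convention; epoch indices are 0-based and intervals half-open.

#' Write / read a hypnogram as TSV plus YAML sidecar
#'
#' The TSV has columns `epoch_index` (0-based) and `stage`; the sidecar
#' stores `lights_off`, `lights_on` (ISO 8601, UTC) and `epoch_s`.
#'
#' @param hyp A [hypnogram()].
#' @param path TSV file path.
#' @param sidecar Sidecar YAML path; defaults to `<path>.yaml`.
#' @return `path` invisibly (writer); a [hypnogram()] (reader).
#' @export
write_hypnogram <- function(hyp, path, sidecar = paste0(path, ".yaml")) {
  df <- data.frame(epoch_index = seq_along(hyp$stages) - 1L, stage = hyp$stages)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    lights_off = format(hyp$lights_off, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lights_on = format(hyp$lights_on, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    epoch_s = hyp$epoch_s
  ), sidecar)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, sidecar = paste0(path, ".yaml")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character"))
  bad <- which(!df$stage %in% sleep_stages())
  if (length(bad)) {
    stop("invalid stage token '", df$stage[bad[1]], "' at line ", bad[1] + 1L,
         " of ", path, call. = FALSE)
  }
  lights_off <- as.POSIXct("2024-03-01 22:30:00", tz = "UTC")
  if (file.exists(sidecar)) {
    sc <- yaml::read_yaml(sidecar)
    lights_off <- as.POSIXct(sc$lights_off, format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
    if (!is.null(sc$epoch_s) && sc$epoch_s != 30) {
      stop("only 30-s epochs are supported (sidecar says ", sc$epoch_s, ")",
           call. = FALSE)
    }
  }
  hypnogram(df$stage[order(df$epoch_index)], lights_off = lights_off)
}

#' Write / read arousal annotations as TSV
#'
#' Columns `onset_s`, `duration_s` (seconds from lights-off).
#'
#' @param arousals An [arousal_annotations()].
#' @param path File path.
#' @return `path` invisibly (writer); an [arousal_annotations()] (reader).
#' @export
write_arousals <- function(arousals, path) {
  utils::write.table(as.data.frame(arousals), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_arousals
#' @export
read_arousals <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  arousal_annotations(df$onset_s, df$duration_s)
}

#' Write the clustering feature table as CSV
#'
#' One row per subject: a `subject` id column followed by the 33 named
#' feature columns in the fixed order of [feature_names()].
#'
#' @param fm A feature matrix from [build_feature_matrix()] (numeric matrix
#'   with subject row names).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path) {
  df <- data.frame(subject = rownames(fm), as.data.frame(unclass(fm)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "subject"), drop = FALSE])
  rownames(m) <- df$subject
  class(m) <- c("feature_matrix", class(m))
  m
}

#' Write a synthetic cohort to disk in standard formats
#'
#' One EDF per subject (six EEG channels, uV), hypnogram TSV + YAML sidecar,
#' arousal TSV, a cohort-level `reports.csv` with the subjective reports and
#' a `labels.csv` with the ground-truth subtype labels.
#'
#' @param cohort A `psg_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    write_edf(cohort_signal(cohort, i), file.path(dir, paste0(s$id, ".edf")))
    write_hypnogram(s$hypnogram, file.path(dir, paste0(s$id, "_hypnogram.tsv")))
    write_arousals(s$arousals, file.path(dir, paste0(s$id, "_arousals.tsv")))
    reports[[i]] <- data.frame(subject = s$id, s$report)
  }
  utils::write.csv(do.call(rbind, reports), file.path(dir, "reports.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject = names(cohort_labels(cohort)),
                              label = unname(cohort_labels(cohort))),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
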