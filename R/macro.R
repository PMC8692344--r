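#' Sleep macroarchitecture metrics from a hypnogram
#'
#' Standard polysomnographic summary variables from a 30-s epoch hypnogram
#' and (optionally) arousal annotations. Sleep onset is the first epoch of
#' any non-wake stage after lights-off; SOL is lights-off to onset, WASO the
#' wake time between onset and the final sleep epoch, terminal wake the wake
#' after the final sleep epoch, and REM latency is referenced from sleep
#' onset. The identity `SOL + TST + WASO + terminal wake = TIB` holds
#' exactly by epoch arithmetic. Arousal indices use stage-specific time
#' denominators (events whose onset falls in an epoch of that stage class,
#' per hour of that stage class).
#'
#' A hypnogram with no sleep epoch returns the documented degenerate
#' contract: `tst = 0`, `se = 0`, `sol = tib`, `waso = 0`, no exception.
#'
#' @param hyp A [hypnogram()].
#' @param arousals Optional [arousal_annotations()].
#' @return One-row data.frame of class `sleep_metrics` with columns `tib`,
#'   `tst`, `se`, `sol`, `waso`, `terminal_wake`, `n1_min`, `n2_min`,
#'   `n3_min`, `rem_min`, `nrem_min`, `rem_latency`, `n1_pct`, `n2_pct`,
#'   `n3_pct`, `rem_pct`, `arousal_index_total`, `arousal_index_nrem`,
#'   `arousal_index_rem` (minutes, percent, events/hour).
#' @export
#' @examples
#' h <- hypnogram(c(rep("W", 10), rep("N1", 2), rep("N2", 100),
#'                  rep("R", 20), rep("W", 4)))
#' compute_sleep_metrics(h)[, c("tib", "sol", "tst", "waso", "se")]
compute_sleep_metrics <- function(hyp, arousals = NULL) {
  st <- hyp$stages
  E <- length(st)
  epm <- 0.5                                  # minutes per 30-s epoch
  tib <- E * epm
  sleep <- st != "W"
  mk <- function(...) {
    out <- data.frame(...)
    class(out) <- c("sleep_metrics", "data.frame")
    out
  }
  stage_min <- function(s) sum(st == s) * epm
  if (!any(sleep)) {
    return(mk(tib = tib, tst = 0, se = 0, sol = tib, waso = 0,
              terminal_wake = 0, n1_min = 0, n2_min = 0, n3_min = 0,
              rem_min = 0, nrem_min = 0, rem_latency = NA_real_,
              n1_pct = NA_real_, n2_pct = NA_real_, n3_pct = NA_real_,
              rem_pct = NA_real_, arousal_index_total = NA_real_,
              arousal_index_nrem = NA_real_, arousal_index_rem = NA_real_))
  }
  onset <- which(sleep)[1]
  last <- max(which(sleep))
  sol <- (onset - 1) * epm
  tst <- sum(sleep) * epm
  waso <- sum(st[onset:last] == "W") * epm
  terminal <- (E - last) * epm
  first_r <- which(st == "R")[1]
  rem_latency <- if (is.na(first_r)) NA_real_ else (first_r - onset) * epm
  n1 <- stage_min("N1"); n2 <- stage_min("N2"); n3 <- stage_min("N3")
  rem <- stage_min("R")
  nrem <- n1 + n2 + n3
  idx_rate <- function(n_events, minutes) {
    if (minutes <= 0) NA_real_ else n_events / (minutes / 60)
  }
  if (is.null(arousals) || nrow(arousals) == 0) {
    ar_tot <- idx_rate(0, tst); ar_nrem <- idx_rate(0, nrem)
    ar_rem <- idx_rate(0, rem)
  } else {
    ep <- pmin(floor(arousals$onset_s / 30) + 1L, E)
    cls <- st[ep]
    ar_tot <- idx_rate(sum(cls != "W"), tst)
    ar_nrem <- idx_rate(sum(cls %in% c("N1", "N2", "N3")), nrem)
    ar_rem <- idx_rate(sum(cls == "R"), rem)
  }
  mk(tib = tib, tst = tst, se = 100 * tst / tib, sol = sol, waso = waso,
     terminal_wake = terminal, n1_min = n1, n2_min = n2, n3_min = n3,
     rem_min = rem, nrem_min = nrem, rem_latency = rem_latency,
     n1_pct = 100 * n1 / tst, n2_pct = 100 * n2 / tst,
     n3_pct = 100 * n3 / tst, rem_pct = 100 * rem / tst,
     arousal_index_total = ar_tot, arousal_index_nrem = ar_nrem,
     arousal_index_rem = ar_rem)
}
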