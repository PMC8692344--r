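#' Interhemispheric delta-power asymmetry index
#'
#' For a sleep stage (or the `NREM`/`ALL` aggregates) the index contrasts
#' delta-band power between the left (F3-M2, C3-M2, O1-M2) and right
#' (F4-M1, C4-M1, O2-M1) hemispheres:
#' \deqn{IAI_s = \frac{\sum_i x_i - \sum_j x_j}{\sum_i x_i + \sum_j x_j}}
#' where \eqn{x_i} and \eqn{x_j} are the per-channel stage-average delta
#' powers over the `n` usable left and `m` usable right channels. The index
#' lies in \[-1, 1\]; positive values indicate greater left-hemisphere
#' delta activity. With unequal usable-channel counts, per-hemisphere means
#' are contrasted instead of raw sums (identical when `n = m`), so a lost
#' channel does not masquerade as asymmetry.
#'
#' @param power A `stage_band_power` table (see [stage_band_power()]).
#' @param stage Stage label: one of `"W"`, `"N1"`, `"N2"`, `"N3"`, `"R"`,
#'   `"NREM"`, `"ALL"`.
#' @return One-row data.frame with columns `stage`, `iai`, `n_left`,
#'   `n_right`. `iai` is `NA` when a hemisphere has no usable channel or
#'   total delta power is zero.
#' @export
compute_iai <- function(power, stage) {
  d <- power[power$stage == stage & power$band == "delta", , drop = FALSE]
  lv <- d$power[match(left_channels(), d$scope)]
  rv <- d$power[match(right_channels(), d$scope)]
  lv <- lv[!is.na(lv)]; rv <- rv[!is.na(rv)]
  n <- length(lv); m <- length(rv)
  iai <- if (n == 0 || m == 0) {
    NA_real_
  } else {
    L <- mean(lv); R <- mean(rv)
    if (L + R <= 0) NA_real_ else (L - R) / (L + R)
  }
  data.frame(stage = stage, iai = iai, n_left = n, n_right = m)
}

#' Asymmetry index across all stages and aggregates
#'
#' @param power A `stage_band_power` table.
#' @param stages Stage labels to evaluate; default all five stages plus the
#'   `NREM` and `ALL` (epoch-weighted all-night) aggregates.
#' @return data.frame, one row per stage, columns as [compute_iai()].
#' @export
iai_table <- function(power, stages = c("W", "N1", "N2", "N3", "R", "NREM", "ALL")) {
  out <- do.call(rbind, lapply(stages, function(s) compute_iai(power, s)))
  rownames(out) <- NULL
  out
}

#' Sleep-state misperception index
#'
#' \deqn{SSM = \frac{objective\,TST - subjective\,TST}{objective\,TST}}
#' Positive values indicate underestimation of total sleep time, negative
#' values overestimation; the index is at most 1 (subjective TST >= 0).
#'
#' @param objective_tst Objective total sleep time in minutes (> 0).
#' @param subjective_tst Reported total sleep time in minutes (>= 0).
#' @return One-row data.frame with `ssm`, `objective_tst`, `subjective_tst`.
#' @export
#' @examples
#' compute_ssm(400, 344)$ssm  # 0.14: underestimation
compute_ssm <- function(objective_tst, subjective_tst) {
  if (objective_tst <= 0) {
    stop("objective_tst must be > 0 (SSM undefined otherwise)", call. = FALSE)
  }
  if (subjective_tst < 0) stop("subjective_tst must be >= 0", call. = FALSE)
  data.frame(ssm = (objective_tst - subjective_tst) / objective_tst,
             objective_tst = objective_tst, subjective_tst = subjective_tst)
}
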