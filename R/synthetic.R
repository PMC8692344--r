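#' Default stage-specific band power spectral densities
#'
#' Target power spectral density (uV^2/Hz) per sleep stage and band for the
#' synthetic EEG generator. Values are synthetic stand-ins chosen so that
#' delta power is ordered N3 >> N2 > N1 ~ R ~ W, as in textbook sleep EEG;
#' they are generator configuration, not empirical claims about any cohort.
#'
#' @return Named list (stage) of named numeric vectors (band -> uV^2/Hz).
#' @export
default_stage_psd <- function() {
  list(
    W  = c(delta = 5,  theta = 2,   alpha = 4,   sigma = 1,   beta = 1.5),
    N1 = c(delta = 8,  theta = 4,   alpha = 2,   sigma = 1,   beta = 1),
    N2 = c(delta = 15, theta = 4.5, alpha = 1.5, sigma = 3,   beta = 0.8),
    N3 = c(delta = 40, theta = 5,   alpha = 1,   sigma = 1.5, beta = 0.5),
    R  = c(delta = 7,  theta = 4.5, alpha = 2,   sigma = 1,   beta = 1.2)
  )
}

#' Subtype generating profile
#'
#' Describes the target sleep architecture, spectral content, hemispheric
#' asymmetry and misperception bias of one planted subtype. Targets refer to
#' a night of `target_sol + target_tst + target_waso` minutes or longer.
#'
#' @param label Subtype name.
#' @param target_tst,target_sol,target_waso Target total sleep time,
#'   sleep-onset latency and wake after sleep onset, minutes.
#' @param stage_band_psd Named list stage -> named band vector of target PSD
#'   levels in uV^2/Hz; see [default_stage_psd()].
#' @param delta_asymmetry_a Planted delta asymmetry `a` in (-1, 1): delta
#'   power is scaled by `(1 + a)` on left-hemisphere channels and `(1 - a)`
#'   on the right, so the planted interhemispheric asymmetry index equals
#'   `a` exactly in expectation.
#' @param misperception_bias_b Expected sleep-state misperception: subjective
#'   TST is generated as `objective TST * (1 - b)` plus noise.
#' @param sq_mean Mean sleep-quality rating on the 1 (best) .. 9 (worst) scale.
#' @param restriction_delta_gain Multiplicative gain applied to delta PSD on
#'   the acute bedtime-restriction night.
#' @param arousal_rate Arousal events per hour of sleep.
#' @param tst_sd,sol_sd,waso_sd Between-subject SDs of the targets, minutes.
#' @param psd_cv Between-subject log-normal coefficient of variation of the
#'   PSD levels.
#' @param sq_sd SD of the sleep-quality rating.
#' @param report_noise_frac SD of subjective-TST noise as a fraction of
#'   objective TST.
#' @return Object of class `subtype_profile`.
#' @export
subtype_profile <- function(label, target_tst, target_sol, target_waso,
                            stage_band_psd = default_stage_psd(),
                            delta_asymmetry_a = 0,
                            misperception_bias_b = 0,
                            sq_mean = 5,
                            restriction_delta_gain = 1,
                            arousal_rate = 10,
                            tst_sd = 12, sol_sd = 5, waso_sd = 8,
                            psd_cv = 0.08, sq_sd = 1,
                            report_noise_frac = 0.05) {
  if (any(unlist(stage_band_psd) <= 0)) stop("all PSD levels must be > 0", call. = FALSE)
  if (abs(delta_asymmetry_a) >= 1) stop("|delta_asymmetry_a| must be < 1", call. = FALSE)
  if (sq_mean < 1 || sq_mean > 9) stop("sq_mean must be in [1, 9]", call. = FALSE)
  if (min(target_tst, target_sol, target_waso) < 0) {
    stop("targets must be non-negative", call. = FALSE)
  }
  stopifnot(setequal(names(stage_band_psd), sleep_stages()))
  structure(
    list(label = label, target_tst = target_tst, target_sol = target_sol,
         target_waso = target_waso, stage_band_psd = stage_band_psd,
         delta_asymmetry_a = delta_asymmetry_a,
         misperception_bias_b = misperception_bias_b,
         sq_mean = sq_mean, restriction_delta_gain = restriction_delta_gain,
         arousal_rate = arousal_rate,
         tst_sd = tst_sd, sol_sd = sol_sd, waso_sd = waso_sd,
         psd_cv = psd_cv, sq_sd = sq_sd,
         report_noise_frac = report_noise_frac),
    class = "subtype_profile"
  )
}

#' Planted insomnia subtype profiles
#'
#' Three generating profiles mirroring the structure of the short-sleep
#' delta-deficient (SSDD), normal-sleep delta-deficient (NSDD) and normal
#' neurophysiological sleep (NNS) phenotypes: SSDD has short sleep plus a
#' halved delta PSD, NSDD normal-length sleep with halved delta, and NNS
#' normal sleep and spectra. Targets are expressed for a 450-min night and
#' scaled proportionally (including their between-subject SDs) for shorter
#' desk-scale nights.
#'
#' @param night_duration Night length in minutes the targets are scaled to.
#' @return Named list of three [subtype_profile()] objects.
#' @export
#' @examples
#' sapply(insomnia_profiles(90), function(p) p$target_tst)
insomnia_profiles <- function(night_duration = 450) {
  f <- night_duration / 450
  deficient <- function(psd) lapply(psd, function(v) { v["delta"] <- v["delta"] * 0.5; v })
  scale_prof <- function(p) {
    p$target_tst <- p$target_tst * f; p$target_sol <- p$target_sol * f
    p$target_waso <- p$target_waso * f
    p$tst_sd <- p$tst_sd * f; p$sol_sd <- p$sol_sd * f; p$waso_sd <- p$waso_sd * f
    p
  }
  base <- default_stage_psd()
  profs <- list(
    SSDD = subtype_profile("SSDD", target_tst = 330, target_sol = 40,
                           target_waso = 70, stage_band_psd = deficient(base),
                           delta_asymmetry_a = 0.01, misperception_bias_b = 0.14,
                           sq_mean = 6, restriction_delta_gain = 1.3,
                           arousal_rate = 18),
    NSDD = subtype_profile("NSDD", target_tst = 400, target_sol = 25,
                           target_waso = 20, stage_band_psd = deficient(base),
                           delta_asymmetry_a = 0.001, misperception_bias_b = 0.05,
                           sq_mean = 5.5, restriction_delta_gain = 1.25,
                           arousal_rate = 14),
    NNS = subtype_profile("NNS", target_tst = 405, target_sol = 15,
                          target_waso = 18, stage_band_psd = base,
                          delta_asymmetry_a = -0.03, misperception_bias_b = 0,
                          sq_mean = 5, restriction_delta_gain = 1,
                          arousal_rate = 10)
  )
  lapply(profs, scale_prof)
}

#' Cohort specification for the synthetic generator
#'
#' @param profiles Named list of [subtype_profile()] objects.
#' @param n_per_profile Integer vector (recycled) of subjects per profile.
#' @param sampling_rate EEG sampling rate in Hz (>= 64 so the 32 Hz beta
#'   edge is below Nyquist).
#' @param night_duration Night length (lights-off to lights-on), minutes.
#' @param seed Integer master seed; all per-subject randomness derives from it.
#' @param scenario `"habitual"` for night 1 or `"restricted"` for the acute
#'   restriction night (bedtime delayed by `restriction_min`, same rise time).
#' @param restriction_min Bedtime delay of the restricted scenario, minutes.
#' @param lights_off `POSIXct` habitual lights-off time.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(profiles, n_per_profile, sampling_rate = 128,
                        night_duration = 450, seed = 1,
                        scenario = c("habitual", "restricted"),
                        restriction_min = 120,
                        lights_off = as.POSIXct("2024-03-01 22:30:00", tz = "UTC")) {
  scenario <- match.arg(scenario)
  n_per_profile <- rep_len(as.integer(n_per_profile), length(profiles))
  if (any(n_per_profile < 1)) stop("n per profile must be >= 1", call. = FALSE)
  if (sampling_rate < 64) stop("sampling_rate must be >= 64 Hz", call. = FALSE)
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, `[[`, "", "label")
  }
  structure(
    list(profiles = profiles, n_per_profile = n_per_profile,
         sampling_rate = sampling_rate, night_duration = night_duration,
         channels = eeg_channels(), seed = as.integer(seed),
         scenario = scenario, restriction_min = restriction_min,
         lights_off = lights_off),
    class = "cohort_spec"
  )
}

# Stage-transition matrix of the nested NREM/REM chain (per 30-s epoch).
stage_transition_matrix <- function() {
  rbind(
    N1 = c(N1 = 0.500, N2 = 0.440, N3 = 0.010, R = 0.05),
    N2 = c(N1 = 0.020, N2 = 0.870, N3 = 0.070, R = 0.04),
    N3 = c(N1 = 0.005, N2 = 0.115, N3 = 0.880, R = 0.00),
    R  = c(N1 = 0.040, N2 = 0.060, N3 = 0.000, R = 0.90)
  )
}

#' Simulate a 30-s epoch hypnogram with target macroarchitecture
#'
#' Generates a full-night stage sequence whose realized sleep-onset latency,
#' total sleep time and wake after sleep onset track the profile targets.
#' Sleep epochs follow a first-order N1/N2/N3/R Markov stage chain;
#' intra-sleep wake is placed as alternating wake bouts (mean dwell about
#' 2 min) whose total equals the night's WASO budget, so realized
#' macroarchitecture reflects the planted between-subject structure rather
#' than within-night dwell noise. The latency run before onset is drawn
#' around the SOL target, and residual time in bed becomes terminal wake.
#'
#' @param profile A [subtype_profile()].
#' @param night_duration Night length in minutes (>= 30).
#' @param seed Integer seed.
#' @param lights_off `POSIXct` lights-off time.
#' @return A [hypnogram()].
#' @export
#' @examples
#' h <- simulate_hypnogram(insomnia_profiles(90)$NNS, 90, seed = 1)
#' table(h$stages)
simulate_hypnogram <- function(profile, night_duration, seed,
                               lights_off = as.POSIXct("2024-03-01 22:30:00",
                                                       tz = "UTC")) {
  if (night_duration < 30) stop("night_duration must be >= 30 min", call. = FALSE)
  tot <- profile$target_sol + profile$target_tst + profile$target_waso
  if (tot > night_duration + 1e-9) {
    stop("infeasible targets: SOL + TST + WASO (", tot,
         " min) exceed night duration (", night_duration, " min)", call. = FALSE)
  }
  set.seed(seed)
  E <- round(night_duration * 2)            # 30-s epochs
  sol_ep <- round(profile$target_sol * 2)
  sleep_ep <- round((profile$target_tst + profile$target_waso) * 2)
  if (sol_ep == 0) {
    sol_real <- 0L
  } else {
    sol_real <- round(stats::rnorm(1, sol_ep, max(1, 0.1 * sol_ep)))
    sol_real <- max(0L, min(as.integer(sol_real), E - sleep_ep))
  }
  sleep_ep <- min(sleep_ep, E - sol_real)
  w_ep <- min(round(profile$target_waso * 2), max(sleep_ep - 2L, 0L))
  s_ep <- sleep_ep - w_ep

  # Wake inside the sleep period: alternating sleep-wake bouts with mean
  # wake dwell ~2 min, total wake fixed to the night's WASO budget so the
  # realized macroarchitecture tracks the planted targets tightly.
  bout_at <- integer(0)                      # wake-bout length per interior gap
  if (w_ep > 0 && s_ep >= 2) {
    k_b <- max(1L, min(round(w_ep / 4), s_ep - 1L))
    lens <- rep(1L, k_b)
    extra <- w_ep - k_b
    if (extra > 0) lens <- lens + tabulate(sample.int(k_b, extra, replace = TRUE), k_b)
    gaps <- sample.int(s_ep - 1L, k_b)       # between sleep epochs, never at edges
    bout_at <- integer(s_ep - 1L)
    bout_at[gaps] <- lens
  }

  P <- stage_transition_matrix()
  st_labels <- rownames(P)
  stage <- "N1"
  period <- character(0)
  for (si in seq_len(s_ep)) {
    period <- c(period, stage)
    stage <- sample(st_labels, 1, prob = P[stage, ])
    if (si <= length(bout_at) && bout_at[si] > 0) {
      period <- c(period, rep("W", bout_at[si]))
      stage <- "N1"                          # re-descend through N1 after waking
    }
  }
  stages <- rep("W", E)
  if (length(period)) stages[sol_real + seq_along(period)] <- period
  hypnogram(stages, lights_off = lights_off)
}

# Per-(stage, hemisphere) amplitude-spectrum lookup used by simulate_eeg.
# Returns, for each stage, a list with left/right vectors of length nf + 1
# (frequency bins 0..fs/2 at df = fs/n).
build_amplitude_spectra <- function(profile, fs, n, bands = eeg_bands()) {
  nf <- n %/% 2
  freqs <- (0:nf) * fs / n
  a <- profile$delta_asymmetry_a
  out <- list()
  for (st in names(profile$stage_band_psd)) {
    lv <- profile$stage_band_psd[[st]]
    S <- numeric(nf + 1)
    for (b in seq_len(nrow(bands))) {
      inb <- freqs >= bands$lo[b] & freqs < bands$hi[b]
      S[inb] <- lv[[bands$band[b]]]
    }
    S[freqs == 32] <- lv[["beta"]]
    deltab <- freqs >= 0.5 & freqs < 4.5
    SL <- S; SL[deltab] <- S[deltab] * (1 + a)
    SR <- S; SR[deltab] <- S[deltab] * (1 - a)
    out[[st]] <- list(left = sqrt(SL * fs * n / 4), right = sqrt(SR * fs * n / 4))
  }
  out
}

#' Simulate multi-channel sleep EEG from a hypnogram
#'
#' For every 30-s staged epoch each channel is synthesised as band-limited
#' Gaussian noise whose one-sided power spectral density matches the
#' profile's stage-specific band levels, by drawing independent complex
#' Gaussian Fourier coefficients and inverse-transforming. Delta-band power
#' is scaled by `(1 + a)` on left and `(1 - a)` on right channels so the
#' planted asymmetry index equals `a` in expectation. Output is in uV.
#'
#' @param hyp A [hypnogram()].
#' @param profile A [subtype_profile()].
#' @param sampling_rate Sampling rate in Hz (>= 64).
#' @param seed Integer seed.
#' @return A [signal_record()] with the six canonical channels.
#' @export
simulate_eeg <- function(hyp, profile, sampling_rate = 128, seed = 1) {
  if (sampling_rate < 64) {
    stop("sampling_rate must be >= 64 Hz (Nyquist above the 32 Hz beta edge)",
         call. = FALSE)
  }
  set.seed(seed)
  fs <- sampling_rate
  n <- round(30 * fs)
  stopifnot(n %% 2 == 0)
  nf <- n %/% 2
  amp <- build_amplitude_spectra(profile, fs, n)
  chans <- eeg_channels()
  hemi <- ifelse(chans %in% left_channels(), "left", "right")
  E <- length(hyp$stages)
  out <- matrix(0, nrow = n * E, ncol = length(chans))
  for (e in seq_len(E)) {
    ak <- amp[[hyp$stages[e]]]
    rows <- ((e - 1) * n + 1):(e * n)
    for (c in seq_along(chans)) {
      av <- ak[[hemi[c]]]
      z <- complex(real = stats::rnorm(nf - 1), imaginary = stats::rnorm(nf - 1))
      X <- c(0, av[2:nf] * z, 0)             # DC and Nyquist carry no power
      full <- c(X, Conj(X[nf:2]))
      out[rows, c] <- Re(stats::fft(full, inverse = TRUE)) / n
    }
  }
  colnames(out) <- chans
  signal_record(out, fs, chans, start_time = hyp$lights_off)
}

#' Inject high-amplitude artifact epochs into a signal
#'
#' Contaminates a stated fraction of consecutive non-overlapping 5-s epochs
#' (all channels) with a high-amplitude 3 Hz transient scaled to 12x the
#' epoch's own RMS, and returns the ground-truth artifact mask.
#'
#' @param signal A [signal_record()].
#' @param fraction Proportion of 5-s epochs to contaminate, in \[0, 1\].
#' @param seed Integer seed.
#' @return List with elements `signal` (contaminated [signal_record()]) and
#'   `mask` (logical vector over 5-s epochs, `TRUE` = artifact).
#' @export
inject_artifacts <- function(signal, fraction, seed = 1) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  fs <- signal$sampling_rate
  ne <- floor(nrow(signal$samples) / (5 * fs))
  mask <- rep(FALSE, ne)
  if (fraction == 0 || ne == 0) return(list(signal = signal, mask = mask))
  set.seed(seed)
  k <- round(fraction * ne)
  idx <- sample.int(ne, k)
  mask[idx] <- TRUE
  x <- signal$samples
  nseg <- round(5 * fs)
  burst <- sin(2 * pi * 3 * (0:(nseg - 1)) / fs)
  for (e in idx) {
    rows <- ((e - 1) * nseg + 1):(e * nseg)
    for (c in seq_len(ncol(x))) {
      rms <- sqrt(mean(x[rows, c]^2))
      x[rows, c] <- x[rows, c] + 12 * rms * burst
    }
  }
  list(signal = signal_record(x, fs, signal$channel_labels, signal$start_time),
       mask = mask)
}

#' Simulate a subjective morning report
#'
#' Subjective TST is `objective TST * (1 - b)` plus zero-mean Gaussian noise
#' (SD `report_noise_frac * TST`), clipped to \[0, TIB\], so the expected
#' sleep-state misperception index of the report equals `b`. Subjective SOL
#' and WASO are the objective values plus noise; the sleep-quality rating is
#' drawn around `sq_mean` and clipped to 1..9.
#'
#' @param metrics A one-row sleep-metrics data.frame from
#'   [compute_sleep_metrics()] (fields `tst`, `sol`, `waso`, `tib`).
#' @param profile A [subtype_profile()].
#' @param seed Integer seed.
#' @return A [subjective_report()].
#' @export
simulate_subjective_report <- function(metrics, profile, seed = 1) {
  if (metrics$tst <= 0) stop("objective TST must be > 0", call. = FALSE)
  set.seed(seed)
  b <- profile$misperception_bias_b
  noise_sd <- profile$report_noise_frac * metrics$tst
  clip <- function(x, lo, hi) min(max(x, lo), hi)
  subj_tst <- clip(metrics$tst * (1 - b) + stats::rnorm(1, 0, noise_sd), 0, metrics$tib)
  subj_sol <- clip(metrics$sol + stats::rnorm(1, 0, 5), 0, metrics$tib)
  subj_waso <- clip(metrics$waso + stats::rnorm(1, 0, 5), 0, metrics$tib)
  sq <- clip(round(stats::rnorm(1, profile$sq_mean, profile$sq_sd)), 1, 9)
  subjective_report(subj_sol, subj_waso, subj_tst, sq)
}

# Draw per-subject deviations from a profile. The same sub-seed yields the
# same deviations for the habitual and restricted scenarios, so paired-night
# comparisons are within-subject.
jitter_profile <- function(profile, seed) {
  set.seed(seed)
  p <- profile
  p$target_tst <- max(30, stats::rnorm(1, p$target_tst, p$tst_sd))
  p$target_sol <- max(0, stats::rnorm(1, p$target_sol, p$sol_sd))
  p$target_waso <- max(0, stats::rnorm(1, p$target_waso, p$waso_sd))
  fac <- stats::rlnorm(5, 0, p$psd_cv)       # one factor per band, shared by stages
  names(fac) <- eeg_bands()$band
  p$stage_band_psd <- lapply(p$stage_band_psd, function(v) v * fac[names(v)])
  p$delta_asymmetry_a <- max(-0.99, min(0.99,
    stats::rnorm(1, p$delta_asymmetry_a, 0.005)))
  p$misperception_bias_b <- stats::rnorm(1, p$misperception_bias_b, 0.01)
  p$tib_jitter <- round(stats::rnorm(1, 0, 8))             # whole minutes
  p
}

# Apply the acute-restriction scenario to an (already jittered) profile and
# night duration: bedtime delayed, sleep consolidated, delta PSD boosted.
restrict_profile <- function(p, night_duration, restriction_min) {
  dur2 <- night_duration - restriction_min
  if (dur2 < 30) stop("restricted night would be shorter than 30 min", call. = FALSE)
  p$target_sol <- 0.6 * p$target_sol
  p$target_waso <- 0.6 * p$target_waso
  p$target_tst <- min(p$target_tst, dur2 - p$target_sol - p$target_waso)
  g <- p$restriction_delta_gain
  p$stage_band_psd <- lapply(p$stage_band_psd, function(v) { v["delta"] <- v["delta"] * g; v })
  list(profile = p, night_duration = dur2)
}

#' Simulate a synthetic PSG cohort
#'
#' Generates one night per subject: hypnogram, arousal annotations,
#' objective sleep metrics and a subjective report, with the ground-truth
#' subtype label retained. EEG signals are not stored (a full cohort would
#' not fit comfortably in memory); they are regenerated deterministically on
#' demand with [cohort_signal()]. Under `scenario = "restricted"` bedtime is
#' delayed by `restriction_min` minutes with the same rise time, subjects
#' keep their per-subject deviations from the habitual night, and delta PSD
#' is multiplied by the profile's `restriction_delta_gain`.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `psg_cohort`: list with `subjects` (per-subject
#'   lists: `id`, `label`, `hypnogram`, `arousals`, `metrics`, `report`,
#'   seeds) and `spec`.
#' @export
#' @examples
#' spec <- cohort_spec(insomnia_profiles(90), n_per_profile = 2,
#'                     night_duration = 90, seed = 7)
#' coh <- simulate_cohort(spec)
#' table(cohort_labels(coh))
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- list()
  sidx <- 0L
  scen_off <- if (spec$scenario == "restricted") 500000L else 0L
  for (pi in seq_along(spec$profiles)) {
    for (si in seq_len(spec$n_per_profile[pi])) {
      sidx <- sidx + 1L
      sub_seed <- derive_seed(spec$seed, sidx)
      p <- jitter_profile(spec$profiles[[pi]], sub_seed)
      dur <- spec$night_duration + p$tib_jitter
      lights_off <- spec$lights_off
      if (spec$scenario == "restricted") {
        r <- restrict_profile(p, dur, spec$restriction_min)
        p <- r$profile
        dur <- r$night_duration
        lights_off <- lights_off + 60 * spec$restriction_min
      }
      # keep targets feasible after jitter
      tot <- p$target_sol + p$target_tst + p$target_waso
      if (tot > dur) {
        sc <- dur / tot
        p$target_sol <- p$target_sol * sc
        p$target_tst <- p$target_tst * sc
        p$target_waso <- p$target_waso * sc
      }
      seed_h <- derive_seed(sub_seed + scen_off, 1)
      seed_e <- derive_seed(sub_seed + scen_off, 2)
      seed_a <- derive_seed(sub_seed + scen_off, 3)
      seed_r <- derive_seed(sub_seed + scen_off, 4)
      hyp <- simulate_hypnogram(p, dur, seed_h, lights_off = lights_off)
      met <- compute_sleep_metrics(hyp)
      set.seed(seed_a)
      n_ev <- stats::rpois(1, p$arousal_rate * met$tst / 60)
      sleep_ep <- which(hyp$stages != "W")
      aro <- if (n_ev > 0 && length(sleep_ep) > 0) {
        ep <- sample(sleep_ep, n_ev, replace = TRUE)
        arousal_annotations((ep - 1) * 30 + stats::runif(n_ev, 0, 30),
                            stats::runif(n_ev, 3, 15))
      } else arousal_annotations()
      met <- compute_sleep_metrics(hyp, aro)
      rep <- simulate_subjective_report(met, p, seed_r)
      subjects[[sidx]] <- list(
        id = sprintf("S%03d", sidx), label = p$label, profile = p,
        night_duration = dur, hypnogram = hyp, arousals = aro,
        metrics = met, report = rep, seed_eeg = seed_e
      )
    }
  }
  structure(list(subjects = subjects, spec = spec), class = "psg_cohort")
}

#' @export
print.psg_cohort <- function(x, ...) {
  cat(sprintf("<psg_cohort> %d subjects, %s scenario, %g Hz, %g-min nights\n",
              length(x$subjects), x$spec$scenario, x$spec$sampling_rate,
              x$spec$night_duration))
  print(table(cohort_labels(x)))
  invisible(x)
}

#' Ground-truth subtype labels of a synthetic cohort
#' @param cohort A `psg_cohort` from [simulate_cohort()].
#' @return Character vector named by subject id.
#' @export
cohort_labels <- function(cohort) {
  stats::setNames(vapply(cohort$subjects, `[[`, "", "label"),
                  vapply(cohort$subjects, `[[`, "", "id"))
}

#' Regenerate the EEG signal of one cohort subject
#'
#' Signals are derived deterministically from the subject's stored seed, so
#' the same cohort always yields byte-identical traces.
#'
#' @param cohort A `psg_cohort`.
#' @param i Subject index.
#' @return A [signal_record()].
#' @export
cohort_signal <- function(cohort, i) {
  s <- cohort$subjects[[i]]
  simulate_eeg(s$hypnogram, s$profile, cohort$spec$sampling_rate, s$seed_eeg)
}
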