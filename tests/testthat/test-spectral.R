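test_that("segmentation yields six 5-s sub-epochs per 30-s staged epoch", {
  p <- insomnia_profiles(90)$NNS
  h <- hypnogram(rep(c("N2", "N3"), 10))           # 10 min
  sig <- simulate_eeg(h, p, 128, seed = 1)
  ep <- segment_epochs(sig, h)
  expect_equal(dim(ep$samples), c(640, 120, 6))
  expect_identical(ep$stage, rep(h$stages, each = 6))
  short <- signal_record(sig$samples[1:1000, ], 128, eeg_channels())
  expect_error(segment_epochs(short, h), "shorter")
})

test_that("PSD satisfies the analytic sinusoid and Parseval oracles", {
  fs <- 128
  t <- (0:639) / fs
  sp <- compute_psd(10 * sin(2 * pi * 2 * t), fs)
  total <- sum(sp$psd) * 0.2
  expect_lt(abs(total - 50) / 50, 0.05)            # A^2/2, window-corrected
  expect_equal(sp$freqs[2] - sp$freqs[1], 0.2)
  bp <- integrate_bands(sp)
  expect_gt(bp["delta"] / sum(bp), 0.99)

  # Parseval: integral of PSD equals windowed mean power on every epoch
  set.seed(42)
  err <- replicate(1000, {
    x <- rnorm(640, sd = 3)
    s <- compute_psd(x, fs)
    w <- somnotype:::hann_window(640)
    abs(sum(s$psd) * 0.2 - sum((x * w)^2) / sum(w^2))
  })
  expect_lt(mean(err) / 9, 0.01)

  expect_equal(max(abs(compute_psd(rep(0, 640), fs)$psd)), 0)
  expect_error(compute_psd(c(rep(0, 639), NA), fs), "non-finite")
})

test_that("band integration matches band widths and is exactly additive", {
  freqs <- seq(0, 64, by = 0.2)
  flat <- structure(list(freqs = freqs, psd = rep(1, length(freqs))),
                    class = "epoch_spectrum")
  expect_equal(integrate_bands(flat),
               c(delta = 4, theta = 3.5, alpha = 4, sigma = 3, beta = 17))
  wts <- somnotype:::band_weights(freqs, 0.5, 32)
  set.seed(7)
  for (r in 1:20) {
    psd <- runif(length(freqs))
    sp <- structure(list(freqs = freqs, psd = psd), class = "epoch_spectrum")
    total <- sum(wts * psd)
    expect_lt(abs(sum(integrate_bands(sp)) - total) / total, 1e-3)
  }
})

test_that("band edges follow the half-open convention, beta closed at 32", {
  expect_identical(band_of(c(0.5, 4.4, 4.5, 8, 12, 15, 31.9, 32)),
                   c("delta", "delta", "theta", "alpha", "sigma", "beta",
                     "beta", "beta"))
  expect_true(is.na(band_of(0.4)))
  expect_true(is.na(band_of(32.2)))
})

test_that("artifact detection recovers injected artifacts with few false alarms", {
  p <- insomnia_profiles(90)$NNS
  h <- hypnogram(rep(c("N2", "N3", "N2", "R"), 8))  # 16 min, stage-varying
  sig <- simulate_eeg(h, p, 128, seed = 11)
  clean_flags <- detect_artifacts(segment_epochs(sig, h))
  expect_lte(mean(clean_flags), 0.02)

  ia <- inject_artifacts(sig, 0.3, seed = 2)
  flags <- detect_artifacts(segment_epochs(ia$signal, h))
  sens <- mean(flags[ia$mask, ])
  expect_gte(sens, 0.9)
  # monotonicity: injecting artifacts never decreases the flagged count
  expect_gte(sum(flags), sum(clean_flags))

  zero <- signal_record(matrix(0, 640 * 24, 6, dimnames = list(NULL, eeg_channels())), 128)
  zf <- detect_artifacts(segment_epochs(zero, hypnogram(rep("W", 4))))
  expect_false(any(zf))
})

test_that("trace quality uses the strict >25% exclusion boundary", {
  flags <- matrix(FALSE, 100, 2, dimnames = list(NULL, c("F3-M2", "F4-M1")))
  flags[1:26, 1] <- TRUE
  flags[1:25, 2] <- TRUE
  q <- assess_trace_quality(flags)
  expect_false(q$usable[q$channel == "F3-M2"])
  expect_true(q$usable[q$channel == "F4-M1"])
  expect_true(attr(q, "analyzable"))
  all_bad <- matrix(TRUE, 10, 6, dimnames = list(NULL, eeg_channels()))
  expect_false(attr(assess_trace_quality(all_bad), "analyzable"))
})

test_that("stage aggregation averages scopes correctly and flags missing cells", {
  # constructed epoch powers: left channels 30, right channels 10
  ne <- 12
  powers <- array(0, dim = c(ne, 6, 5),
                  dimnames = list(NULL, eeg_channels(), eeg_bands()$band))
  powers[, left_channels(), ] <- 30
  powers[, right_channels(), ] <- 10
  stage <- rep("N2", ne)
  flags <- matrix(FALSE, ne, 6, dimnames = list(NULL, eeg_channels()))
  q <- assess_trace_quality(flags)
  out <- aggregate_stage_band_power(powers, stage, flags, q)
  cell <- function(st, sc) out$power[out$stage == st & out$scope == sc &
                                       out$band == "delta"]
  expect_equal(cell("N2", "global"), 20)
  expect_equal(cell("N2", "left"), 30)
  expect_equal(cell("N2", "right"), 10)
  # no R epochs: missing cell (NA), not zero
  expect_true(is.na(cell("R", "global")))
  expect_equal(out$n_epochs[out$stage == "R" & out$scope == "global"][1], 0L)
  # NREM aggregate pools N1/N2/N3 epochs
  expect_equal(cell("NREM", "global"), 20)
  # all flagged epochs in a stage -> subject-level aggregation still works,
  # unusable channels are dropped from scope means
  flags2 <- flags; flags2[, "F3-M2"] <- TRUE
  q2 <- assess_trace_quality(flags2)
  out2 <- aggregate_stage_band_power(powers, stage, flags2, q2)
  expect_equal(out2$power[out2$stage == "N2" & out2$scope == "left" &
                            out2$band == "delta"], 30)
  expect_false("F3-M2" %in% out2$scope)
})

test_that("planted stage PSD is recovered through the full spectral chain", {
  p <- insomnia_profiles(90)$NNS
  h <- stage_block("N2", 10)
  sig <- simulate_eeg(h, p, 128, seed = 21)
  pw <- stage_band_power(sig, h)
  for (b in c("delta", "sigma", "beta")) {
    bw <- with(eeg_bands(), hi[band == b] - lo[band == b])
    want <- p$stage_band_psd$N2[[b]] * bw
    got <- pw$power[pw$stage == "N2" & pw$scope == "global" & pw$band == b]
    expect_lt(abs(got - want) / want, 0.05)
  }
})
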