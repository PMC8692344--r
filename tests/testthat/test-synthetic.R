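test_that("simulated hypnograms hit their macro targets and are seeded", {
  p <- subtype_profile("X", target_tst = 330, target_sol = 40, target_waso = 70)
  m <- t(vapply(1:200, function(s) {
    unlist(compute_sleep_metrics(simulate_hypnogram(p, 450, s))[c("tst", "sol", "waso")])
  }, numeric(3)))
  expect_lt(abs(mean(m[, "tst"]) - 330), 10)
  expect_lt(abs(mean(m[, "sol"]) - 40), 4)     # within 10% of target
  expect_lt(abs(mean(m[, "waso"]) - 70), 7)
  expect_identical(simulate_hypnogram(p, 450, 7)$stages,
                   simulate_hypnogram(p, 450, 7)$stages)
})

test_that("degenerate all-sleep profile yields no wake after epoch 0", {
  p <- subtype_profile("Y", target_tst = 90, target_sol = 0, target_waso = 0)
  h <- simulate_hypnogram(p, 90, 1)
  expect_equal(sum(h$stages[-1] == "W"), 0)
  expect_error(simulate_hypnogram(subtype_profile("Z", 400, 40, 70), 450),
               "infeasible")
})

test_that("synthetic EEG matches planted stage band power", {
  p <- insomnia_profiles(90)$NNS
  h <- stage_block("N3", 30)
  sig <- simulate_eeg(h, p, 128, seed = 2)
  pw <- stage_band_power(sig, h)
  got <- pw$power[pw$stage == "N3" & pw$scope == "global" & pw$band == "delta"]
  want <- p$stage_band_psd$N3[["delta"]] * 4   # 4 Hz delta band width
  expect_lt(abs(got - want) / want, 0.05)
  # wide bands within 5%; narrow bands adjacent to the large delta PSD step
  # carry a small positive Hann-leakage bias, so 10% there
  tol <- c(delta = 0.05, theta = 0.10, alpha = 0.10, sigma = 0.10, beta = 0.05)
  for (b in eeg_bands()$band) {
    got_b <- pw$power[pw$stage == "N3" & pw$scope == "global" & pw$band == b]
    bw <- with(eeg_bands(), hi[band == b] - lo[band == b])
    want_b <- p$stage_band_psd$N3[[b]] * bw
    expect_lt(abs(got_b - want_b) / want_b, tol[[b]])
  }
  expect_error(simulate_eeg(h, p, 32), "sampling_rate")
})

test_that("delta-only PSD concentrates power in the delta band", {
  p <- insomnia_profiles(90)$NNS
  p$stage_band_psd <- lapply(p$stage_band_psd, function(v) {
    v[] <- 1e-9; v["delta"] <- 20; v
  })
  sig <- simulate_eeg(stage_block("N3", 5), p, 128, seed = 3)
  bp <- integrate_bands(compute_psd(sig$samples[1:640, 1], 128))
  expect_gt(bp["delta"] / sum(bp), 0.95)
})

test_that("zero planted asymmetry gives symmetric hemispheric power", {
  p <- insomnia_profiles(90)$NNS
  p$delta_asymmetry_a <- 0
  sig <- simulate_eeg(stage_block("N3", 30), p, 128, seed = 4)
  pw <- stage_band_power(sig, stage_block("N3", 30))
  expect_lt(abs(compute_iai(pw, "N3")$iai), 0.02)
})

test_that("artifact injection counts, masks and amplitudes are correct", {
  p <- insomnia_profiles(90)$NNS
  h <- stage_block("N2", 10)
  sig <- simulate_eeg(h, p, 128, seed = 5)
  same <- inject_artifacts(sig, 0, seed = 1)
  expect_identical(same$signal$samples, sig$samples)
  expect_false(any(same$mask))
  ia <- inject_artifacts(sig, 0.3, seed = 1)
  expect_equal(sum(ia$mask), round(0.3 * 120))
  rms <- function(rows, c) sqrt(mean(ia$signal$samples[rows, c]^2))
  nseg <- 5 * 128
  ep_rms <- vapply(seq_along(ia$mask),
                   function(e) rms(((e - 1) * nseg + 1):(e * nseg), 1), 0)
  expect_true(all(ep_rms[ia$mask] >= 5 * median(ep_rms[!ia$mask])))
  expect_error(inject_artifacts(sig, 1.2), "fraction")
})

test_that("subjective reports encode the planted misperception bias", {
  p <- insomnia_profiles(450)$SSDD
  h <- simulate_hypnogram(p, 450, 1)
  met <- compute_sleep_metrics(h)
  ssm <- vapply(1:500, function(s) {
    compute_ssm(met$tst, simulate_subjective_report(met, p, s)$subj_tst)$ssm
  }, 0)
  expect_lt(abs(mean(ssm) - 0.14), 0.01)
  # zero bias, zero noise: exact identity
  p0 <- p; p0$misperception_bias_b <- 0; p0$report_noise_frac <- 0
  r0 <- simulate_subjective_report(met, p0, 1)
  expect_equal(r0$subj_tst, met$tst)
  sq <- vapply(1:200, function(s) simulate_subjective_report(met, p, s)$sq, 1L)
  expect_true(all(sq >= 1 & sq <= 9))
})

test_that("cohorts have the requested composition and are deterministic", {
  spec <- cohort_spec(insomnia_profiles(90), n_per_profile = c(3, 2, 2),
                      night_duration = 90, seed = 5)
  coh <- simulate_cohort(spec)
  expect_equal(unname(table(cohort_labels(coh))[c("SSDD", "NSDD", "NNS")]),
               c(3L, 2L, 2L), ignore_attr = TRUE)
  coh2 <- simulate_cohort(spec)
  expect_identical(coh$subjects[[4]]$hypnogram$stages,
                   coh2$subjects[[4]]$hypnogram$stages)
  expect_identical(cohort_signal(coh, 2)$samples, cohort_signal(coh2, 2)$samples)
})

test_that("restricted scenario shifts bedtime by the restriction, same rise time", {
  s1 <- cohort_spec(insomnia_profiles(450), n_per_profile = 2,
                    night_duration = 450, seed = 9)
  s2 <- s1; s2$scenario <- "restricted"
  c1 <- simulate_cohort(s1); c2 <- simulate_cohort(s2)
  tib1 <- vapply(c1$subjects, function(s) s$metrics$tib, 0)
  tib2 <- vapply(c2$subjects, function(s) s$metrics$tib, 0)
  expect_equal(tib2, tib1 - 120)
  expect_equal(as.numeric(c2$subjects[[1]]$hypnogram$lights_off -
                            c1$subjects[[1]]$hypnogram$lights_off, units = "mins"),
               120)
  expect_equal(c2$subjects[[1]]$hypnogram$lights_on,
               c1$subjects[[1]]$hypnogram$lights_on)
})
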