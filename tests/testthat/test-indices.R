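fake_power <- function(left_delta, right_delta, stage = "N3") {
  rows <- rbind(
    data.frame(stage = stage, scope = left_channels(), band = "delta",
               power = left_delta, n_epochs = 100L),
    data.frame(stage = stage, scope = right_channels(), band = "delta",
               power = right_delta, n_epochs = 100L)
  )
  class(rows) <- c("stage_band_power", "data.frame")
  rows
}

test_that("IAI matches its defining ratio and sign convention", {
  expect_equal(compute_iai(fake_power(10, 10 / 3), "N3")$iai, 0.5)
  expect_equal(compute_iai(fake_power(7, 7), "N3")$iai, 0)
  expect_gt(compute_iai(fake_power(9, 3), "N3")$iai, 0)  # left > right: positive
})

test_that("IAI is antisymmetric and scale invariant", {
  set.seed(5)
  for (r in 1:25) {
    L <- runif(3, 1, 50); R <- runif(3, 1, 50)
    iai <- compute_iai(fake_power(L, R), "N3")$iai
    flipped <- compute_iai(fake_power(R, L), "N3")$iai
    expect_equal(flipped, -iai)
    c_ <- runif(1, 0.1, 10)
    expect_equal(compute_iai(fake_power(c_ * L, c_ * R), "N3")$iai, iai)
    expect_gte(iai, -1); expect_lte(iai, 1)
  }
})

test_that("IAI is missing (not zero) without usable hemisphere data", {
  pw <- fake_power(10, 5)
  onesided <- pw[pw$scope %in% left_channels(), ]
  expect_true(is.na(compute_iai(onesided, "N3")$iai))
  zero <- fake_power(0, 0)
  expect_true(is.na(compute_iai(zero, "N3")$iai))
  expect_true(is.na(compute_iai(pw, "R")$iai))   # stage absent from table
})

test_that("planted asymmetry is recovered from synthetic N3 EEG", {
  for (a in c(0, 0.1, 0.3)) {
    p <- insomnia_profiles(90)$NNS
    p$delta_asymmetry_a <- a
    h <- stage_block("N3", 30)
    sig <- simulate_eeg(h, p, 128, seed = 100 + round(100 * a))
    pw <- stage_band_power(sig, h)
    expect_lt(abs(compute_iai(pw, "N3")$iai - a), 0.02)
  }
})

test_that("SSM follows its defining formula, sign and domain", {
  expect_equal(compute_ssm(400, 400)$ssm, 0)
  expect_equal(compute_ssm(400, 344)$ssm, 0.14)
  expect_equal(compute_ssm(300, 360)$ssm, -0.2)
  for (T_ in c(30, 100, 400, 480)) {
    for (b in c(-0.5, 0, 0.1, 0.5, 1)) {
      expect_equal(compute_ssm(T_, (1 - b) * T_)$ssm, b)
    }
  }
  expect_error(compute_ssm(0, 100), "objective_tst")
  expect_error(compute_ssm(100, -5), "subjective_tst")
})
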