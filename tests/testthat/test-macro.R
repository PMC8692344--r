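test_that("worked hypnogram reproduces hand-counted metrics", {
  h <- hypnogram(c(rep("W", 10), rep("N1", 2), rep("N2", 100),
                   rep("R", 20), rep("W", 4)))
  m <- compute_sleep_metrics(h)
  expect_equal(m$tib, 68)
  expect_equal(m$sol, 5)
  expect_equal(m$tst, 61)
  expect_equal(m$waso, 0)
  expect_equal(m$terminal_wake, 2)
  expect_equal(m$se, 100 * 61 / 68, tolerance = 1e-12)
  expect_equal(m$rem_latency, 51)
  expect_equal(m$n1_pct + m$n2_pct + m$n3_pct + m$rem_pct, 100)
})

test_that("all-wake hypnogram follows the degenerate contract", {
  m <- compute_sleep_metrics(hypnogram(rep("W", 40)))
  expect_equal(m$tst, 0)
  expect_equal(m$se, 0)
  expect_equal(m$sol, m$tib)
  expect_equal(m$waso, 0)
  expect_true(is.na(m$rem_latency))
})

test_that("arousal indices use stage-time denominators", {
  h <- hypnogram(c(rep("N2", 200), rep("R", 40)))    # 100 min NREM, 20 min REM
  a <- arousal_annotations(onset_s = c(100, 200, 300, 400, 500, 6100),
                           duration_s = rep(5, 6))    # 5 in N2, 1 in R
  m <- compute_sleep_metrics(h, a)
  expect_equal(m$arousal_index_total, 6 / 2)          # 6 events over 2 h sleep
  expect_equal(m$arousal_index_nrem, 5 / (100 / 60))
  expect_equal(m$arousal_index_rem, 1 / (20 / 60))
})

test_that("TIB partition identity holds exactly on random hypnograms", {
  set.seed(3)
  for (r in 1:1000) {
    n <- sample(5:60, 1)
    h <- hypnogram(sample(sleep_stages(), n, replace = TRUE,
                          prob = c(0.3, 0.1, 0.3, 0.15, 0.15)))
    m <- compute_sleep_metrics(h)
    expect_identical(m$sol + m$tst + m$waso + m$terminal_wake, m$tib)
    expect_identical(m$nrem_min, m$n1_min + m$n2_min + m$n3_min)
  }
})

test_that("appending terminal wake padding only grows TIB and terminal wake", {
  h <- hypnogram(c(rep("W", 4), rep("N2", 20), rep("R", 6)))
  hp <- hypnogram(c(h$stages, rep("W", 10)))
  m <- compute_sleep_metrics(h); mp <- compute_sleep_metrics(hp)
  expect_equal(mp$tst, m$tst)
  expect_equal(mp$sol, m$sol)
  expect_equal(mp$waso, m$waso)
  expect_equal(mp$terminal_wake, m$terminal_wake + 5)
  expect_equal(mp$tib, m$tib + 5)
})
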