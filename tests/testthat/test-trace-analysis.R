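test_that("AP detection finds exactly the rendered spikes", {
  tr <- generate_trace(trace_spec("regular", fr_bpm = 400, duration_s = 30))
  train <- detect_aps(tr$V, dt = 1e-3)
  expect_equal(nrow(train$spikes), nrow(tr$truth$spikes))

  # flat trace: no events
  expect_equal(nrow(detect_aps(rep(-60, 5000), dt = 1e-3)$spikes), 0)

  # subthreshold oscillation peaking at -30 mV stays invisible at -20 mV
  t <- seq(0, 5, by = 1e-3)
  v <- -45 + 15 * sin(2 * pi * 5 * t)
  expect_equal(nrow(detect_aps(v, dt = 1e-3, threshold = -20)$spikes), 0)

  # non-uniform sampling is refused
  expect_error(detect_aps(c(-60, 0, -60, 0), times = c(0, 0.1, 0.15, 0.4)),
               "non-uniform")
})

test_that("firing rate follows 60 / mean ISI with degenerate guards", {
  tt <- seq(0.15, 30, by = 0.15)
  train <- sancpace:::new_ap_train(tt, rep(20, length(tt)))
  expect_equal(firing_rate(train), 400, tolerance = 1e-9)

  one <- sancpace:::new_ap_train(5, 20)
  expect_equal(firing_rate(one, c(0, 30)), 0)

  # time-scaling property: stretching time by k divides the rate by k
  for (k in c(0.5, 2, 3)) {
    scaled <- sancpace:::new_ap_train(tt * k, rep(20, length(tt)))
    expect_equal(firing_rate(scaled), firing_rate(train) / k,
                 tolerance = 1e-9)
  }
})

test_that("pattern classification separates R, I and N", {
  tt <- seq(0.15, 30, by = 0.15)
  reg <- sancpace:::new_ap_train(tt, rep(20, length(tt)))
  expect_equal(classify_pattern(reg, c(0, 30))$label, "R")

  empty <- sancpace:::new_ap_train(numeric(0), numeric(0))
  expect_equal(classify_pattern(empty, c(0, 30))$label, "N")

  # clustered bursts (6 spikes every 3 s) are irregular: huge ISI CV
  bt <- as.vector(outer((0:5) * 0.15, seq(0, 27, by = 3), `+`))
  burst <- sancpace:::new_ap_train(sort(bt), rep(20, length(bt)))
  expect_equal(classify_pattern(burst, c(0, 30))$label, "I")

  # a handful of stray spikes in a long window count as no-firing
  stray <- sancpace:::new_ap_train(c(10, 10.2), c(20, 20))
  expect_equal(classify_pattern(stray, c(0, 30))$label, "N")

  expect_error(classify_pattern(reg, c(0, 5)), "at least 10 s")
})

test_that("burst metrics recover designed onset frequencies", {
  mk <- function(period, n_bursts, spikes = 5, isi = 0.15) {
    tt <- as.vector(outer((seq_len(spikes) - 1) * isi,
                          (seq_len(n_bursts) - 1) * period, `+`))
    sancpace:::new_ap_train(sort(tt), rep(20, length(tt)))
  }
  expect_equal(burst_metrics(mk(10, 6))$freq_hz, 0.1, tolerance = 1e-9)
  expect_equal(burst_metrics(mk(2.857, 20))$freq_hz, 1 / 2.857,
               tolerance = 1e-9)

  b <- burst_metrics(mk(10, 6))
  expect_equal(b$n_bursts, 6)
  expect_equal(b$spikes_per_burst, 5)

  single <- burst_metrics(mk(10, 1))
  expect_false(single$freq_defined)
  expect_true(is.na(single$freq_hz))
})

test_that("alternans detection applies the 5% relative threshold", {
  mk <- function(amps) sancpace:::new_ap_train(seq_along(amps) * 0.15, amps)

  alt <- detect_alternans(mk(c(30, 20, 30, 20)))
  expect_true(alt$flag)
  expect_equal(alt$ratio, 1 / 3, tolerance = 1e-9)

  expect_false(detect_alternans(mk(rep(25, 8)))$flag)
  expect_false(detect_alternans(mk(c(30, 29.5, 30, 29.5)))$flag)
  expect_false(detect_alternans(mk(c(30, 20, 30)))$flag)  # too short
})

test_that("phase sampling windows land where the protocol says", {
  # null protocol: both phases match the preictal rate within 1%
  tr0 <- fx_trace_null()
  train <- detect_aps(tr0$V, dt = tr0$dt)
  pre <- firing_rate(train, c(45, 60))
  li <- sample_phase_fr(tr0, "ictal")
  lp <- sample_phase_fr(tr0, "postictal")
  expect_equal(li$label, "R")
  expect_equal(lp$label, "R")
  expect_lt(abs(li$fr_bpm - pre) / pre, 0.01)
  expect_lt(abs(lp$fr_bpm - pre) / pre, 0.01)
  # ictal window is the last 15 s of the clamp; postictal window starts
  # 30 s after the ramp end
  expect_equal(li$window, c(105, 120))
  expect_equal(lp$window, c(195, 210))

  # an asystolic event reads (N, N)
  tr9 <- fx_trace9()
  expect_equal(sample_phase_fr(tr9, "ictal")$label, "N")
  expect_equal(sample_phase_fr(tr9, "postictal")$label, "N")

  # an oscillatory event reads (I, I)
  tr5 <- fx_trace5()
  expect_equal(sample_phase_fr(tr5, "ictal")$label, "I")
  expect_equal(sample_phase_fr(tr5, "postictal")$label, "I")
})

test_that("ictal bursts outpace postictal bursts in an oscillatory event", {
  tr5 <- fx_trace5()
  train <- detect_aps(tr5$V, dt = tr5$dt)
  bi <- burst_metrics(sancpace:::window_train(train, c(105, 120)))
  bp <- burst_metrics(sancpace:::window_train(train, c(195, 210)))
  expect_true(bi$freq_defined && bp$freq_defined)
  expect_gt(bi$freq_hz, bp$freq_hz)
})
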