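test_that("protocol construction enforces the clamp invariants", {
  pr <- seizure_protocol()
  expect_equal(sancpace:::protocol_duration(pr), 240)
  expect_gt(pr$Si, pr$Pi)   # ictal sympathetic dominance
  expect_gt(pr$Pp, pr$Pi)   # postictal parasympathetic dominance
  expect_error(seizure_protocol(tau = 0), "durations")
  expect_error(seizure_protocol(Sp = -1.5), "-100%")
})

test_that("clamp schedule reproduces the protocol arithmetic", {
  ctx <- fx_ctx12()   # pna_mult = 1 at the transition state

  # ictal drive is S x (1 + Si): Si = 100% doubles sympathetic drive
  sch <- autonomic_clamp_schedule(seizure_protocol(Si = 1.0), ctx)
  expect_equal(drive_at(sch, 61)$sna, 2.0)

  # null protocol leaves the drive at baseline throughout
  sch0 <- autonomic_clamp_schedule(
    seizure_protocol(Si = 0, Pi = 0, Sp = 0, Pp = 0), ctx)
  d0 <- drive_at(sch0, seq(0, 240, by = 0.5))
  expect_true(all(d0$sna == 1) && all(d0$pna == 1))

  # minimal postictal sympathetic tone: Sp = -100% -> sna = 0 after the ramp
  schm <- autonomic_clamp_schedule(seizure_protocol(Sp = -1), ctx)
  expect_equal(drive_at(schm, 170)$sna, 0)

  # the ramp is linear: its midpoint is the mean of the clamp endpoints
  pr <- seizure_protocol(Si = 1.0, Sp = -1)
  sch <- autonomic_clamp_schedule(pr, ctx)
  tm <- pr$t_pre + pr$tau + pr$tau_p / 2
  expect_equal(drive_at(sch, tm)$sna, ((1 + pr$Si) + (1 + pr$Sp)) / 2,
               tolerance = 1e-12)
})

test_that("schedule has one discontinuity and an affine ramp", {
  sch <- autonomic_clamp_schedule(seizure_protocol(), fx_ctx12())
  tt <- seq(0, 240, by = 0.05)
  d <- drive_at(sch, tt)
  jumps <- abs(diff(d$sna)) + abs(diff(d$pna))
  # one step at seizure onset (t = 60); elsewhere changes are ramp-sized
  big <- which(jumps > 0.1)
  expect_length(big, 1)
  expect_equal(tt[big], 60, tolerance = 0.05 + 1e-9)
  # second differences vanish on the ramp interior
  ramp <- d$sna[tt > 120.01 & tt < 164.99]
  expect_lt(max(abs(diff(diff(ramp)))), 1e-12)
})

test_that("negative drive multipliers are rejected", {
  expect_error(
    autonomic_clamp_schedule(seizure_protocol(Si = -1, Sp = -1, Pp = 0),
                             fx_ctx12()),
    NA)  # Si = -100% itself is legal (multiplier 0)
  expect_error(seizure_protocol(Pi = -1.2), "-100%")
})

test_that("circadian context hits its documented extrema", {
  sleep <- circadian_context(6, "natural")
  awake <- circadian_context(18, "natural")
  trans <- circadian_context(12, "natural")

  # PNA peaks during daytime sleep; temperature and LCR trough there
  expect_gt(sleep$pna_mult, awake$pna_mult)
  expect_lt(sleep$bt, awake$bt)
  expect_lt(sleep$lcr_mult, awake$lcr_mult)

  # the transition state sits at the mesor of every waveform
  expect_equal(trans$pna_mult, 1, tolerance = 1e-12)
  expect_equal(trans$bt, 37, tolerance = 1e-12)
  expect_equal(trans$lcr_mult, 1, tolerance = 1e-12)
})

test_that("forced vigilance shifts only the PNA channel", {
  nat6 <- circadian_context(6, "natural")
  fa6 <- circadian_context(6, "forced_awake")
  nat18 <- circadian_context(18, "natural")
  fs18 <- circadian_context(18, "forced_sleep")

  # forced wakefulness at ZT6 borrows the natural ZT18 parasympathetic level
  expect_equal(fa6$pna_mult, nat18$pna_mult, tolerance = 1e-12)
  expect_identical(fa6$bt, nat6$bt)
  expect_identical(fa6$lcr_mult, nat6$lcr_mult)

  expect_equal(fs18$pna_mult, nat6$pna_mult, tolerance = 1e-12)
  expect_identical(fs18$bt, nat18$bt)
  expect_identical(fs18$lcr_mult, nat18$lcr_mult)

  # undefined combinations are refused
  expect_error(circadian_context(6, "forced_sleep"), "natural sleep")
  expect_error(circadian_context(18, "forced_awake"), "natural wakefulness")
})

test_that("exactly five canonical states exist", {
  st <- canonical_states()
  expect_named(st, c("awake", "transition", "sleep", "forced_sleep",
                     "forced_awake"))
  zts <- vapply(st, `[[`, numeric(1), "zt")
  expect_equal(unname(zts), c(18, 12, 6, 18, 6))
})

test_that("factor subsets isolate individual circadian channels", {
  bt_only <- apply_factor_subset(18, "BT")
  expect_equal(bt_only$bt, bt_waveform(18))
  expect_equal(bt_only$pna_mult, 1)
  expect_equal(bt_only$lcr_mult, 1)

  full <- apply_factor_subset(6, c("PNA", "BT", "LCR"))
  nat <- circadian_context(6, "natural")
  expect_equal(full$pna_mult, nat$pna_mult)
  expect_equal(full$bt, nat$bt)
  expect_equal(full$lcr_mult, nat$lcr_mult)

  ref <- apply_factor_subset(6, character(0))
  expect_equal(ref$pna_mult, 1)
  expect_equal(ref$bt, 37)

  expect_error(apply_factor_subset(6, "XYZ"), "unknown circadian factor")
})

test_that("waveforms are 24-h periodic with extrema at the stated phases", {
  zt <- seq(0, 23.9, by = 0.1)
  expect_equal(bt_waveform(zt), bt_waveform(zt + 24), tolerance = 1e-12)
  expect_gt(pna_waveform(6), pna_waveform(18))
  # LCR peaks at ZT18: grid-scan argmax
  expect_equal(zt[which.max(lcr_waveform(zt))], 18)
  expect_equal(zt[which.max(pna_waveform(zt))], 6)
})
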