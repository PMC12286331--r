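test_that("default parameters are positive and serialize losslessly", {
  p <- fx_params()
  conds <- unlist(p[c("g_cal", "g_cat", "g_hcn", "g_k", "g_kach", "g_bna")])
  expect_true(all(conds > 0))

  f <- withr::local_tempfile(fileext = ".json")
  write_params(p, f)
  p2 <- read_params(f)
  expect_equal(unclass(p2)[sanc_param_names()], unclass(p)[sanc_param_names()])

  # unknown keys are rejected at both boundaries
  expect_error(build_default_params(not_a_param = 1), "unknown parameter")
  bad <- jsonlite::read_json(f, simplifyVector = TRUE)
  bad$bogus_key <- 1
  jsonlite::write_json(bad, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_params(f), "bogus_key")
})

test_that("state validation reports each violated invariant", {
  expect_length(check_state(default_state()), 0)

  s <- default_state(); s["d_L"] <- 1.2
  expect_match(check_state(s), "gate out of", all = FALSE)

  s <- default_state(); s["Nai"] <- -1
  expect_match(check_state(s), "negative concentration", all = FALSE)

  s <- default_state(); s["V"] <- -120
  expect_match(check_state(s), "membrane potential", all = FALSE)

  s <- default_state(); s["Cai"] <- NaN
  expect_match(check_state(s), "non-finite", all = FALSE)
})

test_that("K-family currents vanish at the K reversal potential", {
  p <- fx_params()
  rtf <- 0.0861733 * (273.15 + 37)
  e_k <- rtf * log(p$ko / p$ki)
  s <- default_state(); s["V"] <- e_k
  cur <- compute_currents(s, p, drive_input())
  expect_equal(cur$i_k, 0, tolerance = 1e-12)
  expect_equal(cur$i_kach, 0, tolerance = 1e-12)
})

test_that("modulation hooks scale their target currents as contracted", {
  p <- fx_params()
  s <- default_state()

  # doubling LCR doubles the funny current
  c1 <- compute_currents(s, p, drive_input(lcr = 1))
  c2 <- compute_currents(s, p, drive_input(lcr = 2))
  expect_equal(c2$i_hcn, 2 * c1$i_hcn, tolerance = 1e-12)

  # raising parasympathetic drive strictly increases |I_KACh|
  k1 <- abs(compute_currents(s, p, drive_input(pna = 1))$i_kach)
  k2 <- abs(compute_currents(s, p, drive_input(pna = 2))$i_kach)
  expect_gt(k2, k1)

  # sympathetic upregulation of the Ca currents acts through the slow
  # phosphorylation state: monotone increasing in that state
  s_hi <- s; s_hi["pka"] <- 2
  c_hi <- compute_currents(s_hi, p, drive_input(sna = 2))
  expect_gt(abs(c_hi$i_cal), abs(c1$i_cal))
  expect_gt(abs(c_hi$i_cat), abs(c1$i_cat))

  # non-finite states are rejected, never silently clamped
  s_bad <- s; s_bad["V"] <- Inf
  expect_error(compute_currents(s_bad, p, drive_input()), "non-finite")
})

test_that("net current equals the sum of its components for random states", {
  set.seed(42)
  p <- fx_params()
  for (i in 1:1000) {
    cur <- compute_currents(random_valid_state(), p, random_drive())
    parts <- cur$i_cal + cur$i_cat + cur$i_hcn + cur$i_k + cur$i_kach +
      cur$i_nak + cur$i_ncx + cur$i_bna + cur$i_bca + cur$i_pca
    expect_equal(cur$i_net, parts, tolerance = 1e-9)
  }
})

test_that("compiled core agrees with the R reference at random states", {
  set.seed(7)
  p <- fx_params()
  for (i in 1:200) {
    s <- random_valid_state()
    d <- random_drive()
    ref <- sanc_rhs(0, s, p, d)
    cc <- sancpace:::sanc_rhs_compiled(0, s, p, d)
    expect_equal(cc$dstate, ref$dstate, tolerance = 1e-12)
    expect_equal(cc$out[["i_net"]], ref$currents$i_net, tolerance = 1e-12)
  }
})

test_that("a gate at its voltage steady state has zero derivative", {
  p <- fx_params()
  s <- default_state()
  b <- function(V, vh, k) 1 / (1 + exp((vh - V) / k))
  s["n"] <- b(s[["V"]], p$v_n, p$k_n)
  d <- sanc_rhs(0, s, p, drive_input())$dstate
  expect_equal(unname(d["n"]), 0, tolerance = 1e-12)
})

test_that("Ca-dependent inactivation steady state falls as cytosolic Ca rises", {
  p <- fx_params()
  fca_inf <- function(cai) p$km_fca / (p$km_fca + cai)
  cais <- c(1e-4, 5e-4, 2e-3, 1e-2)
  expect_true(all(diff(fca_inf(cais)) < 0))
  # and the gate relaxes towards that falling target
  s <- default_state(); s["f_Ca"] <- 0.9; s["Cai"] <- 2e-3
  d <- sanc_rhs(0, s, p, drive_input())$dstate
  expect_lt(d[["f_Ca"]], 0)
})

test_that("unmodulated model fires spontaneously in the murine range", {
  st <- fx_steady12()
  expect_true(attr(st, "firing"))
  expect_gt(attr(st, "fr_bpm"), 300)
  expect_lt(attr(st, "fr_bpm"), 600)

  # coefficient of variation of steady inter-spike intervals is tiny
  out <- sancpace:::integrate_segment(st, seq(0, 10, by = 1e-3), fx_params(),
                                      1, 1, 1, 1, 0, 0, 37, 1)
  isi <- detect_aps(out[, "V"], dt = 1e-3)$isi
  expect_lt(sd(isi) / mean(isi), 0.02)
})

test_that("net Na flux integrates to near zero over one steady cycle", {
  p <- fx_params()
  st <- fx_steady12()
  period <- attr(st, "period_s")
  out <- sancpace:::integrate_segment(st, seq(0, period, by = 1e-4), p,
                                      1, 1, 1, 1, 0, 0, 37, 1)
  d_nai <- unname(out[nrow(out), "Nai"] - out[1, "Nai"])
  expect_lt(abs(d_nai), 0.01)

  # independent quadrature of the Na-carrying flux terms reproduces the
  # solver's concentration change
  flux <- -1000 * (out[, "i_bna"] + p$f_na_hcn * out[, "i_hcn"] +
                     3 * out[, "i_nak"] + 3 * out[, "i_ncx"]) / (96485 * p$vi)
  d_quad <- sum((flux[-1] + flux[-length(flux)]) / 2) * 1e-4
  expect_equal(d_quad, d_nai, tolerance = 5e-4)
})

test_that("steady firing rate responds monotonically to autonomic drive", {
  # checked on a 5x5 drive grid in the stable pacing neighbourhood; the
  # response is monotone to within a 1% tolerance band (the slow Na
  # equilibrium introduces sub-percent ripples)
  p <- fx_params()
  svals <- seq(0.8, 1.2, length.out = 5)
  pvals <- seq(0.8, 1.2, length.out = 5)
  fr <- fixture("drive_grid_fr", {
    m <- matrix(NA_real_, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      st <- run_to_steady(p, drive_input(sna = svals[i], pna = pvals[j]),
                          max_s = 90)
      m[i, j] <- attr(st, "fr_bpm")
    }
    m
  })
  expect_true(all(is.finite(fr)) && all(fr > 200))
  tol <- 0.01 * mean(fr)
  expect_true(all(apply(fr, 2, function(x) all(diff(x) >= -tol))))  # sna up
  expect_true(all(apply(fr, 1, function(x) all(diff(x) <= tol))))   # pna up
})
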