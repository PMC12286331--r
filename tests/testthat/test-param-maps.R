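test_that("grids span the printed protocol ranges inclusively", {
  g <- build_grid("ictal", 40)
  expect_equal(g$axes$Si_pct[1], 20)
  expect_equal(g$axes$Si_pct[40], 220)
  expect_equal(length(g$axes$Si_pct), 40)
  expect_equal(range(g$axes$Pi_pct), c(-20, 40))
  expect_equal(g$n_simulations, 1600)

  g2 <- build_grid("ictal", 2)
  expect_equal(g2$axes$Si_pct, c(20, 220))  # corners only

  gp <- build_grid("postictal", 40)
  expect_equal(range(gp$axes$Pp_pct), c(60, 400))
  expect_equal(unname(gp$fixed["Pi_pct"]), 10)
  expect_equal(unname(gp$fixed["Sp_pct"]), -100)
})

test_that("the joint taxonomy is a bijection onto regions 1..9", {
  labs <- c("R", "I", "N")
  pairs <- expand.grid(ictal = labs, postictal = labs,
                       stringsAsFactors = FALSE)
  ids <- segment_regions(pairs$ictal, pairs$postictal)
  expect_setequal(ids, 1:9)
  expect_equal(length(unique(ids)), 9)

  # anchor cases from the region naming convention
  expect_equal(unname(segment_regions("R", "R")), 1L)
  expect_equal(unname(segment_regions("I", "I")), 5L)
  expect_equal(unname(segment_regions("N", "N")), 9L)
  # rows share the ictal label, columns the postictal label
  expect_equal(unname(segment_regions("N", "R")), 7L)
  expect_equal(unname(segment_regions("R", "N")), 3L)

  expect_error(segment_regions("X", "R"), "labels")
})

test_that("a null-scaling sweep is uniformly rhythmic and deterministic", {
  null_grid <- structure(list(
    axes = list(Si_pct = c(0, 1e-4), Pi_pct = c(0, 1e-4)),
    map_type = "ictal", fixed = c(Sp_pct = 0, Pp_pct = 0),
    n_simulations = 4L), class = "parameter_grid")
  m1 <- fixture("null_map", run_map(null_grid, fx_ctx12(), fx_params()))
  expect_true(all(m1$ictal_label == "R"))
  expect_lt(max(m1$fr) - min(m1$fr), 1e-4 * mean(m1$fr))

  m2 <- run_map(null_grid, fx_ctx12(), fx_params())
  expect_identical(m2$fr, m1$fr)  # bitwise reproducible
})

test_that("ictal severity is ordered along the sympathetic axis", {
  m <- fx_map("ictal", 18, "natural")
  rank <- c(R = 0, I = 1, N = 2)
  for (j in seq_len(ncol(m$ictal_label))) {
    r <- rank[m$ictal_label[, j]]
    expect_true(all(diff(r) >= 0),
                info = paste("column", colnames(m$ictal_label)[j]))
  }
})

test_that("region areas are proper fractions", {
  m <- fx_map("ictal", 18, "natural")
  a <- region_areas(m)
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_true(all(a >= 0))
  expect_equal(m$n_missing, 0)
})

test_that("map directories round-trip exactly", {
  m <- .fixtures$null_map
  d <- withr::local_tempdir()
  write_map(m, d)
  m2 <- read_map(d)
  expect_identical(m2$fr, m$fr)
  expect_identical(m2$ictal_label, m$ictal_label)
  expect_identical(m2$regions, m$regions)
  expect_equal(m2$grid$map_type, m$grid$map_type)

  # malformed directories are named errors
  expect_error(read_map(tempfile()), "meta.json")
  unlink(file.path(d, "fr.csv"))
  expect_error(read_map(d), "missing fr.csv")
})

test_that("missing-cell sentinels survive the round trip", {
  m <- .fixtures$null_map
  m$fr[1, 1] <- NA
  m$ictal_label[1, 1] <- NA
  m$regions[1, 1] <- NA
  d <- withr::local_tempdir()
  write_map(m, d)
  m2 <- read_map(d)
  expect_true(is.na(m2$fr[1, 1]))
  expect_true(is.na(m2$ictal_label[1, 1]))
  expect_true(is.na(m2$regions[1, 1]))
})
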