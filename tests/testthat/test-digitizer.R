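test_that("energy blurring has the specified resolution", {
  set.seed(14)
  e <- blur_energy(rep(511, 1e5), 0.13)
  expect_equal(sd(e) * 2 * sqrt(2 * log(2)), 66.43, tolerance = 1 / 66.43)
  expect_identical(blur_energy(c(200, 511), 0), c(200, 511))
  # 1/sqrt(E) scaling: fractional FWHM worsens at lower energy
  e2 <- blur_energy(rep(255.5, 1e5), 0.13)
  expect_equal(sd(e2) / 255.5, (sd(e) / 511) * sqrt(2), tolerance = 0.03)
})

test_that("energy-weighted centroid follows the weighted-mean example", {
  hits <- data.frame(event = 1, photon = 0, hit_order = 1:2,
                     x = c(0, 10), y = 2, z = 35,
                     energy_deposited = c(100, 411),
                     interaction = c("CS", "PE"), time = c(0, 0.05))
  s <- make_singles(hits)
  expect_equal(s$ewx, 4110 / 511, tolerance = 1e-12)
  expect_identical(s$n_hits, 2L)
  expect_identical(s$n_compton, 1L)
  expect_identical(s$terminal_pe, 1L)
  expect_equal(s$fhx, 0)
  # a one-hit single has EWP = FHP exactly
  h1 <- hits[2, ]; h1$hit_order <- 1
  s1 <- make_singles(h1)
  expect_identical(s1$ewx, s1$fhx)
})

test_that("non-paralyzable dead time discards close-following singles", {
  s <- data.frame(time = c(0, 2000, 9000), sipm = c(3, 3, 3),
                  block = c(1, 1, 1), element = c(7, 7, 7))
  expect_identical(nrow(apply_dead_time(s, tau_us = 6, by = "sipm")), 2L)
  # different units: both survive
  s2 <- s; s2$sipm <- c(3, 4, 3)
  expect_identical(nrow(apply_dead_time(s2, tau_us = 6, by = "sipm")), 3L)
  expect_identical(nrow(apply_dead_time(s, tau_us = 0)), 3L)
  s3 <- s; s3$time <- c(2000, 0, 9000)
  expect_error(apply_dead_time(s3, 6), "sorted")
})

test_that("coincidence sorting applies windows, energy cuts and multiples", {
  base <- data.frame(event = c(1, 1), photon = c(0, 1), panel = c(-1, 1),
                     n_hits = 1, n_compton = 0, terminal_pe = 1,
                     energy_blurred = 511, time = c(0, 3))
  cc <- sort_coincidences(base)
  expect_identical(nrow(cc), 1L)
  expect_identical(cc$class, "SI-SI")
  expect_false(cc$is_random)
  expect_identical(cc$panel_a, -1)   # -z panel listed first
  # out-of-window energy rejected
  low <- base; low$energy_blurred[2] <- 340
  expect_identical(nrow(sort_coincidences(low)), 0L)
  # three singles in one window are discarded entirely
  tri <- base[c(1, 1, 2), ]
  tri$time <- c(0, 2, 4)
  tri$event <- c(1, 2, 1)
  cc3 <- sort_coincidences(tri)
  expect_identical(nrow(cc3), 0L)
  expect_identical(attr(cc3, "n_multiple"), 1L)
  # same-panel pairs do not form coincidences
  sp <- base; sp$panel <- c(1, 1)
  expect_identical(nrow(sort_coincidences(sp)), 0L)
  # singles from different events are flagged random
  rnd <- base; rnd$event <- c(1, 2)
  expect_true(sort_coincidences(rnd)$is_random)
})

test_that("disabling the energy window only adds coincidences", {
  run <- hits_run()
  s <- run$singles
  s <- s[order(s$time), ]
  s$energy_blurred <- blur_energy(s$energy_true, 0.13)
  full <- sort_coincidences(s, energy_window = c(0, Inf))
  windowed <- sort_coincidences(s, energy_window = c(350, 750))
  expect_gt(nrow(full), nrow(windowed))
})

test_that("single-interaction photons have identical EWP and FHP", {
  run <- cuboid_run("monolithic")
  s <- run$singles
  si <- s$n_hits == 1
  expect_true(any(si))
  expect_identical(s$ewx[si], s$fhx[si])
  expect_identical(s$ewy[si], s$fhy[si])
})

test_that("run tables round-trip through CSV with metadata", {
  df <- data.frame(event = 1:4, energy_true = c(511, 340.25, 511, 170.5),
                   panel = c(-1, 1, -1, 1))
  path <- tempfile(fileext = ".csv")
  write_run_table(df, path, meta = list(seed = 42, mode = "monolithic",
                                        n_emissions = 1e5))
  back <- read_run_table(path)
  meta <- attr(back, "meta")
  expect_equal(back$energy_true, df$energy_true)
  expect_equal(meta$seed, 42)
  expect_identical(meta$mode, "monolithic")
  expect_equal(meta$n_emissions, 1e5)
})
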