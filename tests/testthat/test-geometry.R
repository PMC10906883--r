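test_that("crystal counts and volumes match the scanner description", {
  gp <- scanner_geometry("pixelated")
  gm <- scanner_geometry("monolithic")
  expect_identical(gp$n_crystals, 28800L)
  expect_identical(gm$n_crystals, 18L)
  # closed-form sensitive volumes
  expect_equal(crystal_volume(gp), 28800 * 1.35^2 * 10)
  expect_equal(crystal_volume(gm), 18 * 57.4^2 * 10)
  # monolithic panels hold ~13% more LYSO than pixelated ones
  ratio <- crystal_volume(gm, "panel") / crystal_volume(gp, "panel")
  expect_gte(ratio, 1.12)
  expect_lte(ratio, 1.13)
  # panel span within the mechanical footprint
  expect_gte(2 * gm$half_span, 172.2)
  expect_lte(2 * gm$half_span, 176)
  expect_error(scanner_geometry("curved"), "unknown")
  expect_error(scanner_geometry("monolithic", panel_gap = -1), "positive")
})

test_that("locate_element resolves crystals, gaps and outside points", {
  gm <- scanner_geometry("monolithic")
  gp <- scanner_geometry("pixelated")
  # FOV centre is not inside any crystal
  expect_true(is.na(locate_element(gm, c(0, 0, 0))$element))
  # centre of the +z panel, central block
  c35 <- locate_element(gm, c(0, 0, 35))
  expect_identical(c35$panel, 1L)
  expect_identical(c35$block_i, 1L)
  expect_identical(c35$block_j, 1L)
  # a point just inside a pixelated reflector gap
  xgap <- -gp$half_span + 40 * gp$cell_pitch + 0.02   # 0.02 mm into a gap
  expect_true(is.na(locate_element(gp, c(xgap, 0, 35))$element))
  # half-open boundaries, lower edge inclusive: the inner crystal face
  # z = 30 belongs to the crystal, the outer face z = 40 does not
  expect_false(is.na(locate_element(gm, c(0, 0, 30))$element))
  expect_true(is.na(locate_element(gm, c(0, 0, 40))$element))
  xlo <- -gp$half_span + gp$c_lo
  expect_false(is.na(locate_element(gp, c(xlo, 0.72, 35))$element))
  # crystals lie strictly inside their blocks: the first 0.045 mm are gap
  expect_true(is.na(locate_element(gp, c(-gp$half_span + 0.01, 0, 35))$element))
  expect_true(is.na(locate_element(gm, c(-gm$half_span + 0.05, 0, 35))$element))
})

test_that("ray tracing through the panels matches locate_element", {
  gm <- scanner_geometry("monolithic")
  # normal ray from the FOV centre: one 10 mm crystal segment in the +z panel
  seg <- ray_crystal_intersections(gm, c(0, 0, 0), c(0, 0, 1))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$exit - seg$entry, 10)
  # in-plane ray at z = 0 misses both panels
  seg0 <- ray_crystal_intersections(gm, c(0, 0, 0), c(1, 0, 0))
  expect_equal(nrow(seg0), 0)
  # segments are ordered and non-overlapping for an oblique pixelated ray
  gp <- scanner_geometry("pixelated")
  sg <- ray_crystal_intersections(gp, c(-20, 5, 0), c(0.4, 0.1, sqrt(1 - 0.17)))
  expect_true(all(diff(sg$entry) > 0))
  expect_true(all(sg$exit[-nrow(sg)] <= sg$entry[-1] + 1e-9))
})

test_that("random rays: every reported segment midpoint locates to its element", {
  set.seed(71)
  for (mode in c("monolithic", "pixelated")) {
    g <- scanner_geometry(mode)
    n <- if (mode == "monolithic") 7000 else 3000
    bad <- 0
    for (i in seq_len(n)) {
      o <- c(runif(2, -40, 40), runif(1, -5, 5))
      cz <- runif(1, -1, 1)
      ph <- runif(1, 0, 2 * pi)
      d <- c(sqrt(1 - cz^2) * cos(ph), sqrt(1 - cz^2) * sin(ph), cz)
      seg <- ray_crystal_intersections(g, o, d)
      if (nrow(seg) == 0) next
      mid <- (seg$entry + seg$exit) / 2
      pts <- cbind(o[1] + mid * d[1], o[2] + mid * d[2], o[3] + mid * d[3])
      loc <- locate_element(g, pts)
      bad <- bad + sum(is.na(loc$element) | loc$element != seg$element)
    }
    expect_identical(bad, 0)
  }
})

test_that("geometry round-trips through a JSON config", {
  skip_if_not_installed("jsonlite")
  g <- scanner_geometry("pixelated", panel_gap = 80)
  path <- tempfile(fileext = ".json")
  write_geometry_config(g, path)
  g2 <- read_geometry_config(path)
  expect_identical(g2$mode, "pixelated")
  expect_equal(g2$panel_gap, 80)
  expect_equal(g2$n_crystals, g$n_crystals)
})
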