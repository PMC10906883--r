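test_that("Siddon rows are exact on axis-aligned and oblique rays", {
  grid <- recon_grid()
  # axial LOR through the grid centre: 24 voxels of 2.5 mm
  row <- siddon_row(c(0.2, 0.2, -30), c(0.2, 0.2, 30), grid)
  expect_identical(nrow(row), 24L)
  expect_equal(row$length, rep(2.5, 24))
  expect_equal(sum(row$length), 60)
  # 45-degree ray in the x-z plane: total length = sqrt(2) x z-extent
  row45 <- siddon_row(c(-30, 0, -30), c(30, 0, 30), grid)
  expect_equal(sum(row45$length), sqrt(2) * 60, tolerance = 1e-9)
  # a ray missing the grid yields an empty row
  expect_identical(nrow(siddon_row(c(200, 200, -30), c(200, 200, 30), grid)),
                   0L)
  # translation invariance: shifting endpoints by one voxel shifts indices
  r1 <- siddon_row(c(3.1, -2.2, -30), c(-7.5, 4.4, 30), grid)
  r2 <- siddon_row(c(4.1, -2.2, -30), c(-6.5, 4.4, 30), grid)
  expect_equal(r2$i, r1$i + 1L)
  expect_equal(r2$length, r1$length, tolerance = 1e-9)
})

test_that("Siddon lengths sum to the chord for random rays", {
  grid <- recon_grid()
  lo <- grid$origin
  hi <- grid$origin + grid$n * grid$voxel
  set.seed(33)
  for (i in 1:200) {
    p0 <- c(runif(2, -100, 100), -30)
    p1 <- c(runif(2, -100, 100), 30)
    row <- siddon_row(p0, p1, grid)
    expect_equal(sum(row$length), chord_in_box(p0, p1, lo, hi),
                 tolerance = 1e-9)
    expect_true(all(row$length > 0))
  }
})

test_that("virtual LOR endpoints snap to crystal-cell centres", {
  g <- scanner_geometry("monolithic")
  cc <- data.frame(fhx_a = -g$half_span + 0.1, fhy_a = 0,
                   fhx_b = 10, fhy_b = -3,
                   ewx_a = -g$half_span + 0.1, ewy_a = 0,
                   ewx_b = 10, ewy_b = -3)
  vl <- virtual_lors(cc, g, "fhp", pitch = 1.44)
  # 0.1 mm from the panel edge falls into cell 0, centre at 0.72 mm
  expect_equal(vl$A[1, 1], -g$half_span + 0.72)
  expect_equal(vl$A[1, 3], -30)
  expect_equal(vl$B[1, 3], 30)
  # snapping is idempotent for cell-centre positions
  cc2 <- data.frame(fhx_a = vl$A[1, 1], fhy_a = vl$A[1, 2],
                    fhx_b = vl$B[1, 1], fhy_b = vl$B[1, 2],
                    ewx_a = vl$A[1, 1], ewy_a = vl$A[1, 2],
                    ewx_b = vl$B[1, 1], ewy_b = vl$B[1, 2])
  vl2 <- virtual_lors(cc2, g, "fhp", pitch = 1.44)
  expect_equal(vl2$A, vl$A)
  expect_equal(vl2$B, vl$B)
  # identical FHP and EWP positions give identical LORs either way
  vle <- virtual_lors(cc2, g, "ewp", pitch = 1.44)
  expect_equal(vle$A, vl2$A)
  # endpoints outside the span are clamped with a warning
  cc3 <- cc2
  cc3$fhx_a <- -95
  expect_warning(virtual_lors(cc3, g, "fhp"), "clamped")
})

test_that("sensitivity image is scale-invariant and spatially sensible", {
  g <- scanner_geometry("monolithic")
  grid <- recon_grid()
  set.seed(61)
  run <- simulate_study(phantom_planar(), g, n_events = 1.2e6, seed = 61)
  vl <- virtual_lors(run$coincidences, g, "fhp")
  sens <- build_sensitivity(vl, grid)
  # doubling the LOR set leaves the normalized image unchanged
  vl2 <- list(A = rbind(vl$A, vl$A), B = rbind(vl$B, vl$B))
  sens2 <- build_sensitivity(vl2, grid)
  expect_equal(sens2$data, sens$data, tolerance = 1e-12)
  # positive over the central region, weaker towards panel corners
  centre <- sens$data[58:118, 58:118, ]
  expect_true(all(centre > 0))
  corner <- mean(sens$data[1:10, 1:10, ])
  expect_lt(corner, mean(centre))
  expect_error(build_sensitivity(list(A = vl$A[0, ], B = vl$B[0, ]), grid),
               "empty")
})

test_that("list-mode MLEM has the expected fixed point and monotone likelihood", {
  grid <- recon_grid(n = c(40, 40, 8), voxel = c(2, 2, 2.5))
  # parallel axial LORs of equal chord length: the uniform image is a fixed
  # point when the sensitivity equals the backprojection scaled by 1/chord
  set.seed(10)
  xy <- cbind(runif(500, -30, 30), runif(500, -30, 30))
  A <- cbind(xy, -10); B <- cbind(xy, 10)
  sraw <- pemscat:::cpp_backproject(A, B, grid) / 20
  sens <- pem_image(array(sraw, grid$n), grid)
  f1 <- lm_osem(list(A = A, B = B, position = "fhp"), sens, grid,
                iterations = 3, subsets = 1)
  expect_equal(f1$data[sraw > 0], rep(1, sum(sraw > 0)), tolerance = 1e-9)
  expect_true(all(f1$data >= 0))
  # oblique random LORs: log-likelihood non-decreasing over MLEM iterations
  set.seed(11)
  A2 <- cbind(matrix(runif(300, -25, 25), 150, 2), -10)
  B2 <- cbind(matrix(runif(300, -25, 25), 150, 2), 10)
  sens2raw <- pemscat:::cpp_backproject(A2, B2, grid)
  sens2raw <- sens2raw / mean(sens2raw[sens2raw > 0])
  sens2 <- pem_image(array(sens2raw, grid$n), grid)
  ll <- vapply(1:4, function(k) {
    img <- lm_osem(list(A = A2, B = B2), sens2, grid, iterations = k,
                   subsets = 1)
    pemscat:::lm_loglik(list(A = A2, B = B2), sens2, grid, img)
  }, numeric(1))
  expect_true(all(diff(ll) > -1e-8))
  # a single LOR with flat sensitivity concentrates on its voxel row
  flat <- pem_image(array(1, grid$n), grid)
  one <- lm_osem(list(A = A[1, , drop = FALSE], B = B[1, , drop = FALSE]),
                 flat, grid, iterations = 1, subsets = 1)
  lit <- which(one$data > 1e-9, arr.ind = TRUE)
  row <- siddon_row(A[1, ], B[1, ], grid)
  expect_setequal(paste(lit[, 1], lit[, 2], lit[, 3]),
                  paste(row$i, row$j, row$k))
})

test_that("a point-like source reconstructs at its voxel", {
  g <- scanner_geometry("monolithic")
  grid <- recon_grid()
  xs <- lyso_xs()
  set.seed(77)
  n <- 6000
  src <- c(10.2, -5.4, 1.3)
  cz <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  em <- data.frame(event = 1:n, x = src[1], y = src[2], z = src[3],
                   dx = sqrt(1 - cz^2) * cos(phi),
                   dy = sqrt(1 - cz^2) * sin(phi), dz = cz,
                   time = (1:n) * 300)
  s <- track_emissions(em, g, xs, seed = 5)
  dig <- digitize(s)
  vl <- virtual_lors(dig$coincidences, g, "fhp")
  flat <- pem_image(array(1, grid$n), grid)
  img <- lm_osem(vl, flat, grid, iterations = 2, subsets = 4)
  peak <- which(img$data == max(img$data), arr.ind = TRUE)[1, ]
  vox <- floor((src - grid$origin) / grid$voxel) + 1
  expect_true(all(abs(peak - vox) <= 1))
})

test_that("Gaussian post-filter conserves intensity at the stated width", {
  grid <- recon_grid()
  arr <- array(0, grid$n)
  arr[87, 87, 12] <- 100
  img <- pem_image(arr, grid)
  expect_identical(gaussian_post_filter(img, 0)$data, arr)
  blur <- gaussian_post_filter(img, 1.5)
  expect_equal(sum(blur$data), 100, tolerance = 1e-6)
  expect_true(all(blur$data >= 0))
  # in-plane profile width equals the kernel FWHM (1 mm voxels)
  prof <- blur$data[, 87, 12]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  xs87 <- seq_len(grid$n[1])
  lo <- stats::approx(prof[(above[1] - 1):above[1]],
                      xs87[(above[1] - 1):above[1]], half)$y
  hi <- stats::approx(prof[above[2]:(above[2] + 1)],
                      xs87[above[2]:(above[2] + 1)], half)$y
  expect_equal(hi - lo, 1.5, tolerance = 0.1)
  # a filtered study image keeps its total
  arr2 <- array(runif(prod(grid$n)), grid$n)
  arr2[c(1:20, 155:174), , ] <- 0
  img2 <- pem_image(arr2, grid)
  expect_equal(sum(gaussian_post_filter(img2, 1.5)$data) / sum(arr2),
               1, tolerance = 0.01)
})
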