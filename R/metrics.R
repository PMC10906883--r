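#' In-plane display slab of a reconstructed image
#'
#' Mean of a set of axial slices (by default slices 11 to 14, the central
#' 10 mm of the axial field of view).
#'
#' @param image a `pem_image`.
#' @param slices 1-based slice indices to average.
#' @return matrix (x by y) with the grid attached as an attribute.
#' @export
image_slab <- function(image, slices = 11:14) {
  stopifnot(all(slices >= 1), all(slices <= image$grid$n[3]))
  slab <- apply(image$data[, , slices, drop = FALSE], c(1, 2), mean)
  attr(slab, "grid") <- image$grid
  slab
}

# bilinear interpolation of a slab at world coordinates (x, y)
slab_interp <- function(slab, x, y) {
  grid <- attr(slab, "grid")
  gx <- grid$origin[1] + (seq_len(nrow(slab)) - 0.5) * grid$voxel[1]
  gy <- grid$origin[2] + (seq_len(ncol(slab)) - 0.5) * grid$voxel[2]
  fx <- (x - gx[1]) / grid$voxel[1] + 1
  fy <- (y - gy[1]) / grid$voxel[2] + 1
  i0 <- pmin(pmax(floor(fx), 1), nrow(slab) - 1)
  j0 <- pmin(pmax(floor(fy), 1), ncol(slab) - 1)
  wx <- pmin(pmax(fx - i0, 0), 1)
  wy <- pmin(pmax(fy - j0, 0), 1)
  v00 <- slab[cbind(i0, j0)]; v10 <- slab[cbind(i0 + 1, j0)]
  v01 <- slab[cbind(i0, j0 + 1)]; v11 <- slab[cbind(i0 + 1, j0 + 1)]
  (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
    (1 - wx) * wy * v01 + wx * wy * v11
}

#' Intensity profile along a straight line in the display slab
#'
#' @param slab matrix from [image_slab()].
#' @param p0,p1 line endpoints in world coordinates, mm.
#' @param step sampling step along the line, mm.
#' @return data.frame with `pos` (mm from `p0`) and `intensity`.
#' @export
profile_line <- function(slab, p0, p1, step = 0.2) {
  L <- sqrt(sum((p1 - p0)^2))
  pos <- seq(0, L, by = step)
  x <- p0[1] + pos / L * (p1[1] - p0[1])
  y <- p0[2] + pos / L * (p1[2] - p0[2])
  data.frame(pos = pos, intensity = slab_interp(slab, x, y))
}

#' Peak-to-valley ratios along an intensity profile
#'
#' For each rod centre the peak is the maximum intensity within `d/4` of the
#' centre along the profile; the valley between two adjacent rods is the
#' minimum intensity between their peak positions.  Each adjacent pair
#' contributes `PVR = mean(two peaks) / valley`; a zero valley yields
#' `Inf` and is flagged.
#'
#' @param profile data.frame from [profile_line()].
#' @param centers rod-centre positions along the profile, mm.
#' @param d rod diameter, mm.
#' @return list with `mean`, `min`, `max`, per-pair data.frame `pairs` and
#'   `n_infinite`.
#' @export
pvr_from_profile <- function(profile, centers, d) {
  centers <- sort(centers)
  if (length(centers) < 2) stop("need at least two rod centres on the profile")
  peak_pos <- peak_val <- numeric(length(centers))
  for (i in seq_along(centers)) {
    sel <- abs(profile$pos - centers[i]) <= d / 4
    if (!any(sel)) stop("no profile samples near a rod centre")
    k <- which(sel)[which.max(profile$intensity[sel])]
    peak_pos[i] <- profile$pos[k]
    peak_val[i] <- profile$intensity[k]
  }
  pairs <- data.frame(left = head(centers, -1), right = tail(centers, -1),
                      pvr = NA_real_, valley = NA_real_)
  for (i in seq_len(nrow(pairs))) {
    sel <- profile$pos > peak_pos[i] & profile$pos < peak_pos[i + 1]
    valley <- min(profile$intensity[sel])
    pairs$valley[i] <- valley
    pairs$pvr[i] <- if (valley > 0)
      mean(c(peak_val[i], peak_val[i + 1])) / valley else Inf
  }
  list(mean = mean(pairs$pvr), min = min(pairs$pvr), max = max(pairs$pvr),
       pairs = pairs, n_infinite = sum(is.infinite(pairs$pvr)))
}

#' Fit an axis-aligned 2D Gaussian to one hot rod
#'
#' Least-squares fit of
#' `A * exp(-(x - x0)^2 / (2 sx^2) - (y - y0)^2 / (2 sy^2)) + B`
#' to the slab intensities inside a square window centred on the rod.
#'
#' @param slab matrix from [image_slab()].
#' @param center rod centre `(x, y)` seed, mm.
#' @param d rod diameter, mm.
#' @param window window side as a multiple of `d`.
#' @return object of class `rod_fit` with `center`, `fwhm_x`, `fwhm_y` (mm),
#'   `amplitude`, `offset`, `r_squared` and `converged`; on fit divergence
#'   `converged` is `FALSE` and the widths are `NA`.
#' @export
fit_rod <- function(slab, center, d, window = 1.5) {
  grid <- attr(slab, "grid")
  gx <- grid$origin[1] + (seq_len(nrow(slab)) - 0.5) * grid$voxel[1]
  gy <- grid$origin[2] + (seq_len(ncol(slab)) - 0.5) * grid$voxel[2]
  half <- window * d / 2
  ii <- which(abs(gx - center[1]) <= half)
  jj <- which(abs(gy - center[2]) <= half)
  dat <- expand.grid(x = gx[ii], y = gy[jj])
  dat$zz <- as.vector(slab[ii, jj])
  if (!any(dat$zz > 0) || max(dat$zz) <= min(dat$zz)) {
    return(structure(list(center = center, fwhm_x = NA_real_,
                          fwhm_y = NA_real_, amplitude = NA_real_,
                          offset = NA_real_, r_squared = NA_real_,
                          converged = FALSE), class = "rod_fit"))
  }
  s0 <- d / 2.3548
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(
      zz ~ A * exp(-(x - x0)^2 / (2 * sx^2) - (y - y0)^2 / (2 * sy^2)) + B,
      data = dat,
      start = list(A = max(dat$zz) - min(dat$zz), B = min(dat$zz),
                   x0 = center[1], y0 = center[2], sx = s0, sy = s0),
      lower = c(0, 0, center[1] - d, center[2] - d, 0.05, 0.05),
      upper = c(Inf, Inf, center[1] + d, center[2] + d, 3 * d, 3 * d),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(center = center, fwhm_x = NA_real_,
                          fwhm_y = NA_real_, amplitude = NA_real_,
                          offset = NA_real_, r_squared = NA_real_,
                          converged = FALSE), class = "rod_fit"))
  }
  cf <- coef(fit)
  ss_res <- sum((dat$zz - predict(fit))^2)
  ss_tot <- sum((dat$zz - mean(dat$zz))^2)
  structure(list(center = unname(c(cf["x0"], cf["y0"])),
                 fwhm_x = unname(2.3548 * cf["sx"]),
                 fwhm_y = unname(2.3548 * cf["sy"]),
                 amplitude = unname(cf["A"]), offset = unname(cf["B"]),
                 r_squared = 1 - ss_res / ss_tot,
                 converged = TRUE), class = "rod_fit")
}

#' Resolvability index
#'
#' `RI = FWHM / d`, where `d` is the centre-to-centre distance of adjacent
#' rods (twice the rod diameter in this phantom).  Rods are distinguishable
#' when `RI < 1`.
#'
#' @param fwhm fitted full width at half maximum, mm.
#' @param d rod centre-to-centre distance, mm.
#' @return numeric RI.
#' @export
resolvability_index <- function(fwhm, d) {
  stopifnot(all(d > 0))
  fwhm / d
}

#' Image-quality report for one rod-diameter sector
#'
#' Computes, for all rods of one diameter in the phantom layout: peak-to-
#' valley ratios along the lattice-row profiles (rows with at least two
#' rods), an axis-aligned 2D Gaussian fit per rod, and resolvability
#' indices `RI = FWHM / (2 d)` in x and y.  Rods whose fits diverge are
#' excluded from the summaries.
#'
#' @param image a `pem_image`.
#' @param layout Derenzo layout data.frame from [build_derenzo_layout()].
#' @param diameter rod diameter (mm) selecting the sector.
#' @param slices slices averaged for the display slab.
#' @param extend profile extension beyond the outermost rod centres, mm.
#' @return object of class `sector_report`: `pvr` (`mean`, `min`, `max`),
#'   `fits` (per-rod), `fwhm_x`, `fwhm_y`, `ri_x`, `ri_y` (mean and sd),
#'   `n_rods`, `n_unfit`.
#' @export
sector_report <- function(image, layout, diameter, slices = 11:14,
                          extend = 0) {
  rods <- layout[layout$diameter == diameter, , drop = FALSE]
  if (nrow(rods) == 0) stop("no rods with diameter ", diameter)
  slab <- image_slab(image, slices)
  # PVR along lattice rows (perpendicular to the sector bisector)
  pvr_pairs <- list()
  for (r in unique(rods$row)) {
    rr <- rods[rods$row == r, , drop = FALSE]
    if (nrow(rr) < 2) next
    # order along the row and take the row direction from the end points
    o <- order(rr$x, rr$y)
    rr <- rr[o, ]
    p0 <- c(rr$x[1], rr$y[1])
    p1 <- c(rr$x[nrow(rr)], rr$y[nrow(rr)])
    u <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    prof <- profile_line(slab, p0 - extend * u, p1 + extend * u, step = 0.1)
    centers <- extend + sqrt((rr$x - rr$x[1])^2 + (rr$y - rr$y[1])^2)
    pv <- pvr_from_profile(prof, centers, diameter)
    pvr_pairs[[length(pvr_pairs) + 1]] <- pv$pairs
  }
  if (length(pvr_pairs) == 0) stop("no lattice row holds two rods")
  pairs <- do.call(rbind, pvr_pairs)
  fits <- lapply(seq_len(nrow(rods)), function(i)
    fit_rod(slab, c(rods$x[i], rods$y[i]), diameter))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  fx <- vapply(fits[ok], `[[`, numeric(1), "fwhm_x")
  fy <- vapply(fits[ok], `[[`, numeric(1), "fwhm_y")
  spacing <- 2 * diameter
  structure(list(
    diameter = diameter,
    pvr = list(mean = mean(pairs$pvr), min = min(pairs$pvr),
               max = max(pairs$pvr), n_infinite = sum(is.infinite(pairs$pvr)),
               pairs = pairs),
    fits = fits,
    fwhm_x = c(mean = mean(fx), sd = sd(fx)),
    fwhm_y = c(mean = mean(fy), sd = sd(fy)),
    ri_x = c(mean = mean(fx / spacing), sd = sd(fx / spacing)),
    ri_y = c(mean = mean(fy / spacing), sd = sd(fy / spacing)),
    r_squared = vapply(fits[ok], `[[`, numeric(1), "r_squared"),
    n_rods = nrow(rods), n_unfit = sum(!ok)), class = "sector_report")
}

#' @export
print.sector_report <- function(x, ...) {
  cat(sprintf("Sector report, %g mm rods (%d rods, %d unfit)\n", x$diameter,
              x$n_rods, x$n_unfit))
  cat(sprintf("  PVR  mean %.2f (min %.2f, max %.2f)\n", x$pvr$mean,
              x$pvr$min, x$pvr$max))
  cat(sprintf("  FWHM x %.2f+/-%.2f  y %.2f+/-%.2f mm\n", x$fwhm_x[1],
              x$fwhm_x[2], x$fwhm_y[1], x$fwhm_y[2]))
  cat(sprintf("  RI   x %.3f+/-%.3f  y %.3f+/-%.3f\n", x$ri_x[1], x$ri_x[2],
              x$ri_y[1], x$ri_y[2]))
  invisible(x)
}
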