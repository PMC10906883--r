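#' Reconstruction voxel grid
#'
#' Default grid: 174 x 174 x 24 voxels of 1 x 1 x 2.5 mm^3 centred on the
#' field of view, spanning the 60 mm panel gap axially.
#'
#' @param n voxel counts (x, y, z).
#' @param voxel voxel sizes, mm.
#' @param center world coordinate of the grid centre, mm.
#' @return list with `n`, `voxel`, `origin` (corner of voxel `[1,1,1]`).
#' @export
recon_grid <- function(n = c(174L, 174L, 24L), voxel = c(1, 1, 2.5),
                       center = c(0, 0, 0)) {
  list(n = as.integer(n), voxel = as.numeric(voxel),
       origin = center - n * voxel / 2)
}

# world coordinates of voxel centres along one axis
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$n[axis]) - 0.5) * grid$voxel[axis]
}

#' Convert coincidences to virtual-crystal LOR endpoints
#'
#' The reconstruction operates on discrete crystal identifiers, so the
#' continuous in-plane interaction positions (first-hit or energy-weighted)
#' are snapped to the centres of a virtual crystal grid of the given pitch
#' within each block, and the axial coordinate is set to the inner crystal
#' face of the panel.  With the default 1.44 mm pitch the virtual grid of the
#' monolithic crystals coincides with the pixel grid of the pixelated ones,
#' making the two configurations directly comparable.
#'
#' @param coinc coincidence data.frame from [sort_coincidences()].
#' @param geom a [scanner_geometry()].
#' @param position `"fhp"` (first hit) or `"ewp"` (energy-weighted).
#' @param pitch virtual crystal pitch, mm.
#' @return list with `A`, `B` (n x 3 endpoint matrices; `A` on the -z panel),
#'   `subset` hint and `n_clamped` (positions outside the panel span clamped
#'   to the nearest cell).
#' @export
virtual_lors <- function(coinc, geom, position = c("fhp", "ewp"),
                         pitch = 1.44) {
  position <- match.arg(position)
  px <- if (position == "fhp") "fh" else "ew"
  snap <- function(u) {
    v <- u + geom$half_span
    ncell <- floor(2 * geom$half_span / pitch)
    cell <- floor(v / pitch)
    clamped <- cell < 0 | cell > ncell - 1
    cell <- pmin(pmax(cell, 0), ncell - 1)
    list(u = (cell + 0.5) * pitch - geom$half_span, clamped = clamped)
  }
  ax <- snap(coinc[[paste0(px, "x_a")]])
  ay <- snap(coinc[[paste0(px, "y_a")]])
  bx <- snap(coinc[[paste0(px, "x_b")]])
  by <- snap(coinc[[paste0(px, "y_b")]])
  n_clamped <- sum(ax$clamped | ay$clamped | bx$clamped | by$clamped)
  if (n_clamped > 0)
    warning(n_clamped, " LOR endpoint(s) outside the panel span were clamped")
  A <- cbind(ax$u, ay$u, rep(-geom$zin, nrow(coinc)))
  B <- cbind(bx$u, by$u, rep(geom$zin, nrow(coinc)))
  list(A = A, B = B, n_clamped = n_clamped, pitch = pitch,
       position = position)
}

#' Siddon ray-voxel intersection row
#'
#' Exact intersection lengths of the segment `p0 -> p1` with the voxels of
#' `grid`; the lengths sum to the chord length of the segment inside the
#' grid.
#'
#' @param p0,p1 endpoints, mm.
#' @param grid a [recon_grid()].
#' @return data.frame with voxel indices `i`, `j`, `k` (1-based), linear
#'   `index` and `length` (mm).
#' @export
siddon_row <- function(p0, p1, grid) {
  res <- cpp_siddon(as.numeric(p0), as.numeric(p1), grid)
  idx <- res$index
  i <- idx %% grid$n[1]
  j <- (idx %/% grid$n[1]) %% grid$n[2]
  k <- idx %/% (grid$n[1] * grid$n[2])
  data.frame(i = i + 1L, j = j + 1L, k = k + 1L, index = idx + 1L,
             length = res$length)
}

#' Sensitivity image from a planar normalization acquisition
#'
#' Backprojects the LORs of a simulated planar back-to-back source (placed at
#' the field-of-view mid-plane, parallel to the panels) with Siddon
#' intersection-length weights, then normalizes the image to unit mean over
#' traversed voxels.
#'
#' @param norm_lors LOR endpoints from [virtual_lors()] applied to the
#'   normalization coincidences.
#' @param grid a [recon_grid()].
#' @return object of class `pem_image` holding the sensitivity array.
#' @export
build_sensitivity <- function(norm_lors, grid) {
  if (nrow(norm_lors$A) == 0) stop("empty normalization LOR set")
  s <- cpp_backproject(norm_lors$A, norm_lors$B, grid)
  pos <- s > 0
  if (!any(pos)) stop("normalization LORs do not traverse the grid")
  s <- s / mean(s[pos])
  pem_image(array(s, dim = grid$n), grid,
            meta = list(kind = "sensitivity", n_lors = nrow(norm_lors$A)))
}

#' List-mode OSEM reconstruction
#'
#' Standard list-mode ordered-subset MLEM with a Siddon line projector:
#' for each subset `f_j <- (f_j / S_j) * sum_i a_ij / sum_k a_ik f_k`,
#' events assigned to subsets round-robin by list order.  Voxels with zero
#' sensitivity stay zero; events with a non-positive forward projection are
#' skipped and counted in the image metadata.
#'
#' @param lors LOR endpoints from [virtual_lors()].
#' @param sensitivity `pem_image` from [build_sensitivity()].
#' @param grid a [recon_grid()].
#' @param iterations,subsets OSEM iteration and subset counts.
#' @return object of class `pem_image`.
#' @export
lm_osem <- function(lors, sensitivity, grid, iterations = 2, subsets = 28) {
  stopifnot(iterations >= 1, subsets >= 1)
  f <- cpp_lm_osem(lors$A, lors$B, as.numeric(sensitivity$data), grid,
                   as.integer(iterations), as.integer(subsets))
  skipped <- attr(f, "skipped")
  pem_image(array(f, dim = grid$n), grid,
            meta = list(kind = "osem", iterations = iterations,
                        subsets = subsets, n_lors = nrow(lors$A),
                        position = lors$position, skipped = skipped))
}

# list-mode Poisson log-likelihood of an image given the data (up to const)
lm_loglik <- function(lors, sensitivity, grid, image) {
  cpp_lm_loglik(lors$A, lors$B, as.numeric(sensitivity$data), grid,
                as.numeric(image$data))
}

#' Reconstructed image container
#'
#' @param data 3d numeric array.
#' @param grid a [recon_grid()].
#' @param meta free-form metadata list.
#' @return object of class `pem_image`.
#' @export
pem_image <- function(data, grid, meta = list()) {
  stopifnot(all(dim(data) == grid$n), all(data >= 0))
  structure(list(data = data, grid = grid, meta = meta),
            class = "pem_image")
}

#' @export
print.pem_image <- function(x, ...) {
  cat(sprintf("pem_image %s: %dx%dx%d voxels of %gx%gx%g mm, total %.4g\n",
              if (is.null(x$meta$kind)) "" else x$meta$kind,
              x$grid$n[1], x$grid$n[2], x$grid$n[3],
              x$grid$voxel[1], x$grid$voxel[2], x$grid$voxel[3],
              sum(x$data)))
  invisible(x)
}

#' Isotropic Gaussian post-reconstruction filter
#'
#' Separable 3D Gaussian convolution with `sigma = fwhm / 2.3548` converted
#' per axis to voxel units.  The kernel is normalized, so total intensity is
#' conserved up to boundary truncation.
#'
#' @param image a `pem_image`.
#' @param fwhm isotropic kernel FWHM in mm; `0` returns the image unchanged.
#' @return filtered `pem_image`.
#' @export
gaussian_post_filter <- function(image, fwhm = 1.5) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(image)
  arr <- image$data
  for (axis in 1:3) {
    sigma <- fwhm / (2 * sqrt(2 * log(2))) / image$grid$voxel[axis]
    half <- max(1L, ceiling(4 * sigma))
    kern <- dnorm(seq(-half, half), sd = sigma)
    kern <- kern / sum(kern)
    arr <- convolve_axis(arr, kern, axis)
  }
  pem_image(arr, image$grid, meta = c(image$meta, list(filter_fwhm = fwhm)))
}

# zero-padded 1d convolution along one axis of a 3d array
convolve_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  half <- (length(kern) - 1) / 2
  out <- matrix(0, nrow = dm[1], ncol = ncol(m))
  for (t in seq_along(kern)) {
    off <- t - 1 - half
    src <- seq_len(dm[1]) + off
    okk <- src >= 1 & src <= dm[1]
    out[okk, ] <- out[okk, ] + kern[t] * m[src[okk], ]
  }
  aperm(array(out, dm), order(perm))
}

#' Write a reconstructed image to NIfTI
#'
#' @param image a `pem_image`.
#' @param path output file path (`.nii` / `.nii.gz`).
#' @export
write_image_nifti <- function(image, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to write NIfTI images")
  img <- RNifti::asNifti(image$data, pixdim = image$grid$voxel)
  RNifti::writeNifti(img, path)
  invisible(path)
}
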