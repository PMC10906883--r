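#' Dual-panel PEM scanner geometry
#'
#' Builds the spatial model of the dual-panel scanner: two parallel panels of
#' 3x3 LYSO detector blocks separated along the z axis, with the field of view
#' centred at the origin and the inner crystal faces at `z = +/- panel_gap/2`.
#' Each block is either one monolithic 57.4 x 57.4 x 10 mm crystal or a 40x40
#' array of 1.35 mm pixels at 1.44 mm pitch.  Blocks are placed on a 57.6 mm
#' pitch (the 40-pixel pitch span), so the sensitive span of a panel is
#' 172.8 mm per axis; the monolithic crystal is centred in its block and the
#' pixels are centred in their 1.44 mm cells, the surrounding reflector gaps
#' being treated as vacuum for 511 keV photons.
#'
#' Internally the lateral structure along each in-plane axis is periodic: a
#' point is inside a crystal when its in-cell coordinate lies in
#' `[c_lo, c_hi)` (half-open, lower edge inclusive) along both axes.
#'
#' @param mode `"monolithic"` or `"pixelated"`.
#' @param panel_gap inner-face to inner-face panel separation in mm.
#' @return An object of class `scanner_geometry`.
#' @examples
#' g <- scanner_geometry("pixelated")
#' g$n_crystals   # 28800
#' @export
scanner_geometry <- function(mode = c("monolithic", "pixelated"),
                             panel_gap = 60) {
  if (length(mode) == 1 && !mode %in% c("monolithic", "pixelated"))
    stop("unknown crystal mode: ", mode)
  mode <- match.arg(mode)
  if (!is.numeric(panel_gap) || panel_gap <= 0)
    stop("panel_gap must be a positive length in mm")
  block_pitch <- 57.6
  nblocks <- 3L
  thickness <- 10
  g <- list(
    mode = mode,
    panel_gap = panel_gap,
    crystal_thickness = thickness,
    blocks_per_panel = c(nblocks, nblocks),
    block_pitch = block_pitch,
    block_size = 57.4,
    reflector_gap = 0.09,
    zin = panel_gap / 2,
    zout = panel_gap / 2 + thickness,
    half_span = nblocks * block_pitch / 2,
    nblocks = nblocks
  )
  if (mode == "monolithic") {
    g$crystal_size <- 57.4
    g$pixel_size <- NA_real_
    g$pixel_pitch <- NA_real_
    g$pixels_per_block <- c(1L, 1L)
    g$cell_pitch <- block_pitch
    g$c_lo <- (block_pitch - 57.4) / 2
    g$c_hi <- (block_pitch + 57.4) / 2
    g$cells_per_block <- 1L
    g$n_crystals <- as.integer(2 * nblocks^2)
  } else {
    g$crystal_size <- 1.35
    g$pixel_size <- 1.35
    g$pixel_pitch <- 1.44
    g$pixels_per_block <- c(40L, 40L)
    g$cell_pitch <- 1.44
    g$c_lo <- (1.44 - 1.35) / 2
    g$c_hi <- (1.44 + 1.35) / 2
    g$cells_per_block <- 40L
    g$n_crystals <- as.integer(2 * nblocks^2 * 1600)
  }
  class(g) <- "scanner_geometry"
  g
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat("Dual-panel PEM scanner geometry\n")
  cat(sprintf("  crystal mode    : %s\n", x$mode))
  cat(sprintf("  panel gap       : %g mm (crystals at %g <= |z| < %g mm)\n",
              x$panel_gap, x$zin, x$zout))
  cat(sprintf("  blocks per panel: %dx%d on a %g mm pitch (span %g mm)\n",
              x$blocks_per_panel[1], x$blocks_per_panel[2], x$block_pitch,
              2 * x$half_span))
  cat(sprintf("  crystal elements: %d (%g mm, pitch %g mm)\n",
              x$n_crystals, x$crystal_size,
              if (is.na(x$pixel_pitch)) x$block_pitch else x$pixel_pitch))
  invisible(x)
}

#' Total sensitive LYSO volume of the scanner
#'
#' @param geom a [scanner_geometry()].
#' @param per `"scanner"`, `"panel"` or `"block"`.
#' @return volume in mm^3.
#' @export
crystal_volume <- function(geom, per = c("scanner", "panel", "block")) {
  per <- match.arg(per)
  nper <- if (geom$mode == "monolithic") 1L else 1600L
  vol_block <- nper * geom$crystal_size^2 * geom$crystal_thickness
  switch(per,
         block = vol_block,
         panel = vol_block * prod(geom$blocks_per_panel),
         scanner = 2 * vol_block * prod(geom$blocks_per_panel))
}

# in-cell coordinate along one lateral axis; NA outside the panel span
cell_frac <- function(geom, u) {
  v <- u + geom$half_span
  f <- v - geom$cell_pitch * floor(v / geom$cell_pitch)
  f[v < 0 | v >= 2 * geom$half_span] <- NA_real_
  f
}

#' Locate the crystal element containing points
#'
#' Boundaries are half-open with the lower edge inclusive along every axis.
#'
#' @param geom a [scanner_geometry()].
#' @param points numeric matrix (n x 3) or length-3 vector of world
#'   coordinates in mm.
#' @return data.frame with columns `panel` (-1/+1), `block_i`, `block_j`
#'   (0-based), `pix_i`, `pix_j` (0-based within the block) and `element`
#'   (global 0-based id); all `NA` for points in gaps or outside crystals.
#' @export
locate_element <- function(geom, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  az <- abs(z)
  fx <- cell_frac(geom, x)
  fy <- cell_frac(geom, y)
  inside <- az >= geom$zin & az < geom$zout &
    !is.na(fx) & !is.na(fy) &
    fx >= geom$c_lo & fx < geom$c_hi &
    fy >= geom$c_lo & fy < geom$c_hi
  inside[is.na(inside)] <- FALSE
  n <- length(x)
  out <- data.frame(panel = rep(NA_integer_, n), block_i = NA_integer_,
                    block_j = NA_integer_, pix_i = NA_integer_,
                    pix_j = NA_integer_, element = NA_integer_)
  if (any(inside)) {
    xb <- x[inside] + geom$half_span
    yb <- y[inside] + geom$half_span
    bi <- pmin(geom$nblocks - 1L, as.integer(floor(xb / geom$block_pitch)))
    bj <- pmin(geom$nblocks - 1L, as.integer(floor(yb / geom$block_pitch)))
    ci <- as.integer(floor(xb / geom$cell_pitch)) %% geom$cells_per_block
    cj <- as.integer(floor(yb / geom$cell_pitch)) %% geom$cells_per_block
    pan <- ifelse(z[inside] > 0, 1L, -1L)
    block <- ifelse(pan > 0, 9L, 0L) + bi * 3L + bj
    out$panel[inside] <- pan
    out$block_i[inside] <- bi
    out$block_j[inside] <- bj
    out$pix_i[inside] <- ci
    out$pix_j[inside] <- cj
    out$element[inside] <- block * geom$cells_per_block^2 +
      ci * geom$cells_per_block + cj
  }
  out
}

#' Crystal segments intersected by a ray
#'
#' Returns the ordered crystal-element segments along a ray, with entry and
#' exit path lengths from the origin.  Consistent with [locate_element()] at
#' segment midpoints.
#'
#' @param geom a [scanner_geometry()].
#' @param origin length-3 ray origin (mm).
#' @param direction length-3 unit vector.
#' @param tmax maximum path length considered (mm).
#' @return data.frame with `element`, `entry`, `exit` (mm), ordered by entry.
#' @export
ray_crystal_intersections <- function(geom, origin, direction, tmax = 600) {
  d <- direction / sqrt(sum(direction^2))
  # candidate boundary crossings: z faces, panel edges, cell sub-planes
  ts <- c(0, tmax)
  zplanes <- c(-geom$zout, -geom$zin, geom$zin, geom$zout)
  if (d[3] != 0) ts <- c(ts, (zplanes - origin[3]) / d[3])
  ncell <- geom$nblocks * geom$cells_per_block
  lat_planes <- c(
    rep(geom$cell_pitch * (0:(ncell - 1)), each = 2) +
      c(geom$c_lo, geom$c_hi) - geom$half_span,
    c(-geom$half_span, geom$half_span))
  for (ax in 1:2) {
    if (d[ax] != 0) ts <- c(ts, (lat_planes - origin[ax]) / d[ax])
  }
  ts <- sort(unique(ts[ts >= 0 & ts <= tmax]))
  if (length(ts) < 2) return(data.frame(element = integer(), entry = numeric(),
                                        exit = numeric()))
  mid <- (head(ts, -1) + tail(ts, -1)) / 2
  pts <- cbind(origin[1] + mid * d[1], origin[2] + mid * d[2],
               origin[3] + mid * d[3])
  loc <- locate_element(geom, pts)
  seg <- data.frame(element = loc$element, entry = head(ts, -1),
                    exit = tail(ts, -1))
  seg <- seg[!is.na(seg$element) & seg$exit - seg$entry > 1e-9, , drop = FALSE]
  if (nrow(seg) == 0) return(seg)
  # merge contiguous pieces of the same element
  keep <- c(TRUE, seg$element[-1] != seg$element[-nrow(seg)] |
              abs(seg$entry[-1] - seg$exit[-nrow(seg)]) > 1e-9)
  grp <- cumsum(keep)
  out <- data.frame(
    element = tapply(seg$element, grp, `[`, 1),
    entry = tapply(seg$entry, grp, min),
    exit = tapply(seg$exit, grp, max))
  rownames(out) <- NULL
  out
}

# geometry description consumed by the C++ tracker
geom_cpp <- function(geom) {
  list(zin = geom$zin, zout = geom$zout, half_span = geom$half_span,
       cell_pitch = geom$cell_pitch, c_lo = geom$c_lo, c_hi = geom$c_hi,
       block_pitch = geom$block_pitch, nblocks = geom$nblocks,
       cells_per_block = geom$cells_per_block)
}

#' Write or read a geometry configuration file
#'
#' Serializes the defining parameters (crystal mode and panel gap) to JSON.
#'
#' @param geom a [scanner_geometry()].
#' @param path file path.
#' @return `read_geometry_config` returns a rebuilt [scanner_geometry()].
#' @export
write_geometry_config <- function(geom, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for geometry config files")
  jsonlite::write_json(list(mode = geom$mode, panel_gap = geom$panel_gap),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_config
#' @export
read_geometry_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for geometry config files")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  scanner_geometry(cfg$mode, cfg$panel_gap)
}
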