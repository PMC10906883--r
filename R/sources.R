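#' Phantom emission models
#'
#' Three source geometries emitting back-to-back pairs of 511 keV photons:
#' a uniform cuboid (breast-like background), a miniDerenzo resolution
#' phantom with hot rods parallel to z, and a zero-thickness planar source at
#' the field-of-view mid-plane used for normalization.  All phantoms are
#' air-filled: no attenuation or scatter occurs outside the crystals.
#'
#' @param dim cuboid side lengths in mm (x, y, z).
#' @param activity activity concentration in kBq/ml (rods only for the
#'   Derenzo phantom).
#' @return object of class `phantom_spec`.
#' @export
phantom_cuboid <- function(dim = c(150, 100, 60), activity = 3.7) {
  if (length(dim) != 3 || any(dim <= 0)) stop("invalid cuboid dimensions")
  structure(list(kind = "cuboid", dim = dim, activity = activity,
                 volume_ml = prod(dim) / 1000,
                 rate_per_s = activity * 1000 * prod(dim) / 1000),
            class = "phantom_spec")
}

#' @rdname phantom_cuboid
#' @param diameters hot-rod diameters in mm, one per 60-degree sector.
#' @param radius phantom cylinder radius, mm.
#' @param margin radial clearance between rods and the cylinder wall, mm.
#' @param height rod length, mm (rods centred at z = 0).
#' @export
phantom_derenzo <- function(diameters = c(1, 1.5, 2, 3, 4, 5), radius = 25,
                            margin = 2, height = 20, activity = 3) {
  layout <- build_derenzo_layout(diameters, radius, margin)
  vol_ml <- sum(pi * (layout$diameter / 2)^2 * height) / 1000
  structure(list(kind = "derenzo", diameters = diameters, radius = radius,
                 margin = margin, height = height, activity = activity,
                 layout = layout, volume_ml = vol_ml,
                 rate_per_s = activity * 1000 * vol_ml),
            class = "phantom_spec")
}

#' @rdname phantom_cuboid
#' @param half_span half side of the square planar source, mm.
#' @param total_rate_per_s nominal total emission rate (the planar source has
#'   no volume, so a rate is given directly; it only sets time stamps).
#' @export
phantom_planar <- function(half_span = 86.4, total_rate_per_s = 1e6) {
  structure(list(kind = "planar", half_span = half_span, activity = NA_real_,
                 volume_ml = 0, rate_per_s = total_rate_per_s),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom '%s': emission rate %.3g /s", x$kind, x$rate_per_s))
  if (x$kind == "derenzo")
    cat(sprintf(", %d rods in %d sectors", nrow(x$layout),
                length(x$diameters)))
  cat("\n")
  invisible(x)
}

#' Hot-rod layout of the miniDerenzo phantom
#'
#' Each 60-degree sector holds rods of one diameter `d` on a triangular
#' lattice with a centre-to-centre spacing of `2d`.  The innermost rod sits
#' on the sector bisector at radius `2d`; successive lattice rows move
#' outward by `sqrt(3) d`.  A rod is kept when its circle fits inside radius
#' `radius - margin` and its centre keeps a clearance of at least `d` from
#' the sector boundary rays.
#'
#' @param diameters rod diameters in mm (one sector each, at most 6).
#' @param radius cylinder radius, mm.
#' @param margin radial margin, mm.
#' @return data.frame with `sector`, `diameter`, `row` (lattice row, 0-based,
#'   rows are perpendicular to the sector bisector), `x`, `y` (rod centres,
#'   mm).
#' @export
build_derenzo_layout <- function(diameters = c(1, 1.5, 2, 3, 4, 5),
                                 radius = 25, margin = 2) {
  stopifnot(length(diameters) <= 6, all(diameters > 0))
  out <- list()
  for (s in seq_along(diameters)) {
    d <- diameters[s]
    spacing <- 2 * d
    h <- sqrt(3) / 2 * spacing
    phi <- (s - 1) * pi / 3 + pi / 6        # sector bisector angle
    b1 <- phi - pi / 6                       # boundary ray angles
    b2 <- phi + pi / 6
    rows <- list()
    for (k in 0:floor((radius / h) + 2)) {
      u <- 2 * d + k * h
      v <- (seq_len(k + 1) - 1 - k / 2) * spacing
      cu <- cos(phi); su <- sin(phi)
      x <- u * cu - v * su
      y <- u * su + v * cu
      r <- sqrt(x^2 + y^2)
      # clearance from each boundary ray (perpendicular distance)
      d1 <- abs(x * sin(b1) - y * cos(b1))
      d2 <- abs(x * sin(b2) - y * cos(b2))
      eps <- 1e-9
      ok <- (r + d / 2 <= radius - margin + eps) & d1 >= d - eps &
        d2 >= d - eps
      if (any(ok))
        rows[[length(rows) + 1]] <- data.frame(sector = s, diameter = d,
                                               row = k, x = x[ok], y = y[ok])
    }
    if (length(rows)) out[[s]] <- do.call(rbind, rows)
  }
  layout <- do.call(rbind, out)
  rownames(layout) <- NULL
  layout
}

#' Sample back-to-back emission events
#'
#' Origins are uniform over the phantom's active volume (cuboid interior,
#' union of hot rods, or planar rectangle), directions are isotropic on the
#' sphere and shared (anti-parallel) by the two photons, and event times are
#' cumulative exponential inter-arrivals at the phantom's total emission
#' rate.  Uses R's RNG; call `set.seed()` for reproducibility.
#'
#' @param spec a `phantom_spec`.
#' @param n number of emission events.
#' @param t0 start time, ns.
#' @return data.frame with `event`, `x`, `y`, `z` (mm), `dx`, `dy`, `dz`
#'   (unit direction of photon 0; photon 1 is anti-parallel) and `time` (ns).
#' @export
sample_emissions <- function(spec, n, t0 = 0) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (spec$kind == "cuboid") {
    x <- runif(n, -spec$dim[1] / 2, spec$dim[1] / 2)
    y <- runif(n, -spec$dim[2] / 2, spec$dim[2] / 2)
    z <- runif(n, -spec$dim[3] / 2, spec$dim[3] / 2)
  } else if (spec$kind == "planar") {
    x <- runif(n, -spec$half_span, spec$half_span)
    y <- runif(n, -spec$half_span, spec$half_span)
    z <- rep(0, n)
  } else {
    lay <- spec$layout
    w <- lay$diameter^2            # rod volume weight (equal lengths)
    rod <- sample.int(nrow(lay), n, replace = TRUE, prob = w / sum(w))
    rr <- lay$diameter[rod] / 2 * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    x <- lay$x[rod] + rr * cos(th)
    y <- lay$y[rod] + rr * sin(th)
    z <- runif(n, -spec$height / 2, spec$height / 2)
  }
  # isotropic directions
  cz <- runif(n, -1, 1)
  sz <- sqrt(1 - cz^2)
  ph <- runif(n, 0, 2 * pi)
  dt <- rexp(n, rate = spec$rate_per_s) * 1e9   # ns
  data.frame(event = seq_len(n), x = x, y = y, z = z,
             dx = sz * cos(ph), dy = sz * sin(ph), dz = cz,
             time = t0 + cumsum(dt))
}
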