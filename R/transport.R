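#' Klein-Nishina differential cross section
#'
#' Unnormalized differential cross section `d sigma / d Omega` for Compton
#' scattering of a photon of energy `E` off a free electron at rest, in units
#' of the squared classical electron radius.
#'
#' @param E photon energy, keV.
#' @param theta scattering polar angle, radians.
#' @return numeric vector.
#' @export
klein_nishina <- function(E, theta) {
  k <- E / MEC2
  eps <- 1 / (1 + k * (1 - cos(theta)))
  0.5 * eps^2 * (eps + 1 / eps - sin(theta)^2)
}

#' Scattered photon energy after Compton scattering
#'
#' `E' = E / (1 + (E / m_e c^2)(1 - cos(theta)))`.
#'
#' @param E incident photon energy, keV.
#' @param theta scattering angle, radians.
#' @return scattered photon energy, keV.
#' @export
compton_energy <- function(E, theta) {
  E / (1 + (E / MEC2) * (1 - cos(theta)))
}

#' Sample Compton scattering angles and energies
#'
#' Draws scattering angles from the Klein-Nishina differential cross section
#' at energy `E` (free electron at rest) by the standard
#' composition-rejection method, with the azimuth uniform on `[0, 2 pi)`.
#'
#' @param E incident photon energy, keV (scalar).
#' @param n number of samples.
#' @return data.frame with `E_prime` (keV), `theta`, `phi` (radians).
#' @export
sample_compton <- function(E, n = 1) {
  stopifnot(E > 0, n >= 1)
  k <- E / MEC2
  eps0 <- 1 / (1 + 2 * k)
  a1 <- -log(eps0)
  a2 <- (1 - eps0^2) / 2
  eps <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    e <- ifelse(u1 * (a1 + a2) < a1, exp(-a1 * u2),
                sqrt(eps0^2 + (1 - eps0^2) * u2))
    t <- (1 - e) / (k * e)
    sint2 <- t * (2 - t)
    greject <- 1 - e * sint2 / (1 + e^2)
    acc <- u3 < greject
    eps[todo[acc]] <- e[acc]
    todo <- todo[!acc]
  }
  cost <- 1 - (1 / eps - 1) / k
  data.frame(E_prime = E * eps, theta = acos(pmin(1, pmax(-1, cost))),
             phi = runif(n, 0, 2 * pi))
}

#' Sample photon free path lengths in LYSO
#'
#' Exponentially distributed with mean `10 / mu_tot(E)` millimetres.
#'
#' @param E photon energy, keV (scalar or length-n).
#' @param xs an [lyso_attenuation_table()].
#' @param n number of draws (when `E` is scalar).
#' @return path lengths in mm.
#' @export
sample_free_path <- function(E, xs, n = length(E)) {
  mu <- mu_lyso(xs, E)        # 1/cm; errors outside the table range
  rexp(n, rate = mu / 10)     # mm
}

#' Track a single photon through the scanner
#'
#' Transports one 511 keV photon along straight segments, consuming free
#' paths only inside crystal volumes; at each interaction photoelectric
#' absorption (terminating, depositing the remaining energy) or Compton
#' scattering (depositing `E - E'` locally and continuing in the sampled
#' direction) is chosen with probability proportional to the respective
#' attenuation coefficients.  Energy is deposited at interaction points.
#'
#' @param origin,direction emission point (mm) and unit direction.
#' @param geom a [scanner_geometry()].
#' @param xs an [lyso_attenuation_table()].
#' @param time emission time, ns.
#' @param seed RNG seed for the tracker (drawn from R's RNG by default).
#' @return data.frame of hits: `hit_order`, `x`, `y`, `z`,
#'   `energy_deposited` (keV), `interaction` (`"PE"`/`"CS"`), `time` (ns).
#' @export
track_photon <- function(origin, direction, geom, xs, time = 0,
                         seed = NULL) {
  if (is.null(seed)) seed <- runif(1, 0, 2^31)
  d <- direction / sqrt(sum(direction^2))
  res <- cpp_track_pairs(matrix(origin, ncol = 3), matrix(d, ncol = 3),
                         time, geom_cpp(geom), xs_cpp(xs), seed, TRUE)
  h <- as.data.frame(res$hits)
  h <- h[h$photon == 0, c("hit_order", "x", "y", "z", "energy_deposited",
                          "interaction", "time")]
  h$interaction <- c("PE", "CS")[h$interaction]
  rownames(h) <- NULL
  h
}

#' Track back-to-back photon pairs and form detector singles
#'
#' Transports both annihilation photons of each emission event and merges
#' each photon's hits into per-panel singles carrying the energy-weighted
#' position (EWP), the first-hit position (FHP), the true deposited energy
#' and the interaction-chain summary.  This is the production path of the
#' simulator; [track_photon()] exposes single chains for inspection.
#'
#' @param emissions data.frame from [sample_emissions()].
#' @param geom a [scanner_geometry()].
#' @param xs an [lyso_attenuation_table()].
#' @param seed tracker seed (drawn from R's RNG by default).
#' @param hits if `TRUE` also return the full hit list.
#' @param chunk events per tracking chunk (memory control).
#' @return data.frame of singles (see Details), or
#'   `list(singles, hits)` when `hits = TRUE`.
#' @details Singles columns: `event`, `photon` (0/1), `panel` (-1/+1),
#'   `block`, `sipm`, `element` (0-based readout ids of the first hit),
#'   `n_hits`, `n_compton`, `terminal_pe` (1 when the chain ends in
#'   photoelectric absorption inside this panel), `energy_true` (keV),
#'   `ewx`, `ewy`, `ewz`, `fhx`, `fhy`, `fhz` (mm), `time` (ns, first hit)
#'   and `energy_escaped` (keV leaving the detector).
#' @export
track_emissions <- function(emissions, geom, xs, seed = NULL, hits = FALSE,
                            chunk = 500000L) {
  if (is.null(seed)) seed <- runif(1, 0, 2^31)
  n <- nrow(emissions)
  starts <- seq(1L, n, by = chunk)
  gl <- geom_cpp(geom)
  xl <- xs_cpp(xs)
  out_s <- vector("list", length(starts))
  out_h <- if (hits) vector("list", length(starts)) else NULL
  for (ci in seq_along(starts)) {
    i0 <- starts[ci]
    i1 <- min(i0 + chunk - 1L, n)
    idx <- i0:i1
    res <- cpp_track_pairs(
      cbind(emissions$x[idx], emissions$y[idx], emissions$z[idx]),
      cbind(emissions$dx[idx], emissions$dy[idx], emissions$dz[idx]),
      emissions$time[idx], gl, xl, seed + 7919 * (ci - 1), hits)
    s <- cbind(as.data.frame(res$singles), as.data.frame(res$block))
    s$event <- s$event + (i0 - 1)
    out_s[[ci]] <- s
    if (hits) {
      h <- as.data.frame(res$hits)
      h$event <- h$event + (i0 - 1)
      out_h[[ci]] <- h
    }
  }
  singles <- do.call(rbind, out_s)
  if (!hits) return(singles)
  hh <- do.call(rbind, out_h)
  hh$interaction <- c("PE", "CS")[hh$interaction]
  list(singles = singles, hits = hh)
}
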