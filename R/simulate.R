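#' Run a complete simulated acquisition
#'
#' Samples emissions from a phantom, transports both annihilation photons
#' through the chosen crystal configuration and runs the digitizer chain,
#' returning the registered coincidences.  This is the top-level entry point
#' of the simulator; the study-scale defaults (cuboid at 3.7 kBq/ml,
#' Derenzo rods at 3 kBq/ml) live in the phantom constructors.
#'
#' @param phantom a `phantom_spec`.
#' @param geom a [scanner_geometry()].
#' @param n_events number of back-to-back emissions.
#' @param xs attenuation table (defaults to the packaged LYSO table).
#' @param seed integer seed for all randomness in the run (emissions,
#'   transport and digitizer); `NULL` continues from R's current RNG state.
#' @param chunk events per tracking chunk.
#' @param lean drop singles columns not needed by the default digitizer and
#'   the downstream analyses (axial positions, escaped energy, unused
#'   readout ids) to bound memory at large event counts.
#' @param ... digitizer settings passed to [digitize()].
#' @return list with `coincidences`, `singles`, `counters` and `geom`.
#' @examples
#' \donttest{
#' run <- simulate_study(phantom_cuboid(), scanner_geometry("monolithic"),
#'                       n_events = 2e4, seed = 1)
#' classify_coincidences(run$coincidences)
#' }
#' @export
simulate_study <- function(phantom, geom, n_events,
                           xs = lyso_attenuation_table(), seed = NULL,
                           chunk = 500000L, lean = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  cpp_seed <- floor(runif(1, 1, 2^31))
  n_events <- as.integer(n_events)
  dots <- list(...)
  drop_cols <- character(0)
  if (lean) {
    drop_cols <- c("ewz", "fhz", "energy_escaped", "element", "block")
    readout <- if (is.null(dots$readout)) "panel" else dots$readout
    if (readout == "panel")
      drop_cols <- c(drop_cols, "bewx", "bewy", "bewz", "energy_block",
                     "block_win")
  }
  starts <- seq(1L, n_events, by = chunk)
  out <- vector("list", length(starts))
  t0 <- 0
  for (ci in seq_along(starts)) {
    m <- min(chunk, n_events - starts[ci] + 1L)
    em <- sample_emissions(phantom, m, t0 = t0)
    t0 <- em$time[m]
    s <- track_emissions(em, geom, xs, seed = cpp_seed + 104729 * ci,
                         chunk = m)
    s$event <- s$event + (starts[ci] - 1L)
    if (length(drop_cols))
      s <- s[, setdiff(names(s), drop_cols), drop = FALSE]
    out[[ci]] <- s
  }
  singles <- do.call(rbind, out)
  rm(out)
  dig <- digitize(singles, ...)
  list(coincidences = dig$coincidences, singles = dig$singles,
       counters = c(dig$counters, list(n_emissions = n_events)),
       geom = geom)
}

#' Reconstruct a Derenzo acquisition
#'
#' Converts a coincidence set to virtual-crystal LORs at the requested
#' positioning mode, builds the sensitivity image from a planar
#' normalization acquisition and runs list-mode OSEM.
#'
#' @param coinc study coincidences.
#' @param norm_coinc planar-source normalization coincidences (same geometry
#'   and digitizer settings).
#' @param geom a [scanner_geometry()].
#' @param position `"fhp"` or `"ewp"` LOR endpoints.
#' @param grid a [recon_grid()].
#' @param filter_fwhm optional Gaussian post-filter FWHM in mm (0 = none).
#' @param iterations,subsets OSEM settings.
#' @param pitch virtual crystal pitch, mm.
#' @return a `pem_image`.
#' @export
reconstruct_study <- function(coinc, norm_coinc, geom, position = "fhp",
                              grid = recon_grid(), filter_fwhm = 0,
                              iterations = 2, subsets = 28, pitch = 1.44) {
  norm_lors <- virtual_lors(norm_coinc, geom, position = "fhp", pitch = pitch)
  sens <- build_sensitivity(norm_lors, grid)
  lors <- virtual_lors(coinc, geom, position = position, pitch = pitch)
  img <- lm_osem(lors, sens, grid, iterations = iterations,
                 subsets = subsets)
  if (filter_fwhm > 0) img <- gaussian_post_filter(img, filter_fwhm)
  img
}
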