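#' Merge a photon's hits into detector singles
#'
#' Reference implementation of the singles builder: hits are grouped per
#' `(event, photon, panel)` and merged into one single per group with the
#' energy-weighted centroid position (EWP), the first-hit position (FHP),
#' the summed true energy and the interaction-chain summary.  The production
#' tracker ([track_emissions()]) performs the same aggregation in compiled
#' code; the two paths are interchangeable.
#'
#' @param hits data.frame with `event`, `photon`, `hit_order`, `x`, `y`, `z`,
#'   `energy_deposited`, `interaction` (`"PE"`/`"CS"` or 1/2), `time`.
#' @return data.frame of singles with the columns described in
#'   [track_emissions()] (readout ids omitted).
#' @export
make_singles <- function(hits) {
  if (nrow(hits) == 0) stop("no hits to merge")
  inter <- if (is.character(hits$interaction)) {
    match(hits$interaction, c("PE", "CS"))
  } else as.integer(hits$interaction)
  panel <- ifelse(hits$z > 0, 1L, -1L)
  key <- interaction(hits$event, hits$photon, panel, drop = TRUE)
  ord <- order(hits$event, hits$photon, hits$hit_order)
  hits <- hits[ord, ]; inter <- inter[ord]; panel <- panel[ord]
  key <- key[ord]
  res <- lapply(split(seq_len(nrow(hits)), key), function(ii) {
    h <- hits[ii, ]
    e <- h$energy_deposited
    # chain terminal: last hit of the whole photon chain
    all_ph <- hits$event == h$event[1] & hits$photon == h$photon[1]
    last <- hits[all_ph, ][which.max(hits$hit_order[all_ph]), ]
    data.frame(
      event = h$event[1], photon = h$photon[1], panel = panel[ii[1]],
      n_hits = nrow(h), n_compton = sum(inter[ii] == 2L),
      terminal_pe = as.integer(inter[all_ph][which.max(hits$hit_order[all_ph])] == 1L &&
                                 (last$z > 0) == (panel[ii[1]] > 0)),
      energy_true = sum(e),
      ewx = if (nrow(h) == 1) h$x[1] else sum(e * h$x) / sum(e),
      ewy = if (nrow(h) == 1) h$y[1] else sum(e * h$y) / sum(e),
      ewz = if (nrow(h) == 1) h$z[1] else sum(e * h$z) / sum(e),
      fhx = h$x[1], fhy = h$y[1], fhz = h$z[1], time = h$time[1])
  })
  out <- do.call(rbind, res)
  out <- out[order(out$event, out$photon, out$panel), ]
  rownames(out) <- NULL
  out
}

#' Gaussian energy blurring
#'
#' Applies the detector energy resolution as a Gaussian blur with
#' `FWHM(E) = resolution * sqrt(511 / E) * E` (the conventional
#' 1/sqrt(E) scaling anchored at 511 keV).
#'
#' @param E true energies, keV.
#' @param resolution fractional FWHM resolution at 511 keV.
#' @return blurred energies, keV.
#' @export
blur_energy <- function(E, resolution = 0.13) {
  stopifnot(all(E > 0), resolution >= 0)
  if (resolution == 0) return(E)
  fwhm <- resolution * sqrt(511 * E)
  rnorm(length(E), mean = E, sd = fwhm / (2 * sqrt(2 * log(2))))
}

#' Non-paralyzable dead time
#'
#' Discards singles arriving less than `tau_us` after the last accepted
#' single in the same electronic unit.
#'
#' @param singles data.frame of singles, sorted by `time` (an error
#'   otherwise).
#' @param tau_us dead time in microseconds.
#' @param by readout granularity at which dead time applies: `"sipm"`
#'   (per 6x6 mm SiPM cell, 64 per block), `"block"` (per detector block) or
#'   `"element"` (per crystal element).
#' @return the surviving singles.
#' @export
apply_dead_time <- function(singles, tau_us = 6,
                            by = c("sipm", "block", "element")) {
  by <- match.arg(by)
  if (tau_us == 0 || nrow(singles) == 0) return(singles)
  if (is.unsorted(singles$time))
    stop("singles must be sorted by time before dead-time filtering")
  unit <- as.integer(singles[[by]])
  keep <- cpp_dead_time(singles$time, unit, tau_us * 1000)
  singles[keep, , drop = FALSE]
}

#' Coincidence sorting
#'
#' Keeps singles whose blurred energy falls inside the energy window, then
#' forms coincidence windows of fixed width: the first qualifying single
#' opens a window; a window holding exactly two singles in opposite panels
#' yields a coincidence, and windows with more than two singles are discarded
#' entirely.  A coincidence is flagged random when its two singles belong to
#' different emission events.
#'
#' @param singles data.frame of singles with a `energy_blurred` column,
#'   sorted by time.
#' @param window_ns coincidence timing window, ns.
#' @param energy_window keV pair `(low, high)`.
#' @return data.frame of coincidences: all single columns suffixed `_a`
#'   (panel -z) and `_b` (panel +z), plus `class` (`"SI-SI"`, `"MI-SI"`,
#'   `"MI-MI"`) and `is_random`; attributes `n_multiple` and `n_same_panel`
#'   count discarded windows.
#' @export
sort_coincidences <- function(singles, window_ns = 6,
                              energy_window = c(350, 750)) {
  if (is.unsorted(singles$time))
    stop("singles must be sorted by time before coincidence sorting")
  if (!"energy_blurred" %in% names(singles))
    stop("singles must carry blurred energies (see blur_energy)")
  ok <- singles$energy_blurred >= energy_window[1] &
    singles$energy_blurred <= energy_window[2]
  s <- singles[ok, , drop = FALSE]
  res <- cpp_coincidence_sort(s$time, as.integer(s$panel), window_ns)
  a <- s[res$a, , drop = FALSE]
  b <- s[res$b, , drop = FALSE]
  names(a) <- paste0(names(a), "_a")
  names(b) <- paste0(names(b), "_b")
  coinc <- cbind(a, b)
  rownames(coinc) <- NULL
  mi_a <- coinc$n_hits_a >= 2
  mi_b <- coinc$n_hits_b >= 2
  coinc$class <- ifelse(mi_a & mi_b, "MI-MI",
                        ifelse(mi_a | mi_b, "MI-SI", "SI-SI"))
  coinc$is_random <- coinc$event_a != coinc$event_b
  attr(coinc, "n_multiple") <- res$n_multiple
  attr(coinc, "n_same_panel") <- res$n_same_panel
  coinc
}

#' Full digitizer chain
#'
#' Time-sorts the singles, applies dead time, blurs energies and sorts
#' coincidences, mirroring the digitizer of the simulated acquisition:
#' 13% energy resolution at 511 keV, 6 us dead time, 6 ns coincidence
#' window and a 350-750 keV energy window.
#'
#' @param singles data.frame from [track_emissions()].
#' @inheritParams apply_dead_time
#' @inheritParams sort_coincidences
#' @param resolution fractional energy resolution (FWHM) at 511 keV.
#' @param dead_time_by readout granularity for dead time (see
#'   [apply_dead_time()]).
#' @param readout `"panel"` (default) merges all of a photon's hits in a
#'   panel into one pulse, so the energy-weighted position spans the full
#'   track including cross-block scatter.  `"block"` forms the recorded
#'   pulse at detector-block depth instead: the single's energy and
#'   energy-weighted position come from the block collecting the most
#'   energy, so a chain scattering across blocks is accepted only if one
#'   block's deposit passes the energy window.  Chain descriptors
#'   (`n_hits`, `n_compton`, first-hit position) always refer to the
#'   photon's full track in the panel.
#' @return list with `coincidences`, `singles` (post dead time, blurred) and
#'   `counters` (singles in/out, discarded windows, randoms).
#' @export
digitize <- function(singles, resolution = 0.13, tau_us = 6,
                     dead_time_by = "sipm", window_ns = 6,
                     energy_window = c(350, 750),
                     readout = c("panel", "block")) {
  readout <- match.arg(readout)
  if (readout == "block" && "energy_block" %in% names(singles)) {
    singles$energy_true <- singles$energy_block
    singles$ewx <- singles$bewx
    singles$ewy <- singles$bewy
    singles$ewz <- singles$bewz
  }
  singles <- singles[order(singles$time), , drop = FALSE]
  n_in <- nrow(singles)
  singles <- apply_dead_time(singles, tau_us, dead_time_by)
  singles$energy_blurred <- blur_energy(singles$energy_true, resolution)
  coinc <- sort_coincidences(singles, window_ns, energy_window)
  list(coincidences = coinc, singles = singles,
       counters = list(singles_in = n_in, singles_alive = nrow(singles),
                       n_multiple = attr(coinc, "n_multiple"),
                       n_same_panel = attr(coinc, "n_same_panel"),
                       n_coincidences = nrow(coinc),
                       n_random = sum(coinc$is_random)))
}
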