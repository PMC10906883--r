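# shared fixtures; heavyweight runs are memoised so several test files can
# reuse the same simulated acquisition
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

lyso_xs <- function() fixture("xs", lyso_attenuation_table)

# uniform-cuboid study at the acceptance scale (5e5 emissions)
cuboid_run <- function(mode) {
  fixture(paste0("cuboid_", mode), function()
    simulate_study(phantom_cuboid(), scanner_geometry(mode), n_events = 5e5,
                   seed = 20240301))
}

# small hit-level tracking run for transport/digitizer checks
hits_run <- function(mode = "monolithic", n = 20000) {
  fixture(paste0("hits_", mode), function() {
    set.seed(402)
    em <- sample_emissions(phantom_cuboid(), n)
    track_emissions(em, scanner_geometry(mode), lyso_xs(), seed = 915,
                    hits = TRUE)
  })
}

# a cross-section table with one process switched off
xs_single_process <- function(keep = c("pe", "cs")) {
  keep <- match.arg(keep)
  xs <- lyso_xs()
  if (keep == "pe") xs$mu_cs[] <- 1e-12 else xs$mu_pe[] <- 1e-12
  xs$mu_tot <- xs$mu_pe + xs$mu_cs
  xs
}

# analytic chord length of a segment through an axis-aligned box
chord_in_box <- function(p0, p1, lo, hi) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (a in 1:3) {
    if (d[a] == 0) {
      if (p0[a] < lo[a] || p0[a] >= hi[a]) return(0)
    } else {
      ta <- (lo[a] - p0[a]) / d[a]; tb <- (hi[a] - p0[a]) / d[a]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
    }
  }
  if (t1 <= t0) return(0)
  (t1 - t0) * sqrt(sum(d^2))
}
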