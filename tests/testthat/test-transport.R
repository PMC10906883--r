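test_that("LYSO attenuation table reproduces the expected 511 keV behaviour", {
  xs <- lyso_xs()
  share <- mu_lyso(xs, 511, "compton") / mu_lyso(xs, 511)
  expect_equal(share, 0.67, tolerance = 0.03)
  mt <- mu_lyso(xs, 511)
  expect_gte(mt, 0.80)
  expect_lte(mt, 0.90)
  # photoelectric falls with energy; coefficients additive by construction
  expect_gt(mu_lyso(xs, 100, "photoelectric"), mu_lyso(xs, 511, "photoelectric"))
  expect_equal(xs$mu_tot, xs$mu_pe + xs$mu_cs)
  expect_error(mu_lyso(xs, 5), "range")
  expect_error(mu_lyso(xs, 800), "range")
  # mixture needs every element over the full range
  tab <- read.csv(system.file("extdata", "element_photon_xs_synthetic.csv",
                              package = "pemscat"))
  tmp <- tempfile(fileext = ".csv")
  write.csv(tab[tab$element != "Lu", ], tmp, row.names = FALSE)
  expect_error(lyso_attenuation_table(tmp), "Lu")
})

test_that("Compton kinematics follow the closed-form energy relation", {
  expect_equal(compton_energy(511, 0), 511)
  # 511/3 up to the difference between 511 keV and the electron rest energy
  expect_equal(compton_energy(511, pi), 511 / 3, tolerance = 1e-5)
  expect_equal(compton_energy(200, pi / 2), 200 / (1 + 200 / 510.99895),
               tolerance = 1e-9)
})

test_that("sampled Compton angles follow the Klein-Nishina distribution", {
  # oracle: numerically integrated Klein-Nishina dsigma/dOmega * sin(theta)
  for (E in c(511, 200)) {
    set.seed(5150 + E)
    n <- 2e5
    sm <- sample_compton(E, n)
    # consistency of the sampled pair (E', theta)
    expect_equal(sm$E_prime, compton_energy(E, sm$theta), tolerance = 1e-9)
    breaks <- seq(0, pi, length.out = 31)
    th <- seq(0, pi, length.out = 20001)
    dens <- klein_nishina(E, th) * sin(th)
    cdf <- cumsum(c(0, (dens[-1] + dens[-length(th)]) / 2 * diff(th)))
    cdf <- cdf / max(cdf)
    pexp <- diff(stats::approx(th, cdf, breaks)$y)
    obs <- tabulate(cut(sm$theta, breaks, labels = FALSE), nbins = 30)
    chi2 <- sum((obs - n * pexp)^2 / (n * pexp))
    # 30 bins: generous chi-square bound (p ~ 1e-4)
    expect_lt(chi2, 70)
  }
})

test_that("free path lengths are exponential with mean 10/mu_tot mm", {
  xs <- lyso_xs()
  set.seed(99)
  s <- sample_free_path(511, xs, n = 1e6)
  expect_equal(mean(s), 10 / mu_lyso(xs, 511), tolerance = 0.005)
  # doubling the attenuation halves the mean free path
  xs2 <- xs
  xs2$mu_pe <- 2 * xs$mu_pe; xs2$mu_cs <- 2 * xs$mu_cs
  xs2$mu_tot <- 2 * xs$mu_tot
  s2 <- sample_free_path(511, xs2, n = 1e6)
  expect_equal(mean(s2) / mean(s), 0.5, tolerance = 0.01)
  expect_error(sample_free_path(900, xs), "range")
})

test_that("photoelectric-only physics yields single full-energy hits", {
  g <- scanner_geometry("monolithic")
  xs <- xs_single_process("pe")
  set.seed(31)
  em <- sample_emissions(phantom_cuboid(), 3000)
  tr <- track_emissions(em, g, xs, seed = 8, hits = TRUE)
  expect_true(all(tr$singles$n_hits == 1))
  expect_true(all(tr$singles$energy_true == 511))
  expect_true(all(tr$hits$interaction == "PE"))
  # track_photon exposes the same chain for a single photon
  h1 <- track_photon(c(0, 0, 0), c(0, 0, 1), g, xs, seed = 4)
  expect_identical(nrow(h1), 1L)
  expect_identical(h1$interaction, "PE")
  expect_equal(h1$energy_deposited, 511)
})

test_that("photon chains conserve energy and terminate correctly", {
  tr <- hits_run()
  h <- tr$hits
  key <- paste(h$event, h$photon)
  esum <- tapply(h$energy_deposited, key, sum)
  expect_true(all(esum <= 511 + 1e-9))
  # chains ending in photoelectric absorption deposit the full 511 keV
  ord <- order(h$event, h$photon, h$hit_order)
  h <- h[ord, ]
  lastint <- tapply(h$interaction, paste(h$event, h$photon), function(v)
    v[length(v)])
  pe_chains <- as.numeric(esum[names(lastint)[lastint == "PE"]])
  expect_lt(max(abs(pe_chains - 511)), 1e-9)
  # hit order strictly increasing, PE only terminal
  expect_true(all(tapply(h$hit_order, paste(h$event, h$photon), function(v)
    all(diff(v) == 1))))
  notlast <- tapply(h$interaction, paste(h$event, h$photon), function(v)
    any(v[-length(v)] == "PE"))
  expect_false(any(notlast))
})

test_that("interaction probability in a 10 mm slab matches exp(-mu t)", {
  g <- scanner_geometry("monolithic")
  xs <- lyso_xs()
  set.seed(12)
  n <- 1e5
  # normal incidence through the crystal centre of the +z panel
  em <- data.frame(event = seq_len(n), x = runif(n, -20, 20),
                   y = runif(n, -20, 20), z = 0, dx = 0, dy = 0, dz = 1,
                   time = seq_len(n) * 1e4)
  s <- track_emissions(em, g, xs, seed = 55)
  # count photons with at least one interaction (a backscattered photon can
  # produce singles in both panels, so count distinct photons, not singles)
  p_obs <- nrow(unique(s[, c("event", "photon")])) / (2 * n)
  p_exp <- 1 - exp(-mu_lyso(xs, 511) * 1.0)
  expect_equal(p_obs, p_exp, tolerance = 3 * sqrt(p_exp / (2 * n)) / p_exp)
})

test_that("compiled singles match the reference R implementation", {
  tr <- hits_run()
  s_ref <- make_singles(tr$hits)
  s_cpp <- tr$singles[order(tr$singles$event, tr$singles$photon,
                            tr$singles$panel), ]
  expect_identical(nrow(s_ref), nrow(s_cpp))
  for (col in c("event", "photon", "panel", "n_hits", "n_compton",
                "terminal_pe"))
    expect_equal(s_ref[[col]], s_cpp[[col]], ignore_attr = TRUE)
  for (col in c("energy_true", "ewx", "ewy", "ewz", "fhx", "fhy", "fhz",
                "time"))
    expect_equal(s_ref[[col]], s_cpp[[col]], tolerance = 1e-12,
                 ignore_attr = TRUE)
})
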