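test_that("chamber validation", {
  expect_error(chamber_spec(injection_y_cm = 2), "within")
  expect_error(chamber_spec(injection_band_width_um = 2e4), "narrower")
  expect_error(chamber_spec(collection_edge = "y_max"), "x_max")
})

test_that("weak field effectively off sends every particle along theta1", {
  # duty -> 1 starves the weak-field half-cycle below its reorientation time
  p <- paper_protocol(f_Hz = 2, duty = 0.999)
  sim <- simulate_streams(p, 2000, chamber_spec(), builtin_mobility_model(),
                          n_particles = 50, seed = 3)
  expect_true(all(sim$samples$collected))
  expect_equal(sim$samples$angle_deg, rep(25, 50), tolerance = 1e-9)
})

test_that("identical seeds reproduce bit-identical exit samples", {
  p <- paper_protocol(f_Hz = 2)
  args <- list(p, c(2000, 10000), chamber_spec(), builtin_mobility_model(),
               n_particles = 300, seed = 11)
  s1 <- do.call(simulate_streams, args)
  s2 <- do.call(simulate_streams, args)
  expect_identical(s1$samples, s2$samples)
  # and with diffusion on
  s3 <- simulate_streams(p, 2000, chamber_spec(), builtin_mobility_model(),
                         n_particles = 100, seed = 11,
                         diffusion_coeff = 1e-8)
  s4 <- simulate_streams(p, 2000, chamber_spec(), builtin_mobility_model(),
                         n_particles = 100, seed = 11,
                         diffusion_coeff = 1e-8)
  expect_identical(s3$samples, s4$samples)
})

test_that("particles are conserved: injected = collected + still in chamber", {
  p <- paper_protocol(f_Hz = 0.5)
  sim <- simulate_streams(p, 5000, chamber_spec(), builtin_mobility_model(),
                          n_particles = 200, seed = 4, max_periods = 20)
  pf <- sim$per_fragment[[1]]
  expect_identical(pf$n_collected + pf$n_in_chamber, 200L + 0L)
  expect_gt(pf$n_in_chamber, 0)  # the cap left some in transit
  # uncollected positions are inside the chamber
  pos <- pf$positions[!pf$samples$collected, , drop = FALSE]
  expect_true(all(pos[, "x_cm"] >= 0 & pos[, "x_cm"] <= 1))
})

test_that("mean simulated exit angle agrees with the closed-form angle", {
  m <- builtin_mobility_model()
  for (f in c(0.5, 2)) {
    p <- paper_protocol(f_Hz = f)
    d <- migration_angle(p, fragment_spec(2000), model = m)
    sim <- simulate_streams(p, 2000, chamber_spec(), m,
                            n_particles = 2000, seed = 8)
    # deterministic sawtooth: agreement limited by the finite-chamber
    # first-crossing offset, far below any measurable angle difference
    expect_lt(abs(sim$per_fragment[[1]]$angle_mean_deg - d$phi_deg), 0.05)
  }
  # quasi-static limit is exact
  p0 <- paper_protocol(f_Hz = 0)
  d0 <- migration_angle(p0, fragment_spec(2000), model = m)
  s0 <- simulate_streams(p0, 2000, chamber_spec(), m,
                         n_particles = 50, seed = 8)
  expect_equal(s0$per_fragment[[1]]$angle_mean_deg, d0$phi_deg,
               tolerance = 1e-9)
})

test_that("one-period transverse excursion of a logged trajectory matches the closed form", {
  m <- builtin_mobility_model()
  fr <- fragment_spec(2000)
  mu2 <- evaluate_mobility(m, 22.4, fr)
  f_or2 <- mu2 * 22.4 / (2 * fr$contour_length_cm)
  f <- f_or2 / 100  # far below the weak-field reorientation frequency
  p <- paper_protocol(f_Hz = f)
  sim <- simulate_streams(p, fr, chamber_spec(), m, n_particles = 1,
                          seed = 2, random_phase = FALSE,
                          log_trajectories = TRUE)
  tr <- sim$per_fragment[[1]]$trajectory
  # steps alternate field-1 / field-2 half-cycles after the step-0 origin;
  # take the weak-field leg of the second full period
  leg2 <- tr[tr$step == 4, ] # end of field-2 half-cycle
  leg1 <- tr[tr$step == 3, ] # end of preceding field-1 half-cycle
  dy2 <- leg2$y_cm - leg1$y_cm
  dx2 <- leg2$x_cm - leg1$x_cm
  measured_um <- abs(dy2 + tanpi(25 / 180) * dx2) * 1e4
  lfr <- band_broadening_excursion(p, mu2, fr)
  expect_equal(measured_um, lfr$L_fr_um, tolerance = 0.05)
})

test_that("band broadening excursion scales as 1/f and hits the worked values", {
  fr <- fragment_spec(10000)
  p1 <- field_protocol(59.5, 24.6, 25, 115, f_Hz = 0.05)
  p2 <- field_protocol(59.5, 24.6, 25, 115, f_Hz = 0.1)
  b1 <- band_broadening_excursion(p1, 2.75e-5, fr)
  b2 <- band_broadening_excursion(p2, 2.75e-5, fr)
  expect_equal(b1$L_fr_um, 2 * b2$L_fr_um)
  expect_equal(b1$L_fr_um, 48, tolerance = 0.1)  # direct arithmetic
  # a 33 um excursion against the 110 um injection band is a 30% fraction
  expect_equal(band_broadening_excursion(p1, 2.75e-5, fr)$fraction_of_injection,
               b1$L_fr_um / 110)
  expect_error(
    band_broadening_excursion(field_protocol(50, 20, 90, 115, f_Hz = 1),
                              2.75e-5, fr), "singular")
  expect_error(
    band_broadening_excursion(field_protocol(50, 20, 25, 115, f_Hz = 0),
                              2.75e-5, fr), "f > 0")
})

test_that("exit-position spread stays close to the injection width at f >= 2 Hz", {
  m <- builtin_mobility_model()
  inj_sd <- 110 / sqrt(12)  # top-hat standard deviation, um
  for (f in c(2, 12)) {
    sim <- simulate_streams(paper_protocol(f_Hz = f), 500, chamber_spec(),
                            m, n_particles = 3000, seed = 21)
    sd_um <- sim$per_fragment[[1]]$exit_sd_cm * 1e4
    expect_lt(abs(sd_um - inj_sd) / inj_sd, 0.15)
  }
})

test_that("a protocol with no transport raises an explicit error", {
  m <- builtin_mobility_model()
  expect_error(
    simulate_streams(paper_protocol(f_Hz = 30), 10000, chamber_spec(), m,
                     n_particles = 10, seed = 1),
    "no transport")
  # diffusion rescues transport (no error)
  expect_s3_class(
    simulate_streams(paper_protocol(f_Hz = 30), 10000, chamber_spec(), m,
                     n_particles = 5, seed = 1, diffusion_coeff = 1e-7,
                     max_periods = 50),
    "stream_simulation")
})

test_that("seed is mandatory", {
  expect_error(simulate_streams(paper_protocol(), 2000, chamber_spec(),
                                builtin_mobility_model(), n_particles = 5),
               "seed")
})

test_that("exit profiles histogram and normalize exit positions", {
  # all particles at one position: a single occupied bin
  pr <- exit_profile(rep(500, 40), bin_width_um = 10)
  expect_identical(sum(pr$intensities > 0), 1L)
  expect_equal(sum(pr$intensities), 1)

  # a known Gaussian cloud: fitted sigma within 10% at n = 5000
  set.seed(31)
  y <- rnorm(5000, 4000, 50)
  pk <- fit_peaks(exit_profile(y, bin_width_um = 10), 1)
  expect_equal(pk$sigma_um, sd(y), tolerance = 0.1)
  expect_equal(pk$center_um, mean(y), tolerance = 0.01)

  # two well-separated streams give two disjoint modes
  sim <- simulate_streams(paper_protocol(f_Hz = 2), c(500, 10000),
                          chamber_spec(), builtin_mobility_model(),
                          n_particles = 400, seed = 13)
  pr2 <- exit_profile(sim, bin_width_um = 20)
  occ <- which(pr2$intensities > 0)
  expect_gt(max(diff(occ)), 50)  # a wide empty gap between the modes
})
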