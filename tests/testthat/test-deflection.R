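test_that("effective velocity: no switching loss at f = 0, zero at f = f_or", {
  fr <- fragment_spec(10000)
  expect_equal(effective_velocity(2.75e-5, 22.4, 0, fr), 2.75e-5 * 22.4)
  f_or <- 2.75e-5 * 22.4 / (2 * fr$contour_length_cm)
  expect_equal(effective_velocity(2.75e-5, 22.4, f_or, fr), 0)
  # worked value: mu E = 6.16e-4 cm/s, 2 f L = 3.4e-4 cm/s
  expect_equal(effective_velocity(2.75e-5, 22.4, 0.5, fr),
               6.16e-4 - 3.4e-4, tolerance = 1e-10)
})

test_that("migration angle symmetric and clamped limits", {
  # equal fields at 0 and 90 degrees bisect to 45
  p <- field_protocol(50, 50, 0, 90, f_Hz = 0)
  d <- migration_angle(p, fragment_spec(1000), mu = c(1e-4, 1e-4))
  expect_equal(d$phi_deg, 45)
  # f above the weak-field f_or but below the strong-field one: phi = theta1
  fr <- fragment_spec(10000)
  p2 <- paper_protocol(f_Hz = 2)
  d2 <- migration_angle(p2, fr, model = builtin_mobility_model())
  expect_identical(d2$phi_deg, 25)
  expect_identical(d2$v_eff2_cm_s, 0)
  expect_identical(d2$regime, "switchback_window")
})

test_that("migration angle reproduces the direct vector-sum worked value", {
  p <- paper_protocol(f_Hz = 0)
  d <- migration_angle(p, fragment_spec(2000), mu = c(2.75e-5, 2.75e-5))
  # independent arithmetic: atan2(v1 sin25 + v2 sin115, v1 cos25 + v2 cos115)
  v1 <- 2.75e-5 * 59.5
  v2 <- 2.75e-5 * 22.4
  ref <- atan2(v1 * sinpi(25 / 180) + v2 * sinpi(115 / 180),
               v1 * cospi(25 / 180) + v2 * cospi(115 / 180)) * 180 / pi
  expect_equal(d$phi_deg, ref)
  expect_equal(d$phi_deg, 45.63, tolerance = 1e-2)
})

test_that("ion angle is mobility- and frequency-free and matches its limits", {
  expect_equal(ion_angle(field_protocol(30, 30, 0, 90)), 45)
  # E2 -> 0 follows field 1 (use a tiny weak field: E2 must stay positive)
  expect_equal(ion_angle(field_protocol(50, 1e-12, 25, 115)), 25,
               tolerance = 1e-9)
  p <- paper_protocol()
  expect_equal(ion_angle(p), 45.63, tolerance = 1e-2)
  for (f in c(0, 0.5, 20)) {
    p$f_Hz <- f
    expect_equal(ion_angle(p), ion_angle(paper_protocol()))
  }
})

test_that("equal mobilities at f = 0 reduce the DNA angle to the ion angle (random protocols)", {
  set.seed(99)
  for (i in 1:200) {
    E2 <- runif(1, 1, 80)
    E1 <- E2 * runif(1, 1, 3.5)
    p <- field_protocol(E1, E2, runif(1, -80, 80), runif(1, -80, 170),
                        f_Hz = 0, duty = runif(1, 0.1, 0.9))
    mu <- runif(1, 1e-5, 1e-3)
    d <- migration_angle(p, fragment_spec(3000), mu = c(mu, mu))
    expect_lt(abs(d$phi_deg - ion_angle(p)), 1e-9)
  }
})

test_that("angle is bounded by the field angles and decreases with frequency", {
  m <- builtin_mobility_model()
  set.seed(5)
  for (i in 1:40) {
    p <- paper_protocol(f_Hz = runif(1, 0, 8))
    fr <- fragment_spec(sample(five_fragments, 1))
    d <- migration_angle(p, fr, model = m)
    expect_gte(d$phi_deg, 25 - 1e-12)
    expect_lte(d$phi_deg, 115 + 1e-12)
  }
  # strict decrease while both effective speeds are positive
  fr <- fragment_spec(2000)
  f_grid <- seq(0, 8, by = 0.5)
  phi <- vapply(f_grid, function(f)
    migration_angle(paper_protocol(f_Hz = f), fr, model = m)$phi_deg, 0)
  v2 <- vapply(f_grid, function(f)
    migration_angle(paper_protocol(f_Hz = f), fr, model = m)$v_eff2_cm_s, 0)
  active <- v2 > 0
  expect_true(all(diff(phi[active]) < 0))
})

test_that("regime classification and its boundaries", {
  expect_identical(classify_regime(0.01, 50, 2.4), "field_dependent_mobility")
  expect_identical(classify_regime(10, 50, 2.4), "switchback_window")
  expect_identical(classify_regime(2.4, 50, 2.4), "switchback_window")
  expect_identical(classify_regime(50, 50, 2.4), "switchback_window")
  expect_identical(classify_regime(60, 50, 2.4), "no_reorientation")
  expect_error(classify_regime(1, 2.4, 50), "f_or_strong > f_or_weak")
})

test_that("fallback above both reorientation frequencies is flagged, not thrown", {
  m <- builtin_mobility_model()
  fr <- fragment_spec(10000)
  d <- migration_angle(paper_protocol(f_Hz = 30), fr, model = m)
  expect_true(d$no_net_motion)
  expect_identical(d$regime, "no_reorientation")
  # ion-limit fallback with per-field mobilities
  ref <- atan2(d$mu1 * 59.5 * sinpi(25/180) + d$mu2 * 22.4 * sinpi(115/180),
               d$mu1 * 59.5 * cospi(25/180) + d$mu2 * 22.4 * cospi(115/180))
  expect_equal(d$phi_deg, ref * 180 / pi)
})

test_that("as-printed convention differs from the vector sum except in trivial cases", {
  p <- paper_protocol(f_Hz = 0)
  fr <- fragment_spec(2000)
  a <- migration_angle(p, fr, mu = c(2.75e-5, 2.75e-5))$phi_deg
  b <- migration_angle(p, fr, mu = c(2.75e-5, 2.75e-5),
                       convention = "as_printed")$phi_deg
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("frequency sweep: shape, degenerate inputs, plateau continuity, CSV", {
  m <- builtin_mobility_model()
  p <- paper_protocol()
  expect_error(frequency_sweep(p, list(), c(1, 2), m), "at least one fragment")
  expect_error(frequency_sweep(p, 2000, c(2, 1), m), "strictly increasing")
  expect_error(frequency_sweep(p, 2000, 3, m), ">= 2 points")

  f_grid <- exp(seq(log(0.016), log(33), length.out = 30))
  sw <- frequency_sweep(p, five_fragments, f_grid, m)
  expect_identical(nrow(sw), length(f_grid) * 5L)
  for (l in five_fragments) {
    s <- sw[sw$length_bp == l & !sw$no_net_motion, ]
    expect_true(all(diff(s$phi_deg) <= 1e-12))  # monotone until fallback
  }

  # two fragments with identical mu at both fields and equal L: same curves
  mpar <- mobility_model_parametric(1e-4, beta = 2e-4)
  fa <- fragment_spec(1500, label = "a")
  fb <- fragment_spec(1500, label = "b")
  sw2 <- frequency_sweep(p, list(fa, fb), c(0.1, 1, 5), mpar)
  expect_equal(sw2$phi_deg[sw2$label == "a"], sw2$phi_deg[sw2$label == "b"])

  # at a vanishing frequency the angular separation equals the f = 0 value
  low <- frequency_sweep(p, c(500, 5000), c(1e-10, 1), m)
  sep_low <- diff(low$phi_deg[low$f_Hz == 1e-10])
  phi0 <- vapply(c(500, 5000), function(l)
    migration_angle(paper_protocol(f_Hz = 0), fragment_spec(l),
                    model = m)$phi_deg, 0)
  expect_lt(abs(abs(sep_low) - abs(diff(phi0))), 1e-9)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, csv)
  back <- read.csv(csv)
  expect_identical(names(back), c("f_Hz", "length_bp", "phi_deg", "regime",
                                  "v_eff1_cm_s", "v_eff2_cm_s"))
  expect_equal(back$phi_deg, sw$phi_deg, tolerance = 1e-12)
})

test_that("fixture mobilities give four streams quasi-statically and five at 2 Hz", {
  m <- builtin_mobility_model()
  phi0 <- vapply(five_fragments, function(l)
    migration_angle(paper_protocol(f_Hz = 0), fragment_spec(l),
                    model = m)$phi_deg, 0)
  # 0.5-5 kbp distinct and ordered, 5 and 10 kbp co-migrating
  expect_true(all(diff(phi0[1:4]) < -1e-6))
  expect_lt(abs(phi0[4] - phi0[5]), 1e-9)
  phi2 <- vapply(five_fragments, function(l)
    migration_angle(paper_protocol(f_Hz = 2), fragment_spec(l),
                    model = m)$phi_deg, 0)
  expect_true(all(diff(phi2) < -1e-6))  # five strictly ordered streams
})
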