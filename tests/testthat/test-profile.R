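test_that("stream profile validation", {
  expect_error(stream_profile(c(1, 1, 2), c(0, 0, 0)), "strictly increasing")
  expect_error(stream_profile(1:3, 1:2), "equal")
  expect_warning(stream_profile(1:3, c(1, -1, 1)), "negative")
})

test_that("image conditioning: constant image, point response, centre preservation", {
  expect_error(process_image(array(0, c(3, 3, 2))), "matrix")
  expect_error(process_image(matrix(0, 3, 3)), "5 x 5")

  # constant image is removed entirely by background subtraction
  expect_true(all(process_image(matrix(7, 16, 16)) == 0))

  # single bright pixel smears into exactly the 5x5 kernel footprint
  m <- matrix(0, 21, 21)
  m[11, 11] <- 1000
  sm <- process_image(m, contrast = FALSE)
  lit <- which(sm > max(sm) * 1e-9, arr.ind = TRUE)
  expect_true(all(abs(lit[, 1] - 11) <= 2 & abs(lit[, 2] - 11) <= 2))
  expect_identical(nrow(lit), 25L)

  # stream centres survive the full chain (contrast stretch is monotone):
  # compare the per-stream intensity maximum of the raw and processed scan
  # line within a window around each known centre
  st <- data.frame(center_um = c(3000, 7000), sigma_um = c(120, 120),
                   amplitude = c(2000, 1500))
  img <- render_image(st, image_shape = c(256, 64), noise = TRUE,
                      noise_seed = 9)
  proc <- process_image(img$image, contrast = TRUE)
  line <- 60
  xline <- (line - 0.5) * img$um_per_px_x
  pk <- fit_peaks(extract_profile(proc, line, averaging_width_px = 1,
                                  um_per_px = img$um_per_px_y), 2)
  ctr_line <- 100 + (st$center_um - 100) * xline / 1e4
  expect_lt(max(abs(pk$center_um - ctr_line)) / img$um_per_px_y, 0.5)
})

test_that("line-profile extraction", {
  m <- matrix(0, 50, 30)
  expect_error(extract_profile(m, 31), "outside")
  expect_true(all(extract_profile(m, 15)$intensities == 0))

  # one Gaussian stream: profile peak within a pixel of ground truth
  st <- data.frame(center_um = 5200, sigma_um = 80, amplitude = 1000)
  img <- render_image(st, image_shape = c(512, 64), noise = FALSE,
                      psf_sigma_px = 0)
  pr <- extract_profile(img, line_position_px = 64, averaging_width_px = 1)
  expect_lt(abs(pr$positions_um[which.max(pr$intensities)] -
                (100 + (5200 - 100) * (63.5 / 64))), 2 * img$um_per_px_y)

  # averaging width 1 vs 5 identical for a stream parallel to the scan axis
  # (flat background: the x gradient would otherwise shift integer rounding)
  flat <- data.frame(center_um = 100, sigma_um = 120, amplitude = 800,
                     injection_y_um = 100)
  img2 <- render_image(flat, image_shape = c(128, 32), noise = FALSE,
                       psf_sigma_px = 0, background = c(100, 0))
  p1 <- extract_profile(img2, 16, averaging_width_px = 1)
  p5 <- extract_profile(img2, 16, averaging_width_px = 5)
  expect_equal(p1$intensities, p5$intensities, tolerance = 1e-12)
})

test_that("multi-Gaussian fitting: exact recovery, noisy recovery, failure modes", {
  x <- seq(0, 2000, by = 5)
  # exact single Gaussian recovered to high relative accuracy
  tru <- list(A = 120, c = 940, s = 55, b = 10)
  pr <- stream_profile(x, tru$b + tru$A * exp(-(x - tru$c)^2 / (2 * tru$s^2)))
  pk <- fit_peaks(pr, 1)
  expect_equal(pk$center_um, tru$c, tolerance = 1e-6)
  expect_equal(pk$sigma_um, tru$s, tolerance = 1e-6)
  expect_equal(pk$amplitude, tru$A, tolerance = 1e-6)
  expect_equal(attr(pk, "baseline"), tru$b, tolerance = 1e-6)

  # two Gaussians 4 sigma apart with 1% noise
  set.seed(77)
  y2 <- 100 * exp(-(x - 800)^2 / (2 * 50^2)) +
        100 * exp(-(x - 1000)^2 / (2 * 50^2))
  y2 <- y2 + rnorm(length(x), 0, 1)
  pk2 <- fit_peaks(stream_profile(x, pmax(y2, 0)), 2)
  expect_equal(pk2$center_um, c(800, 1000), tolerance = 0.1 * 50 / 800)
  expect_equal(pk2$sigma_um, c(50, 50), tolerance = 0.05)

  # degenerate inputs
  expect_error(fit_peaks(stream_profile(1:5, rep(1, 5)), 2),
               "fewer than 3 samples")
  flat <- stream_profile(seq(0, 100, by = 1),
                         c(seq(0, 1, length.out = 51),
                           seq(1, 0, length.out = 50)))
  err <- tryCatch(fit_peaks(flat, 3), error = identity)
  expect_s3_class(err, "pulsegel_fit_error")
  expect_match(conditionMessage(err), "local maxima")
})

test_that("resolution definition and degenerate cases", {
  expect_equal(resolution(list(center_um = 0, sigma_um = 10),
                          list(center_um = 40, sigma_um = 10)), 1)
  expect_equal(resolution(list(center_um = 5, sigma_um = 3),
                          list(center_um = 5, sigma_um = 7)), 0)
  # 5.2 sigma spacing at equal widths: Rs = 1.3
  p <- peaks_with_rs(1.3)
  expect_equal(resolution(p$a, p$b), 1.3)
  expect_error(resolution(list(center_um = 0, sigma_um = 0),
                          list(center_um = 1, sigma_um = 1)), "sigma")
})

test_that("overlap/purity: published worked values, limits, oracle agreement", {
  op <- overlap_purity(c(1.3, 0.6, 1.0, 1.4))
  expect_equal(round(op$purity_percent, 1), c(99.5, 88.5, 97.7, 99.7))
  expect_equal(round(op$overlap_percent, 1)[2], 11.5)
  expect_equal(overlap_purity(0)$overlap_percent, 50)
  expect_identical(op$purity_percent + op$overlap_percent, rep(100, 4))

  rs <- seq(0, 3, by = 0.2)
  ov <- overlap_purity(rs)$overlap_percent
  expect_true(all(diff(ov) < 0))  # strictly decreasing
  # quadrature oracle: misassigned tail of a unit Gaussian at separation 4 Rs
  oracle <- vapply(rs, function(r)
    100 * stats::integrate(dnorm, lower = 2 * r, upper = Inf,
                           rel.tol = 1e-12)$value, 0)
  expect_true(all(abs(ov - oracle) < 1e-6))
})

test_that("recovery from inlet/outlet integrals", {
  # published worked numbers: inlet 2897, outlet sum 2783 -> 96.06%
  inlet <- gauss_profile(2897)
  outs <- list(gauss_profile(1200), gauss_profile(983), gauss_profile(600))
  expect_equal(round(recovery(inlet, outs), 2), 96.06)
  expect_equal(recovery(inlet, inlet), 100, tolerance = 1e-9)
  empty <- stream_profile(seq(0, 100, 1), rep(0, 101))
  expect_equal(recovery(inlet, empty), 0)
  expect_error(recovery(empty, inlet), "zero")
})

test_that("separation reports mirror a published-style purity table", {
  # four synthetic peaks engineered to Rs = {1.3, 0.6, 1.0, 1.4}... needs 5 peaks
  sigma <- 10
  centers <- cumsum(c(0, 4 * sigma * c(1.3, 0.6, 1.0, 1.4)))
  pk <- data.frame(center_um = centers, sigma_um = sigma, amplitude = 1,
                   area = sigma * sqrt(2 * pi))
  class(pk) <- c("peak_set", "data.frame")
  rep5 <- separation_report(pk, chamber = chamber_spec())
  expect_identical(nrow(rep5$pairs), 4L)
  expect_equal(round(rep5$pairs$Rs, 1), c(1.3, 0.6, 1.0, 1.4))
  expect_equal(round(rep5$pairs$purity_pct, 1), c(99.5, 88.5, 97.7, 99.7))
  expect_identical(length(rep5$angles_deg), 5L)

  # two coincident peaks: Rs 0, purity 50
  pk2 <- pk[1:2, ]
  pk2$center_um <- c(100, 100 + 1e-12)
  rep2 <- separation_report(pk2)
  expect_equal(rep2$pairs$Rs, 0, tolerance = 1e-12)
  expect_equal(rep2$pairs$purity_pct, 50, tolerance = 1e-9)

  # JSON serialization carries the documented schema
  js <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep5, js)
  got <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_true(all(c("a", "b", "Rs", "overlap_pct", "purity_pct") %in%
                  names(got$pairs)))
  expect_error(separation_report(pk[1, , drop = FALSE]), "two peaks")
})
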