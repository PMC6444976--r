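#' A 1-D intensity-vs-position stream profile
#'
#' The record read along the collection line: fluorescence (or simulated
#' particle density) against position. Positions must be strictly
#' increasing; negative intensities (possible after baseline subtraction)
#' are flagged with a warning.
#'
#' @param positions_um Strictly increasing positions, um.
#' @param intensities Non-negative intensities, arbitrary units.
#' @param source `"simulated"` or `"image"`.
#' @param baseline Baseline level already present in `intensities`
#'   (subtracted by downstream integrators; default 0).
#' @return A `stream_profile`.
#' @export
stream_profile <- function(positions_um, intensities,
                           source = c("simulated", "image"), baseline = 0) {
  source <- match.arg(source)
  positions_um <- as.numeric(positions_um)
  intensities <- as.numeric(intensities)
  if (length(positions_um) != length(intensities) || !length(positions_um))
    stop_user("positions and intensities must have equal, non-zero length")
  if (any(!is.finite(positions_um)) || any(diff(positions_um) <= 0))
    stop_user("profile positions must be finite and strictly increasing")
  if (any(!is.finite(intensities)))
    stop_user("profile intensities must be finite")
  flagged <- any(intensities < 0)
  if (flagged)
    warning("profile has negative intensities after baseline subtraction")
  .check_number(baseline, "baseline")
  structure(
    list(positions_um = positions_um, intensities = intensities,
         source = source, baseline = baseline, negative_flagged = flagged),
    class = "stream_profile"
  )
}

#' @export
print.stream_profile <- function(x, ...) {
  cat(sprintf("<stream_profile> %d samples over [%g, %g] um (%s), baseline %g\n",
              length(x$positions_um), min(x$positions_um),
              max(x$positions_um), x$source, x$baseline))
  invisible(x)
}

#' Standard image conditioning for fluorescence micrographs
#'
#' The measurement chain applied before profiles are read: (1) the image
#' background, estimated as the per-image median (robust when the bright
#' streams are sparse), is subtracted and the result clipped at zero;
#' (2) noise is reduced with a 5x5 Gaussian kernel (sigma = 1 px);
#' (3) optionally the contrast is stretched linearly, saturating 1% of the
#' pixels at each end (2% total). The stretch is monotone, so peak positions
#' are unaffected, but it rescales intensities: take quantitative profiles
#' with `contrast = FALSE`.
#'
#' @param image Numeric matrix (rows = y), at least 5x5, or a `gel_image`.
#' @param smooth Apply the 5x5 Gaussian filter (default TRUE).
#' @param contrast Apply the 2% linear contrast stretch (default TRUE,
#'   mirroring the full display chain).
#' @return The processed matrix (same shape; stretched output spans
#'   0..65535).
#' @export
process_image <- function(image, smooth = TRUE, contrast = TRUE) {
  if (inherits(image, "gel_image")) image <- image$image
  if (!is.matrix(image) || !is.numeric(image))
    stop_user("process_image expects a 2-D numeric matrix")
  if (nrow(image) < 5 || ncol(image) < 5)
    stop_user("image must be at least 5 x 5 pixels")
  out <- image - median(image)
  out[out < 0] <- 0
  if (isTRUE(smooth)) out <- .gauss_blur(out, sigma_px = 1, size = 5L)
  if (isTRUE(contrast)) {
    lo <- quantile(out, 0.01, names = FALSE)
    hi <- quantile(out, 0.99, names = FALSE)
    if (hi > lo) {
      out <- (out - lo) / (hi - lo)
      out[out < 0] <- 0
      out[out > 1] <- 1
      out <- out * 65535
    } else {
      out[] <- 0
    }
  }
  out
}

#' Extract a line profile from an image
#'
#' Reads intensity against y at a fixed x column (in front of the collection
#' microchannels), averaged over a few columns to suppress pixel noise.
#'
#' @param image Numeric matrix or `gel_image`.
#' @param line_position_px Column index of the scan line; defaults to just
#'   inside the right (collection) edge.
#' @param averaging_width_px Number of columns averaged, centred on the line
#'   (default 5; clipped at the image border).
#' @param um_per_px Pixel pitch along y; taken from a `gel_image`
#'   automatically.
#' @return A [stream_profile()] with `source = "image"`.
#' @export
extract_profile <- function(image, line_position_px = NULL,
                            averaging_width_px = 5, um_per_px = 1) {
  if (inherits(image, "gel_image")) {
    um_per_px <- image$um_per_px_y
    image <- image$image
  }
  if (!is.matrix(image) || !is.numeric(image))
    stop_user("extract_profile expects a 2-D numeric matrix")
  nx <- ncol(image)
  if (is.null(line_position_px))
    line_position_px <- max(nx - ceiling(averaging_width_px / 2), 1L)
  .check_number(line_position_px, "line_position_px")
  if (line_position_px < 1 || line_position_px > nx)
    stop_user("scan line at column ", line_position_px,
              " lies outside the image (1..", nx, ")")
  half <- floor(averaging_width_px / 2)
  cols <- max(1L, line_position_px - half):min(nx, line_position_px + half)
  stream_profile(
    positions_um = (seq_len(nrow(image)) - 0.5) * um_per_px,
    intensities = rowMeans(image[, cols, drop = FALSE]),
    source = "image")
}

#' Multi-Gaussian peak fit of a stream profile
#'
#' Least-squares fit of `n_peaks` Gaussians plus a constant baseline,
#' initialized from the `n_peaks` highest local maxima of the (lightly
#' smoothed) profile. Fitting uses Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) with positivity bounds on amplitudes and widths.
#'
#' @param profile A [stream_profile()].
#' @param n_peaks Number of Gaussians (>= 1); the profile must contain at
#'   least `3 * n_peaks` samples.
#' @return A `peak_set`: data frame with one row per peak (`center_um`,
#'   `sigma_um`, `amplitude`, `area`), sorted by centre, with attributes
#'   `baseline`, `rms` (residual root-mean-square) and `fit`.
#'   Non-convergence raises a condition of class `pulsegel_fit_error`
#'   carrying the optimizer diagnostics; too few local maxima raise an
#'   initialization error.
#' @export
fit_peaks <- function(profile, n_peaks = 1) {
  stopifnot(inherits(profile, "stream_profile"))
  .check_number(n_peaks, "n_peaks", positive = TRUE)
  n_peaks <- as.integer(n_peaks)
  x <- profile$positions_um
  yv <- profile$intensities
  if (length(x) < 3 * n_peaks)
    stop_user("profile has fewer than 3 samples per requested peak")

  ys <- .runmean(yv, 5L)
  base0 <- quantile(ys, 0.1, names = FALSE)
  locmax <- .local_maxima(ys)
  locmax <- locmax[order(ys[locmax], decreasing = TRUE)]
  if (length(locmax) < n_peaks) {
    cond <- structure(
      class = c("pulsegel_fit_error", "pulsegel_user_error", "error",
                "condition"),
      list(message = sprintf(
        "initialization failed: found %d local maxima for %d requested peaks",
        length(locmax), n_peaks), call = NULL))
    stop(cond)
  }
  picks <- sort(locmax[seq_len(n_peaks)])
  dx <- mean(diff(x))
  # parameter vector: b, then (A, c, s) per peak
  start <- max(base0, 0)
  lower <- -Inf
  upper <- Inf
  for (k in seq_len(n_peaks)) {
    i <- picks[k]
    hwhm <- .half_width(x, ys, i, base0)
    start <- c(start, max(ys[i] - base0, .Machine$double.eps), x[i],
               max(hwhm / sqrt(2 * log(2)), dx))
    lower <- c(lower, 0, min(x), dx / 10)
    upper <- c(upper, Inf, max(x), diff(range(x)))
  }
  model_fun <- function(par) {
    out <- rep(par[1], length(x))
    for (k in seq_len(n_peaks)) {
      A <- par[3 * k - 1]; cc <- par[3 * k]; s <- par[3 * k + 1]
      out <- out + A * exp(-(x - cc)^2 / (2 * s^2))
    }
    out
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(par) yv - model_fun(par),
                       control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) e)
  ok <- !inherits(fit, "error") && fit$info %in% 1:4
  if (!ok) {
    cond <- structure(
      class = c("pulsegel_fit_error", "error", "condition"),
      list(message = paste0(
        "peak fit did not converge: ",
        if (inherits(fit, "error")) conditionMessage(fit) else fit$message),
        call = NULL,
        diagnostics = list(start = start, n_peaks = n_peaks,
                           info = if (!inherits(fit, "error")) fit$info)))
    stop(cond)
  }
  cf <- fit$par
  ord <- order(cf[3 * seq_len(n_peaks)])
  ps <- data.frame(
    center_um = cf[3 * seq_len(n_peaks)][ord],
    sigma_um = abs(cf[3 * seq_len(n_peaks) + 1][ord]),
    amplitude = cf[3 * seq_len(n_peaks) - 1][ord])
  ps$area <- ps$amplitude * ps$sigma_um * sqrt(2 * pi)
  attr(ps, "baseline") <- cf[1]
  attr(ps, "rms") <- sqrt(mean(fit$fvec^2))
  attr(ps, "fit") <- fit
  class(ps) <- c("peak_set", "data.frame")
  ps
}

.runmean <- function(v, k) {
  if (length(v) < k) return(v)
  as.numeric(stats::filter(v, rep(1 / k, k), sides = 2)) ->
    s
  s[is.na(s)] <- v[is.na(s)]
  s
}

.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- which(diff(sign(diff(v))) < 0) + 1L
  # flat-topped peaks: keep first index of any plateau that is a maximum
  if (!length(i) && max(v) > min(v)) i <- which.max(v)
  i
}

.half_width <- function(x, y, i, base) {
  half <- base + (y[i] - base) / 2
  r <- i
  while (r < length(y) && y[r] > half) r <- r + 1L
  l <- i
  while (l > 1 && y[l] > half) l <- l - 1L
  max((x[r] - x[l]) / 2, diff(range(x)) / length(x))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s), baseline %.3g, residual RMS %.3g\n",
              nrow(x), attr(x, "baseline"), attr(x, "rms")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Separation resolution between two stream peaks
#'
#' \deqn{R_s = \frac{|\Delta X|}{2\sigma_1 + 2\sigma_2}}
#' with `DeltaX` the distance between the peak centres and `sigma` the
#' Gaussian stream widths. `Rs = 1` corresponds to a 4-sigma centre spacing
#' for equal widths.
#'
#' @param peak_a,peak_b Single peaks: one-row subsets of a `peak_set`, or
#'   any list with `center_um` and `sigma_um`.
#' @return Rs (dimensionless, >= 0).
#' @examples
#' resolution(list(center_um = 0, sigma_um = 10),
#'            list(center_um = 52, sigma_um = 10))  # 1.3
#' @export
resolution <- function(peak_a, peak_b) {
  ca <- .peak_field(peak_a, "center_um"); sa <- .peak_field(peak_a, "sigma_um")
  cb <- .peak_field(peak_b, "center_um"); sb <- .peak_field(peak_b, "sigma_um")
  if (sa <= 0 || sb <= 0) stop_user("resolution requires both sigmas > 0")
  abs(ca - cb) / (2 * sa + 2 * sb)
}

.peak_field <- function(p, field) {
  v <- if (is.data.frame(p)) p[[field]][1] else p[[field]]
  if (!.is_number(v)) stop_user("peak is missing a numeric ", field)
  v
}

#' Gaussian-overlap and purity of adjacent streams at a given resolution
#'
#' Assuming two adjacent streams are equal-width, equal-area Gaussians, a
#' resolution Rs puts their centres `4 Rs sigma` apart; the fraction of one
#' stream's material carried past the midpoint into its neighbour's
#' collection window is the normal survival function at two standard scores,
#' \deqn{\mathrm{overlap} = 100\, Q(2 R_s), \qquad
#'       \mathrm{purity} = 100 - \mathrm{overlap}.}
#' Overlap decreases strictly with Rs; coincident peaks (Rs = 0) give 50%
#' overlap.
#'
#' @param Rs Resolution value(s), >= 0.
#' @return Data frame with columns `Rs`, `overlap_percent`,
#'   `purity_percent` (one row per input value).
#' @examples
#' overlap_purity(c(1.3, 0.6, 1.0, 1.4))
#' @export
overlap_purity <- function(Rs) {
  if (!is.numeric(Rs) || !length(Rs) || any(!is.finite(Rs)) || any(Rs < 0))
    stop_user("Rs must be finite and >= 0")
  ov <- 100 * pnorm(2 * Rs, lower.tail = FALSE)
  data.frame(Rs = Rs, overlap_percent = ov, purity_percent = 100 - ov)
}

#' DNA recovery from inlet and outlet stream profiles
#'
#' Integrates the baseline-subtracted fluorescence over each stream's fitted
#' +/- 3 sigma window (trapezoidal rule) at the inlet and at the outlet(s),
#' and reports
#' `100 * sum(outlet integrals) / inlet integral`. An outlet profile with no
#' signal above baseline contributes zero; a zero inlet integral is a domain
#' error.
#'
#' @param inlet_profile A [stream_profile()] of the injected band.
#' @param outlet_profiles A [stream_profile()] or list of them, one per
#'   collected stream (or one profile spanning several streams, see
#'   `n_outlet_peaks`).
#' @param n_outlet_peaks Number of Gaussians fitted per outlet profile
#'   (default 1).
#' @return Recovery in percent.
#' @examples
#' g <- function(area) {
#'   x <- seq(-300, 300, by = 2)
#'   stream_profile(x, area * dnorm(x, 0, 40))
#' }
#' recovery(g(2897), g(2783))  # 96.06
#' @export
recovery <- function(inlet_profile, outlet_profiles, n_outlet_peaks = 1) {
  stopifnot(inherits(inlet_profile, "stream_profile"))
  if (inherits(outlet_profiles, "stream_profile"))
    outlet_profiles <- list(outlet_profiles)
  if (!length(outlet_profiles) ||
      !all(vapply(outlet_profiles, inherits, TRUE, "stream_profile")))
    stop_user("outlet_profiles must be stream_profile objects")
  inlet_int <- .stream_integral(inlet_profile, 1)
  if (inlet_int <= 0)
    stop_user("inlet profile integrates to zero; recovery is undefined")
  outlet_int <- sum(vapply(outlet_profiles, .stream_integral, 0,
                           n_peaks = n_outlet_peaks))
  100 * outlet_int / inlet_int
}

# Baseline-subtracted trapezoidal integral over the union of the fitted
# +/- 3 sigma windows.
.stream_integral <- function(profile, n_peaks = 1) {
  y <- profile$intensities - profile$baseline
  if (all(y <= 0)) return(0)
  pk <- fit_peaks(profile, n_peaks = n_peaks)
  keep <- rep(FALSE, length(y))
  # widen by half a grid step so a sample sitting exactly on the 3-sigma
  # boundary is included regardless of floating-point rounding of the centre
  half_dx <- median(diff(profile$positions_um)) / 2
  for (k in seq_len(nrow(pk)))
    keep <- keep |
      (profile$positions_um >= pk$center_um[k] - 3 * pk$sigma_um[k] - half_dx &
       profile$positions_um <= pk$center_um[k] + 3 * pk$sigma_um[k] + half_dx)
  if (sum(keep) < 2) return(0)
  pracma::trapz(profile$positions_um[keep], pmax(y[keep], 0))
}

#' Assemble a separation report from fitted stream peaks
#'
#' Computes resolution, Gaussian-overlap and purity for every adjacent pair
#' of peaks (streams sorted by position), plus overall recovery when inlet
#' and outlet profiles are supplied, and per-stream deflection angles when
#' the chamber geometry is given.
#'
#' @param peaks A `peak_set` with >= 2 peaks, or a list of
#'   [stream_profile()]s (each is fitted with a single Gaussian first).
#' @param inlet_profile,outlet_profiles Optional profiles for [recovery()].
#' @param chamber Optional [chamber_spec()]; when given, each stream's
#'   deflection angle `atan((center - injection_y)/width)` is reported.
#' @param labels Optional stream labels (default: peak index).
#' @return A `separation_report`: `pairs` data frame
#'   (`a`, `b`, `Rs`, `overlap_pct`, `purity_pct`), `recovery_pct` (or NA),
#'   `angles_deg` (or NULL). Values are stored at full precision; printing
#'   rounds Rs and purity to 1 decimal and overlap to 2.
#' @export
separation_report <- function(peaks, inlet_profile = NULL,
                              outlet_profiles = NULL, chamber = NULL,
                              labels = NULL) {
  if (is.list(peaks) && !is.data.frame(peaks) &&
      all(vapply(peaks, inherits, TRUE, "stream_profile"))) {
    if (is.null(outlet_profiles)) outlet_profiles <- peaks
    fitted <- lapply(peaks, fit_peaks, n_peaks = 1)
    peaks <- do.call(rbind, lapply(fitted, function(p) as.data.frame(p)))
    class(peaks) <- c("peak_set", "data.frame")
  }
  if (!is.data.frame(peaks) || nrow(peaks) < 2)
    stop_user("separation_report needs at least two peaks")
  ord <- order(peaks$center_um)
  peaks <- peaks[ord, , drop = FALSE]
  if (is.null(labels)) {
    labels <- if (!is.null(peaks$label)) as.character(peaks$label)
              else as.character(seq_len(nrow(peaks)))
  } else {
    labels <- as.character(labels)[ord]
  }
  n <- nrow(peaks)
  rs <- vapply(seq_len(n - 1), function(i)
    resolution(peaks[i, ], peaks[i + 1, ]), 0)
  op <- overlap_purity(rs)
  pairs <- data.frame(a = labels[-n], b = labels[-1], Rs = rs,
                      overlap_pct = op$overlap_percent,
                      purity_pct = op$purity_percent,
                      stringsAsFactors = FALSE)
  rec <- if (!is.null(inlet_profile) && !is.null(outlet_profiles))
    recovery(inlet_profile, outlet_profiles) else NA_real_
  ang <- if (!is.null(chamber)) {
    .rad2deg(atan2(peaks$center_um * 1e-4 - chamber$injection_y_cm,
                   chamber$width_cm))
  } else NULL
  structure(
    list(pairs = pairs, recovery_pct = rec, angles_deg = ang,
         peaks = peaks),
    class = "separation_report"
  )
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report>\n")
  shown <- data.frame(
    pair = paste(x$pairs$a, "vs", x$pairs$b),
    Rs = round(x$pairs$Rs, 1),
    overlap_pct = round(x$pairs$overlap_pct, 2),
    purity_pct = round(x$pairs$purity_pct, 1))
  print(shown, row.names = FALSE)
  if (!is.na(x$recovery_pct))
    cat(sprintf("recovery: %.2f%%\n", x$recovery_pct))
  if (!is.null(x$angles_deg))
    cat("deflection angles (deg):",
        paste(sprintf("%.2f", x$angles_deg), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a separation report as JSON
#'
#' Schema: `pairs: [{a, b, Rs, overlap_pct, purity_pct}], recovery_pct,
#' angles_deg`.
#'
#' @param report A `separation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "separation_report"))
  jsonlite::write_json(
    list(pairs = report$pairs, recovery_pct = report$recovery_pct,
         angles_deg = report$angles_deg),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
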