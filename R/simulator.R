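#' Separation-chamber geometry
#'
#' The gel-filled chamber is a square slab; fragments are injected as a
#' narrow band on the left edge and collected along the right edge, where a
#' microchannel array samples the streams. Coordinates follow the package
#' convention (x toward the collection edge, y along the collection line).
#'
#' @param width_cm,height_cm Chamber extent in cm (defaults 1 x 1).
#' @param injection_y_cm y position of the injection band centre, cm.
#' @param injection_band_width_um Width of the injected band, um
#'   (default 110). Must be small compared to the chamber height.
#' @param collection_edge Boundary that terminates trajectories; only
#'   `"x_max"` (the right edge, x = width) is supported.
#' @return A `chamber_spec` object.
#' @export
chamber_spec <- function(width_cm = 1, height_cm = 1, injection_y_cm = 0.01,
                         injection_band_width_um = 110,
                         collection_edge = "x_max") {
  .check_number(width_cm, "width_cm", positive = TRUE)
  .check_number(height_cm, "height_cm", positive = TRUE)
  .check_number(injection_y_cm, "injection_y_cm")
  .check_number(injection_band_width_um, "injection_band_width_um",
                positive = TRUE)
  if (injection_y_cm < 0 || injection_y_cm > height_cm)
    stop_user("injection_y_cm must lie within [0, height_cm]")
  if (injection_band_width_um * 1e-4 >= height_cm)
    stop_user("injection band must be much narrower than the chamber height")
  if (!identical(collection_edge, "x_max"))
    stop_user('only collection_edge = "x_max" is supported')
  structure(
    list(width_cm = width_cm, height_cm = height_cm,
         injection_y_cm = injection_y_cm,
         injection_band_width_um = injection_band_width_um,
         collection_edge = collection_edge),
    class = "chamber_spec"
  )
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf(
    "<chamber_spec> %g x %g cm, injection band %g um at y = %g cm\n",
    x$width_cm, x$height_cm, x$injection_band_width_um, x$injection_y_cm))
  invisible(x)
}

#' Stochastic sawtooth simulation of fragment streams
#'
#' Particles are injected at x = 0 with y drawn from a top-hat of the
#' injection band width, then advanced half-cycle by half-cycle: at each field
#' switch a fragment first sits through its reorientation dead time
#' `min(t_or, half-period)` with zero net displacement, then migrates in a
#' straight line at `mu_i E_i` along the field direction. This dead-time model
#' reproduces the `-2fL` reorientation loss of the closed-form migration angle
#' exactly. Optional isotropic diffusion adds a Gaussian kick of variance
#' `2 D dt` per coordinate and half-cycle. A trajectory terminates at its
#' first crossing of the collection edge (x = chamber width); the crossing y
#' is interpolated within the straight segment.
#'
#' By default each particle starts at a uniformly random phase of the
#' switching period (`random_phase`), which removes phase-locking artifacts
#' from the exit positions; with `random_phase = FALSE` every particle starts
#' at the beginning of a field-1 half-cycle. `f = 0` is the quasi-static
#' limit: straight-line motion along the duty-weighted mean velocity.
#'
#' Particles at the left edge are clamped to x >= 0 (the gel boundary): a
#' retrograde weak-field leg cannot push a particle out of the injection
#' edge. For near-45-degree streams the nominal chamber height may be
#' slightly overrun near the collection edge; trajectories are terminated
#' only at the collection edge, mirroring a device whose exit channel array
#' spans the full edge.
#'
#' @param protocol A [field_protocol()].
#' @param fragments Fragments to simulate (list of [fragment_spec()] or bp).
#' @param chamber A [chamber_spec()].
#' @param model Mobility model (see [builtin_mobility_model()]).
#' @param n_particles Particles per fragment (>= 1).
#' @param seed Mandatory RNG seed; identical seeds give bit-identical output.
#' @param diffusion_coeff Isotropic diffusion coefficient D, cm^2/s
#'   (default 0: band broadening is injection-width plus sawtooth dominated).
#' @param random_phase Randomize the starting phase (default when
#'   `n_particles > 1`).
#' @param log_trajectories Keep per-half-cycle positions for the first few
#'   particles (disables the fast multi-period stepping).
#' @param max_periods Safety cap on simulated switching periods.
#'
#' @return A `stream_simulation` with `$samples` (one row per particle:
#'   `length_bp`, `label`, `y0_cm`, `y_exit_cm`, `angle_deg`, `collected`),
#'   `$per_fragment` summaries (mean/sd of exit position, mean angle and its
#'   standard error, counts, optional trajectory log), and the run inputs.
#' @examples
#' sim <- simulate_streams(
#'   field_protocol(59.5, 22.4, 25, 115, f_Hz = 2),
#'   fragments = c(2000, 10000), chamber = chamber_spec(),
#'   model = builtin_mobility_model(), n_particles = 200, seed = 1)
#' sim$per_fragment[["2 kbp"]]$angle_mean_deg
#' @export
simulate_streams <- function(protocol, fragments, chamber = chamber_spec(),
                             model = builtin_mobility_model(),
                             n_particles = 1000, seed,
                             diffusion_coeff = 0,
                             random_phase = n_particles > 1,
                             log_trajectories = FALSE,
                             max_periods = 1e6) {
  stopifnot(inherits(protocol, "field_protocol"),
            inherits(chamber, "chamber_spec"))
  fragments <- .as_fragment_list(fragments)
  if (!length(fragments)) stop_user("simulate_streams needs at least one fragment")
  .check_number(n_particles, "n_particles", positive = TRUE)
  .check_number(diffusion_coeff, "diffusion_coeff", nonneg = TRUE)
  if (missing(seed) || is.null(seed))
    stop_user("seed is mandatory for stochastic runs")
  .check_number(seed, "seed")
  set.seed(as.integer(seed))
  per <- lapply(fragments, function(fr)
    .simulate_fragment(protocol, fr, chamber, model, n_particles,
                       diffusion_coeff, random_phase, log_trajectories,
                       max_periods))
  names(per) <- vapply(fragments, `[[`, "", "label")
  samples <- do.call(rbind, lapply(per, `[[`, "samples"))
  rownames(samples) <- NULL
  structure(
    list(samples = samples, per_fragment = per, protocol = protocol,
         chamber = chamber, n_particles = n_particles, seed = seed,
         diffusion_coeff = diffusion_coeff, random_phase = random_phase),
    class = "stream_simulation"
  )
}

#' @export
print.stream_simulation <- function(x, ...) {
  cat(sprintf("<stream_simulation> %d fragment(s) x %d particles, f = %g Hz, seed = %g\n",
              length(x$per_fragment), x$n_particles, x$protocol$f_Hz, x$seed))
  for (nm in names(x$per_fragment)) {
    p <- x$per_fragment[[nm]]
    cat(sprintf("  %-8s exit y = %8.1f +/- %5.1f um   angle = %6.2f deg   collected %d/%d\n",
                nm, p$exit_mean_cm * 1e4, p$exit_sd_cm * 1e4,
                p$angle_mean_deg, p$n_collected,
                p$n_collected + p$n_in_chamber))
  }
  invisible(x)
}

# One fragment's particle ensemble. Vectorized over particles; when no
# trajectory log is requested, whole switching periods are jumped in blocks
# (the per-period displacement is the same for every particle once the first,
# phase-dependent partial period has been stepped).
.simulate_fragment <- function(protocol, fr, chamber, model, n, D,
                               random_phase, log_traj, max_periods) {
  W <- chamber$width_cm
  mu1 <- evaluate_mobility(model, protocol$E1, fr)
  mu2 <- evaluate_mobility(model, protocol$E2, fr)
  u1 <- mu1 * protocol$E1
  u2 <- mu2 * protocol$E2
  L <- fr$contour_length_cm
  th1 <- .deg2rad(protocol$theta1_deg)
  th2 <- .deg2rad(protocol$theta2_deg)
  c1 <- cos(th1); s1 <- sin(th1)
  c2 <- cos(th2); s2 <- sin(th2)
  f <- protocol$f_Hz
  duty <- protocol$duty

  wb <- chamber$injection_band_width_um * 1e-4
  y0 <- chamber$injection_y_cm + runif(n, -wb / 2, wb / 2)
  x <- numeric(n)
  y <- y0
  done <- logical(n)
  ye <- rep(NA_real_, n)

  n_log <- if (log_traj) min(n, 20L) else 0L
  traj <- if (n_log > 0) list(cbind(step = 0, particle = seq_len(n_log),
                                    x_cm = x[seq_len(n_log)],
                                    y_cm = y[seq_len(n_log)])) else NULL
  step_id <- 0L

  record <- function() {
    if (n_log > 0) {
      step_id <<- step_id + 1L
      traj[[length(traj) + 1L]] <<- cbind(step = step_id,
                                          particle = seq_len(n_log),
                                          x_cm = x[seq_len(n_log)],
                                          y_cm = y[seq_len(n_log)])
    }
  }

  # advance active particles by (dx, dy) over durations dt (vectors or
  # scalars), detect first crossings of x = W, clamp at the injection edge
  advance <- function(dx, dy, dt) {
    act <- !done
    if (!any(act)) return(invisible())
    dx <- rep_len(dx, n)[act]
    dy <- rep_len(dy, n)[act]
    if (D > 0) {
      dt <- rep_len(dt, n)[act]
      sdv <- sqrt(2 * D * pmax(dt, 0))
      dx <- dx + rnorm(sum(act), 0, sdv)
      dy <- dy + rnorm(sum(act), 0, sdv)
    }
    xn <- x[act] + dx
    yn <- y[act] + dy
    cross <- xn >= W & dx > 0
    if (any(cross)) {
      frac <- (W - x[act][cross]) / dx[cross]
      yex <- y[act][cross] + frac * dy[cross]
      idx <- which(act)[cross]
      ye[idx] <<- yex
      done[idx] <<- TRUE
      x[idx] <<- W
      y[idx] <<- yex
    }
    keep <- which(act)[!cross]
    x[keep] <<- pmax(xn[!cross], 0)  # gel boundary at the injection edge
    y[keep] <<- yn[!cross]
    record()
    invisible()
  }

  if (f == 0) {
    # quasi-static limit: straight motion at the duty-weighted mean velocity
    Vx <- duty * u1 * c1 + (1 - duty) * u2 * c2
    Vy <- duty * u1 * s1 + (1 - duty) * u2 * s2
    if (Vx <= 0 && D == 0)
      stop_user("no transport: quasi-static drift does not point toward the collection edge and diffusion is off")
    if (Vx > 0) {
      t_cross <- W / Vx
      yex <- y0 + Vy * t_cross
      if (D > 0) yex <- yex + rnorm(n, 0, sqrt(2 * D * t_cross))
      ye <- yex
      done <- rep(TRUE, n)
      x <- rep(W, n)
      y <- ye
      record()
    }
  } else {
    h1 <- duty / f
    h2 <- (1 - duty) / f
    Tper <- 1 / f
    tor1 <- if (L > 0) L / u1 else 0
    tor2 <- if (L > 0) L / u2 else 0
    m1 <- u1 * max(h1 - tor1, 0)  # strong-field path length per period
    m2 <- u2 * max(h2 - tor2, 0)
    dxp <- m1 * c1 + m2 * c2
    dyp <- m1 * s1 + m2 * s2
    if (m1 == 0 && m2 == 0 && D == 0)
      stop_user("no transport: switching frequency exceeds both reorientation frequencies and diffusion is off")
    if (dxp <= 0 && D == 0)
      stop_user("no transport: net per-period displacement does not point toward the collection edge and diffusion is off")

    # initial, phase-dependent partial period
    ph <- if (random_phase) runif(n, 0, Tper) else numeric(n)
    in1 <- ph < h1
    mv1 <- ifelse(in1, u1 * pmax(h1 - pmax(ph, tor1), 0), 0)
    dt1 <- ifelse(in1, h1 - ph, 0)
    advance(mv1 * c1, mv1 * s1, dt1)
    a2 <- ifelse(in1, 0, ph - h1)
    mv2 <- u2 * pmax(h2 - pmax(a2, tor2), 0)
    advance(mv2 * c2, mv2 * s2, h2 - a2)

    margin <- m1 * abs(c1) + m2 * abs(c2) + 1e-9
    periods <- 1
    while (any(!done) && periods < max_periods) {
      jumped <- FALSE
      if (n_log == 0 && dxp > 0) {
        avail <- W - margin - max(x[!done])
        k <- floor(avail / dxp)
        if (D > 0 && k > 1)
          k <- floor((avail - 6 * sqrt(2 * D * k * Tper)) / dxp)
        k <- min(k, max_periods - periods)
        if (k >= 2) {
          act <- !done
          nn <- sum(act)
          nx <- if (D > 0) rnorm(nn, 0, sqrt(2 * D * k * Tper)) else 0
          ny <- if (D > 0) rnorm(nn, 0, sqrt(2 * D * k * Tper)) else 0
          x[act] <- pmax(pmin(x[act] + k * dxp + nx, W * (1 - 1e-12)), 0)
          y[act] <- y[act] + k * dyp + ny
          periods <- periods + k
          jumped <- TRUE
        }
      }
      if (!jumped) {
        advance(m1 * c1, m1 * s1, h1)
        advance(m2 * c2, m2 * s2, h2)
        periods <- periods + 1
      }
    }
  }

  angle <- .rad2deg(atan2(ye - y0, W))
  samples <- data.frame(
    length_bp = fr$length_bp, label = fr$label, y0_cm = y0,
    y_exit_cm = ye, angle_deg = angle, collected = done,
    stringsAsFactors = FALSE)
  ok <- samples$collected
  list(
    fragment = fr, samples = samples,
    n_collected = sum(ok), n_in_chamber = sum(!ok),
    exit_mean_cm = if (any(ok)) mean(ye[ok]) else NA_real_,
    exit_sd_cm = if (sum(ok) > 1) sd(ye[ok]) else NA_real_,
    angle_mean_deg = if (any(ok)) mean(angle[ok]) else NA_real_,
    angle_se_deg = if (sum(ok) > 1) sd(angle[ok]) / sqrt(sum(ok)) else NA_real_,
    positions = cbind(x_cm = x, y_cm = y),
    trajectory = if (!is.null(traj)) as.data.frame(do.call(rbind, traj)) else NULL,
    mu1 = mu1, mu2 = mu2)
}

#' Per-period transverse excursion of the sawtooth trajectory
#'
#' At low switching frequency a fragment's path is a long-period zig-zag; the
#' transverse distance covered within one period no longer averages out at
#' the band scale and becomes the dominant field-protocol contribution to
#' band broadening. It is quantified by
#' \deqn{L_{fr} = \frac{\mu_2 E_2}{2 f}\,(\tan\theta_1\cos\theta_2 + \sin\theta_2),}
#' the vertical-axis distance travelled per switching period (reported as a
#' magnitude). Halving `f` doubles `L_fr`, which is why very low frequencies
#' broaden the streams.
#'
#' @param protocol A [field_protocol()] with `f_Hz > 0`.
#' @param mobility_2 Mobility in the weak field E2, cm^2/(V s).
#' @param fragment A [fragment_spec()] or bp (used only for validation /
#'   reporting; the excursion itself is set by the weak-field drift).
#' @param injection_band_width_um Reference band width for the
#'   `fraction_of_injection` field (default 110 um).
#' @return A `broadening_result`: `L_fr_um` (>= 0) and
#'   `fraction_of_injection`.
#' @export
band_broadening_excursion <- function(protocol, mobility_2, fragment = NULL,
                                      injection_band_width_um = 110) {
  stopifnot(inherits(protocol, "field_protocol"))
  .check_number(mobility_2, "mobility_2", positive = TRUE)
  .check_number(injection_band_width_um, "injection_band_width_um",
                positive = TRUE)
  if (protocol$f_Hz <= 0)
    stop_user("band_broadening_excursion requires f > 0")
  th1 <- .deg2rad(protocol$theta1_deg)
  th2 <- .deg2rad(protocol$theta2_deg)
  if (abs(cos(th1)) < 1e-12)
    stop_user("theta1 = 90 deg makes the excursion singular (tan theta1)")
  if (!is.null(fragment)) fragment <- .as_fragment(fragment)
  L_fr_cm <- abs(0.5 * mobility_2 * protocol$E2 / protocol$f_Hz *
                   (tan(th1) * cos(th2) + sin(th2)))
  structure(
    list(L_fr_um = L_fr_cm * 1e4,
         fraction_of_injection = L_fr_cm * 1e4 / injection_band_width_um,
         fragment = fragment, protocol = protocol),
    class = "broadening_result"
  )
}

#' @export
print.broadening_result <- function(x, ...) {
  cat(sprintf("<broadening_result> L_fr = %.1f um (%.0f%% of the injection band)\n",
              x$L_fr_um, 100 * x$fraction_of_injection))
  invisible(x)
}

#' Histogram a set of exit positions into a stream profile
#'
#' Bins exit y positions on a fixed grid and normalizes by the total particle
#' count, mimicking a fluorescence line profile read at the collection line.
#'
#' @param exit_samples Exit positions. Either a numeric vector in um, or a
#'   `stream_simulation` (all collected particles of all fragments pooled,
#'   as on a real collection line).
#' @param bin_width_um Histogram bin width, um (default 10).
#' @param range_um Optional `c(lo, hi)` grid range in um; defaults to the
#'   chamber height for a simulation input, or the padded data range.
#' @return A [stream_profile()] with `positions` at bin centres (um) and
#'   `intensities` summing to the collected fraction.
#' @export
exit_profile <- function(exit_samples, bin_width_um = 10, range_um = NULL) {
  .check_number(bin_width_um, "bin_width_um", positive = TRUE)
  if (inherits(exit_samples, "stream_simulation")) {
    if (is.null(range_um))
      range_um <- c(0, exit_samples$chamber$height_cm * 1e4)
    total <- nrow(exit_samples$samples)
    yy <- exit_samples$samples$y_exit_cm * 1e4
    yy <- yy[!is.na(yy)]
  } else {
    yy <- as.numeric(exit_samples)
    yy <- yy[!is.na(yy)]
    total <- length(yy)
  }
  if (!length(yy)) stop_user("exit_profile needs at least one collected sample")
  if (is.null(range_um))
    range_um <- range(yy) + c(-2, 2) * bin_width_um
  breaks <- seq(floor(range_um[1] / bin_width_um) * bin_width_um,
                ceiling(range_um[2] / bin_width_um) * bin_width_um,
                by = bin_width_um)
  if (min(yy) < breaks[1] || max(yy) > breaks[length(breaks)])
    breaks <- seq(floor(min(yy) / bin_width_um) * bin_width_um,
                  ceiling(max(yy) / bin_width_um) * bin_width_um + bin_width_um,
                  by = bin_width_um)
  counts <- tabulate(findInterval(yy, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  stream_profile(positions_um = breaks[-length(breaks)] + bin_width_um / 2,
                 intensities = counts / total, source = "simulated")
}
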