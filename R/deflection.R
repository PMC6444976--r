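#' Alternating two-field protocol
#'
#' The drive applied to the separation chamber: two transverse fields of
#' magnitudes `E1 >= E2` at angles `theta1`, `theta2` from the x axis,
#' switched at frequency `f`. By convention field 1 is the strong field.
#'
#' @param E1,E2 Field magnitudes in V/cm; `E1 >= E2 > 0`.
#' @param theta1_deg,theta2_deg Field angles from the x axis, degrees
#'   (counterclockwise).
#' @param f_Hz Switching frequency in Hz; `f = 0` denotes the quasi-static
#'   limit in which each field is applied long enough that reorientation lag
#'   is negligible.
#' @param duty Fraction of each period spent in field 1; default 0.5
#'   (symmetric alternation).
#'
#' @return An object of class `field_protocol`.
#' @examples
#' field_protocol(59.5, 22.4, 25, 115, f_Hz = 2)
#' @export
field_protocol <- function(E1, E2, theta1_deg, theta2_deg, f_Hz = 0,
                           duty = 0.5) {
  .check_number(E1, "E1", positive = TRUE)
  .check_number(E2, "E2", positive = TRUE)
  if (E1 < E2)
    stop_user("field protocol requires E1 >= E2 > 0 ",
              "(field 1 is the strong field by convention); got E1 = ",
              E1, ", E2 = ", E2)
  .check_number(theta1_deg, "theta1_deg")
  .check_number(theta2_deg, "theta2_deg")
  .check_number(f_Hz, "f_Hz", nonneg = TRUE)
  .check_number(duty, "duty")
  if (duty <= 0 || duty >= 1) stop_user("duty must lie strictly between 0 and 1")
  structure(
    list(E1 = E1, E2 = E2, theta1_deg = theta1_deg, theta2_deg = theta2_deg,
         f_Hz = f_Hz, duty = duty),
    class = "field_protocol"
  )
}

#' @export
print.field_protocol <- function(x, ...) {
  cat(sprintf(
    "<field_protocol> E1 = %g V/cm @ %g deg | E2 = %g V/cm @ %g deg | f = %g Hz, duty = %g\n",
    x$E1, x$theta1_deg, x$E2, x$theta2_deg, x$f_Hz, x$duty))
  invisible(x)
}

#' Effective migration speed in one field of a switched protocol
#'
#' During each half period a fragment first spends the reorientation time
#' `t_or = L/(mu E)` realigning (no net progress), then migrates at `mu E`.
#' Averaged over a symmetric half period this gives the reorientation-
#' penalized speed
#' \deqn{v_{eff} = \max(\mu E - 2 f L,\; 0).}
#' The clamp at zero encodes the switchback regime: once `f` exceeds the
#' field's reorientation frequency `f_or = mu E/(2L)` the fragment never
#' finishes realigning and that field contributes no displacement.
#'
#' @param mobility Mobility in this field, cm^2/(V s) (> 0).
#' @param E Field magnitude, V/cm (> 0).
#' @param f Switching frequency, Hz (>= 0).
#' @param fragment A [fragment_spec()] or length in bp.
#' @return Speed in cm/s.
#' @export
effective_velocity <- function(mobility, E, f, fragment) {
  .check_number(mobility, "mobility", positive = TRUE)
  .check_number(E, "E", positive = TRUE)
  .check_number(f, "f", nonneg = TRUE)
  fragment <- .as_fragment(fragment)
  max(mobility * E - 2 * f * fragment$contour_length_cm, 0)
}

# per-period displacement weights d_i = max(duty_i * mu_i E_i - f L, 0)
# (for duty = 0.5 this is 0.5 * v_eff_i, so the angle is unchanged)
.duty_weights <- function(mu1, mu2, protocol, L) {
  f <- protocol$f_Hz
  d1 <- protocol$duty
  d2 <- 1 - protocol$duty
  c(max(d1 * mu1 * protocol$E1 - f * L, 0),
    max(d2 * mu2 * protocol$E2 - f * L, 0))
}

#' Migration angle of a DNA fragment under an alternating field protocol
#'
#' The net trajectory direction from the time-weighted vector sum of the two
#' per-field displacements, each penalized by the reorientation dead time:
#' \deqn{\Phi = \mathrm{atan2}\big(v_1 \sin\theta_1 + v_2\sin\theta_2,\;
#'                                 v_1 \cos\theta_1 + v_2\cos\theta_2\big)}
#' with \eqn{v_i = \max(\mu_i E_i - 2 f L, 0)} (see
#' [effective_velocity()]; for `duty != 0.5` the weights generalize to
#' `max(duty_i mu_i E_i - f L, 0)`). The two-argument arctangent (plus-sign
#' vector sum) is used because it reduces exactly to the non-reptating ion
#' limit [ion_angle()] when `f = 0` and `mu1 = mu2`; the historical
#' minus-denominator variant of the formula is available via
#' `convention = "as_printed"` for comparison only.
#'
#' When the weak-field speed clamps to zero the fragment follows the strong
#' field exactly (`phi = theta1`). When both speeds clamp (f above both
#' reorientation frequencies) the dead-time model predicts no motion; the
#' result is then flagged `no_net_motion` and the reported angle falls back to
#' the time-averaged ion-limit direction computed with the per-field
#' mobilities, on the rationale that a never-reorienting coil responds to the
#' time-averaged force.
#'
#' @param protocol A [field_protocol()].
#' @param fragment A [fragment_spec()] or length in bp.
#' @param model A [mobility_model_parametric()]/[mobility_model_table()];
#'   ignored if `mu` is given.
#' @param mu Optional explicit mobilities `c(mu1, mu2)` at `E1` and `E2`,
#'   bypassing the model.
#' @param convention `"vector_sum"` (default) or `"as_printed"`.
#'
#' @return A `deflection_result`: `phi_deg`, `v_eff1_cm_s`, `v_eff2_cm_s`,
#'   `regime` (one of `field_dependent_mobility`, `switchback_window`,
#'   `no_reorientation`), `no_net_motion` flag, plus the inputs.
#' @examples
#' p <- field_protocol(59.5, 22.4, 25, 115, f_Hz = 0)
#' migration_angle(p, fragment_spec(2000), mu = c(2.75e-5, 2.75e-5))$phi_deg
#' @export
migration_angle <- function(protocol, fragment, model = NULL, mu = NULL,
                            convention = c("vector_sum", "as_printed")) {
  convention <- match.arg(convention)
  stopifnot(inherits(protocol, "field_protocol"))
  fragment <- .as_fragment(fragment)
  if (is.null(mu)) {
    if (is.null(model))
      stop_user("migration_angle needs a mobility model or explicit mu = c(mu1, mu2)")
    mu1 <- evaluate_mobility(model, protocol$E1, fragment)
    mu2 <- evaluate_mobility(model, protocol$E2, fragment)
  } else {
    if (length(mu) != 2 || any(mu <= 0))
      stop_user("mu must be two positive mobilities c(mu1, mu2)")
    mu1 <- mu[1]
    mu2 <- mu[2]
  }
  L <- fragment$contour_length_cm
  f <- protocol$f_Hz
  th1 <- .deg2rad(protocol$theta1_deg)
  th2 <- .deg2rad(protocol$theta2_deg)

  v1 <- effective_velocity(mu1, protocol$E1, f, fragment)
  v2 <- effective_velocity(mu2, protocol$E2, f, fragment)
  w <- .duty_weights(mu1, mu2, protocol, L)

  # regime from the two reorientation frequencies (strong field first)
  if (L > 0) {
    f_or <- sort(c(mu1 * protocol$E1, mu2 * protocol$E2) / (2 * L),
                 decreasing = TRUE)
    regime <- if (f_or[1] > f_or[2]) {
      classify_regime(f, f_or[1], f_or[2])
    } else {
      # both fields share one reorientation frequency (e.g. E1 = E2, mu1 = mu2)
      if (f < f_or[2]) "field_dependent_mobility"
      else if (f <= f_or[1]) "switchback_window"
      else "no_reorientation"
    }
  } else {
    regime <- "field_dependent_mobility"  # point-like: no reorientation lag
  }

  no_net_motion <- all(w == 0)
  if (no_net_motion) {
    # ion-limit fallback: time-averaged drift ignoring the dead-time model
    w <- c(protocol$duty * mu1 * protocol$E1,
           (1 - protocol$duty) * mu2 * protocol$E2)
  }

  phi <- if (convention == "vector_sum" || no_net_motion) {
    if (w[2] == 0 && w[1] > 0) th1         # weak-field clamp: exactly theta1
    else if (w[1] == 0 && w[2] > 0) th2
    else atan2(w[1] * sin(th1) + w[2] * sin(th2),
               w[1] * cos(th1) + w[2] * cos(th2))
  } else {
    if (v1 <= 0) stop_user("as_printed convention is undefined when the strong-field speed clamps to zero")
    rho <- v2 / v1
    atan((sin(th1) + rho * sin(th2)) / (cos(th1) - rho * cos(th2)))
  }

  structure(
    list(phi_deg = .rad2deg(phi), v_eff1_cm_s = v1, v_eff2_cm_s = v2,
         regime = regime, no_net_motion = no_net_motion,
         mu1 = mu1, mu2 = mu2, fragment = fragment, protocol = protocol,
         convention = convention),
    class = "deflection_result"
  )
}

#' @export
print.deflection_result <- function(x, ...) {
  cat(sprintf(
    "<deflection_result> %s: phi = %.2f deg [%s]%s  v_eff = (%.3g, %.3g) cm/s\n",
    x$fragment$label, x$phi_deg, x$regime,
    if (x$no_net_motion) " (no net motion; ion-limit fallback)" else "",
    x$v_eff1_cm_s, x$v_eff2_cm_s))
  invisible(x)
}

#' Migration angle of non-reptating ionic species
#'
#' Small ions reorient instantly and have field-independent mobility, so the
#' reorientation loss term vanishes and the mobilities cancel: the trajectory
#' follows the duty-weighted vector sum of the fields themselves,
#' \deqn{\Phi_0 = \mathrm{atan2}(E_1\sin\theta_1 + E_2\sin\theta_2,\;
#'                               E_1\cos\theta_1 + E_2\cos\theta_2),}
#' independent of the switching frequency. Because `Phi0` exceeds the DNA
#' angles, small-molecule contaminants stream away from every DNA fraction:
#' the device purifies while it separates.
#'
#' @param protocol A [field_protocol()].
#' @return Angle from the x axis in degrees.
#' @export
ion_angle <- function(protocol) {
  stopifnot(inherits(protocol, "field_protocol"))
  th1 <- .deg2rad(protocol$theta1_deg)
  th2 <- .deg2rad(protocol$theta2_deg)
  w1 <- protocol$duty * protocol$E1
  w2 <- (1 - protocol$duty) * protocol$E2
  .rad2deg(atan2(w1 * sin(th1) + w2 * sin(th2),
                 w1 * cos(th1) + w2 * cos(th2)))
}

#' Classify the switching regime of a fragment
#'
#' Compares the switching frequency with the fragment's two reorientation
#' frequencies (`f_or_strong` in the strong field, `f_or_weak` in the weak
#' field, `f_or_strong > f_or_weak`):
#'
#' * `f < f_or_weak`: the fragment realigns in both fields and the
#'   length-dependent mobility gain drives the separation
#'   (`field_dependent_mobility`);
#' * `f_or_weak <= f <= f_or_strong`: the fragment can only realign in the
#'   strong field and follows it (`switchback_window`); the boundary is
#'   inclusive upward;
#' * `f > f_or_strong`: the fragment realigns in neither field
#'   (`no_reorientation`).
#'
#' @param f Switching frequency, Hz.
#' @param f_or_strong,f_or_weak Reorientation frequencies, Hz, with
#'   `f_or_strong > f_or_weak > 0`.
#' @return One of `"field_dependent_mobility"`, `"switchback_window"`,
#'   `"no_reorientation"`.
#' @export
classify_regime <- function(f, f_or_strong, f_or_weak) {
  .check_number(f, "f", nonneg = TRUE)
  if (!is.numeric(f_or_strong) || !is.numeric(f_or_weak) ||
      !(f_or_strong > f_or_weak) || f_or_weak <= 0)
    stop_user("classify_regime requires f_or_strong > f_or_weak > 0 ",
              "(the strong field gives the higher reorientation frequency)")
  if (f < f_or_weak) "field_dependent_mobility"
  else if (f <= f_or_strong) "switchback_window"
  else "no_reorientation"
}

#' Deflection-angle spectra over a switching-frequency grid
#'
#' Evaluates [migration_angle()] for every (frequency, fragment) pair. For a
#' fixed fragment with `theta1 < theta2` the angle is non-increasing in `f`:
#' a plateau at low frequency (quasi-static, mobility-difference regime), a
#' decay toward `theta1` as the weak-field displacement is progressively eaten
#' by reorientation dead time, then the flagged ion-limit fallback once
#' neither field can reorient the chain.
#'
#' @param protocol A [field_protocol()]; its `f_Hz` is ignored in favour of
#'   `f_grid`.
#' @param fragments Fragments (list of [fragment_spec()] or numeric bp).
#' @param f_grid Strictly increasing frequencies in Hz, at least 2 points.
#' @param model Mobility model.
#' @return A data frame with columns `f_Hz`, `length_bp`, `label`, `phi_deg`,
#'   `regime`, `no_net_motion`, `v_eff1_cm_s`, `v_eff2_cm_s`.
#' @export
frequency_sweep <- function(protocol, fragments, f_grid, model) {
  stopifnot(inherits(protocol, "field_protocol"))
  fragments <- .as_fragment_list(fragments)
  if (!length(fragments)) stop_user("frequency_sweep needs at least one fragment")
  if (length(f_grid) < 2 || any(diff(f_grid) <= 0) || any(f_grid < 0))
    stop_user("f_grid must be non-negative, strictly increasing, with >= 2 points")
  rows <- lapply(fragments, function(fr) {
    per_f <- lapply(f_grid, function(f) {
      p <- protocol
      p$f_Hz <- f
      d <- migration_angle(p, fr, model = model)
      data.frame(f_Hz = f, length_bp = fr$length_bp, label = fr$label,
                 phi_deg = d$phi_deg, regime = d$regime,
                 no_net_motion = d$no_net_motion,
                 v_eff1_cm_s = d$v_eff1_cm_s, v_eff2_cm_s = d$v_eff2_cm_s,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_f)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a frequency sweep as CSV
#'
#' Columns: `f_Hz,length_bp,phi_deg,regime,v_eff1_cm_s,v_eff2_cm_s`.
#'
#' @param sweep Result of [frequency_sweep()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  cols <- c("f_Hz", "length_bp", "phi_deg", "regime",
            "v_eff1_cm_s", "v_eff2_cm_s")
  if (!all(cols %in% names(sweep)))
    stop_user("not a frequency_sweep result")
  write.csv(sweep[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
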