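#' Reorientation time of a DNA fragment after a field switch
#'
#' When the applied field changes direction, a reptating DNA chain must pull
#' itself into a new tube before it resumes steady migration. The lag scales
#' with the time the chain needs to travel its own contour length,
#' \deqn{t_{or} = \frac{L}{\mu E},}
#' and the corresponding reorientation frequency is
#' `f_or = 1/(2 t_or) = mu E / (2 L)`: above `f_or` a fragment cannot follow
#' that field component at all. Both depend on fragment length, which is what
#' the switchback separation mechanism exploits.
#'
#' @param mobility Mobility mu at the field `E`, cm^2/(V s) (> 0). Either a
#'   bare number or obtained from [evaluate_mobility()].
#' @param E Field strength, V/cm (> 0).
#' @param fragment A [fragment_spec()] or length in bp.
#'
#' @return `reorientation_time()` returns a `kinetics_result` with fields
#'   `t_or_s`, `f_or_Hz` (`= 1/(2 t_or)` exactly), `field_V_per_cm` and
#'   `fragment`. A zero contour length gives `t_or = 0` and `f_or = Inf`.
#'   `reorientation_frequency()` returns the bare frequency in Hz.
#' @examples
#' # 10 kbp at 59.5 V/cm with mu such that mu*E/L = 4.8 1/s:
#' r <- reorientation_time(2.742857e-5, 59.5, fragment_spec(10000))
#' r$t_or_s   # ~0.208 s
#' r$f_or_Hz  # ~2.4 Hz
#' @export
reorientation_time <- function(mobility, E, fragment) {
  .check_number(mobility, "mobility")
  .check_number(E, "E")
  if (mobility <= 0 || E <= 0)
    stop_user("reorientation kinetics need mobility > 0 and E > 0")
  fragment <- .as_fragment(fragment)
  L <- fragment$contour_length_cm
  t_or <- L / (mobility * E)
  f_or <- if (t_or > 0) 1 / (2 * t_or) else Inf
  structure(
    list(t_or_s = t_or, f_or_Hz = f_or, field_V_per_cm = E,
         mobility_cm2_per_Vs = mobility, fragment = fragment),
    class = "kinetics_result"
  )
}

#' @rdname reorientation_time
#' @export
reorientation_frequency <- function(mobility, E, fragment) {
  reorientation_time(mobility, E, fragment)$f_or_Hz
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("<kinetics_result> %s at %g V/cm: t_or = %.3g s, f_or = %.3g Hz\n",
              x$fragment$label, x$field_V_per_cm, x$t_or_s, x$f_or_Hz))
  invisible(x)
}

#' Mobility implied by an observed reorientation frequency
#'
#' Inverts `f_or = mu E / (2 L)` to `mu = 2 f_or L / E`. Useful to anchor a
#' mobility value on an optically measured reorientation frequency.
#'
#' @param f_or Reorientation frequency, Hz (> 0).
#' @inheritParams reorientation_time
#' @return Mobility in cm^2/(V s).
#' @export
mobility_from_reorientation <- function(f_or, E, fragment) {
  .check_number(f_or, "f_or", positive = TRUE)
  .check_number(E, "E", positive = TRUE)
  fragment <- .as_fragment(fragment)
  2 * f_or * fragment$contour_length_cm / E
}
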