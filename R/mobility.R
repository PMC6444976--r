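#' Parametric biased-reptation mobility model
#'
#' Mobility of a reptating DNA fragment in a sieving gel as a function of
#' field strength E (V/cm) and chain length, in the standard
#' biased-reptation-with-orientation form
#' \deqn{\mu(E, N) = \mu_0 \left[\frac{1}{3N} + \frac{\beta E^2}{1 + \gamma E^2}\right]}
#' where N is the chain length in Kuhn segments. The 1/(3N) term carries the
#' size dependence (longer chains wrap more gel fibres and move slower); the
#' saturating field term carries the field-induced chain orientation that
#' makes mobility grow with E. By construction the form is non-decreasing in
#' E and non-increasing in length.
#'
#' @param mu0 Mobility scale, cm^2/(V s); > 0.
#' @param beta Field-response coefficient, (cm/V)^2; >= 0. `beta = 0` removes
#'   the field dependence entirely.
#' @param gamma Saturation coefficient, (cm/V)^2; >= 0. `gamma = 0` leaves the
#'   field term unsaturated (quadratic in E).
#' @param kuhn_bp Base pairs per Kuhn segment used to convert `length_bp` to
#'   N. Default 300 bp (~100 nm Kuhn length of dsDNA at 0.34 nm/bp).
#'
#' @return A `mobility_model` of mode `"parametric"`.
#' @seealso [mobility_model_table()], [evaluate_mobility()]
#' @export
mobility_model_parametric <- function(mu0, beta = 0, gamma = 0, kuhn_bp = 300) {
  .check_number(mu0, "mu0", positive = TRUE)
  .check_number(beta, "beta", nonneg = TRUE)
  .check_number(gamma, "gamma", nonneg = TRUE)
  .check_number(kuhn_bp, "kuhn_bp", positive = TRUE)
  structure(
    list(mode = "parametric", mu0 = mu0, beta = beta, gamma = gamma,
         kuhn_bp = kuhn_bp),
    class = c("parametric_mobility_model", "mobility_model")
  )
}

#' Table-interpolated mobility model
#'
#' Wraps a calibration table of (E, length_bp, mobility) triples, as measured
#' on a device, into a mobility model. Evaluation is bilinear in
#' (E, log length_bp); a query at a tabulated grid point returns the tabulated
#' value exactly, and between grid points the result is bounded by the
#' surrounding grid values. The table must be a complete rectangular grid.
#'
#' Queries outside the grid's convex hull raise a range error naming the
#' offending axis unless `extrapolate = TRUE`, in which case the query is
#' clamped to the grid edge (constant extrapolation, which preserves
#' positivity and monotonicity).
#'
#' @param table Data frame with columns `E_V_per_cm`, `length_bp`,
#'   `mobility_cm2_per_Vs` covering a full grid.
#' @param extrapolate Allow clamped-edge evaluation outside the grid
#'   (default `FALSE`).
#'
#' @return A `mobility_model` of mode `"table"`.
#' @seealso [synthetic_mobility_table()], [read_mobility_table()]
#' @export
mobility_model_table <- function(table, extrapolate = FALSE) {
  need <- c("E_V_per_cm", "length_bp", "mobility_cm2_per_Vs")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop_user("calibration table needs columns ", paste(need, collapse = ", "))
  E_grid <- sort(unique(table$E_V_per_cm))
  L_grid <- sort(unique(table$length_bp))
  if (any(E_grid <= 0) || any(L_grid <= 0))
    stop_user("calibration table axes must be positive")
  if (nrow(table) != length(E_grid) * length(L_grid))
    stop_user("calibration table must cover a complete (E, length_bp) grid")
  mu <- matrix(NA_real_, length(E_grid), length(L_grid))
  iE <- match(table$E_V_per_cm, E_grid)
  iL <- match(table$length_bp, L_grid)
  mu[cbind(iE, iL)] <- table$mobility_cm2_per_Vs
  if (anyNA(mu)) stop_user("calibration table has duplicate or missing grid cells")
  if (any(mu <= 0)) stop_user("tabulated mobilities must be > 0")
  structure(
    list(mode = "table", E_grid = E_grid, L_grid = L_grid, mu = mu,
         extrapolate = isTRUE(extrapolate), table = table[need]),
    class = c("table_mobility_model", "mobility_model")
  )
}

#' @export
print.mobility_model <- function(x, ...) {
  if (x$mode == "parametric") {
    cat(sprintf(
      "<mobility_model: parametric> mu0=%.3g beta=%.3g gamma=%.3g kuhn_bp=%g\n",
      x$mu0, x$beta, x$gamma, x$kuhn_bp))
  } else {
    cat(sprintf(
      "<mobility_model: table> %d fields x %d lengths, E in [%g, %g] V/cm, L in [%g, %g] bp%s\n",
      length(x$E_grid), length(x$L_grid),
      min(x$E_grid), max(x$E_grid), min(x$L_grid), max(x$L_grid),
      if (x$extrapolate) " (clamped extrapolation on)" else ""))
  }
  invisible(x)
}

#' Evaluate the electrophoretic mobility mu(E, L)
#'
#' @param model A [mobility_model_parametric()] or [mobility_model_table()].
#' @param E Field strength in V/cm (> 0).
#' @param fragment A [fragment_spec()] (or a bare length in bp).
#' @return Mobility in cm^2/(V s).
#' @export
evaluate_mobility <- function(model, E, fragment) {
  UseMethod("evaluate_mobility")
}

#' @export
evaluate_mobility.parametric_mobility_model <- function(model, E, fragment) {
  .check_number(E, "E", positive = TRUE)
  fragment <- .as_fragment(fragment)
  N <- fragment$length_bp / model$kuhn_bp
  model$mu0 * (1 / (3 * N) + model$beta * E^2 / (1 + model$gamma * E^2))
}

#' @export
evaluate_mobility.table_mobility_model <- function(model, E, fragment) {
  .check_number(E, "E", positive = TRUE)
  fragment <- .as_fragment(fragment)
  .table_interp(model, E, fragment$length_bp)
}

# Bilinear interpolation in (E, log length_bp) with exact grid-point recovery.
.table_interp <- function(model, E, L_bp) {
  Eg <- model$E_grid
  Lg <- model$L_grid
  if (E < Eg[1] || E > Eg[length(Eg)]) {
    if (!model$extrapolate)
      stop_user(sprintf(
        "field E = %g V/cm outside calibration range [%g, %g]; enable extrapolation or extend the table (axis: E)",
        E, Eg[1], Eg[length(Eg)]))
    E <- min(max(E, Eg[1]), Eg[length(Eg)])
  }
  if (L_bp < Lg[1] || L_bp > Lg[length(Lg)]) {
    if (!model$extrapolate)
      stop_user(sprintf(
        "length %g bp outside calibration range [%g, %g]; enable extrapolation or extend the table (axis: length_bp)",
        L_bp, Lg[1], Lg[length(Lg)]))
    L_bp <- min(max(L_bp, Lg[1]), Lg[length(Lg)])
  }
  i <- findInterval(E, Eg, rightmost.closed = TRUE)
  j <- findInterval(L_bp, Lg, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(Eg) - 1L)
  j <- min(max(j, 1L), length(Lg) - 1L)
  tE <- if (Eg[i + 1] > Eg[i]) (E - Eg[i]) / (Eg[i + 1] - Eg[i]) else 0
  lg <- log(Lg)
  tL <- if (lg[j + 1] > lg[j]) (log(L_bp) - lg[j]) / (lg[j + 1] - lg[j]) else 0
  # snap to grid so tabulated values are reproduced exactly
  if (E == Eg[i]) tE <- 0 else if (E == Eg[i + 1]) tE <- 1
  if (L_bp == Lg[j]) tL <- 0 else if (L_bp == Lg[j + 1]) tL <- 1
  m <- model$mu
  (1 - tE) * (1 - tL) * m[i, j] + tE * (1 - tL) * m[i + 1, j] +
    (1 - tE) * tL * m[i, j + 1] + tE * tL * m[i + 1, j + 1]
}

#' Derivative of mobility with respect to field strength
#'
#' For the parametric family the derivative is analytic,
#' `dmu/dE = 2 mu0 beta E / (1 + gamma E^2)^2`, and is always >= 0. For table
#' models a central finite difference with step h = 1% of the local E grid
#' spacing is used (one-sided at the grid edges).
#'
#' @inheritParams evaluate_mobility
#' @return dmu/dE in cm^2/(V s) per (V/cm), i.e. cm^3/(V^2 s).
#' @export
mobility_derivative <- function(model, E, fragment) {
  UseMethod("mobility_derivative")
}

#' @export
mobility_derivative.parametric_mobility_model <- function(model, E, fragment) {
  .check_number(E, "E", positive = TRUE)
  .as_fragment(fragment)  # validate
  2 * model$mu0 * model$beta * E / (1 + model$gamma * E^2)^2
}

#' @export
mobility_derivative.table_mobility_model <- function(model, E, fragment) {
  .check_number(E, "E", positive = TRUE)
  fragment <- .as_fragment(fragment)
  Eg <- model$E_grid
  if (!model$extrapolate && (E < Eg[1] || E > Eg[length(Eg)]))
    stop_user(sprintf(
      "field E = %g V/cm outside calibration range [%g, %g] (axis: E)",
      E, Eg[1], Eg[length(Eg)]))
  i <- min(max(findInterval(E, Eg, rightmost.closed = TRUE), 1L),
           length(Eg) - 1L)
  h <- 0.01 * (Eg[i + 1] - Eg[i])
  lo <- if (model$extrapolate) -Inf else Eg[1]
  hi <- if (model$extrapolate) Inf else Eg[length(Eg)]
  if (E - h >= lo && E + h <= hi) {
    (.table_interp(model, E + h, fragment$length_bp) -
       .table_interp(model, E - h, fragment$length_bp)) / (2 * h)
  } else if (E - h < lo) {
    (.table_interp(model, E + h, fragment$length_bp) -
       .table_interp(model, E, fragment$length_bp)) / h
  } else {
    (.table_interp(model, E, fragment$length_bp) -
       .table_interp(model, E - h, fragment$length_bp)) / h
  }
}

#' Mobility gain between the strong and weak field
#'
#' The length dependence of `delta_mobility` is what makes quasi-static
#' (low-frequency) separation possible: the more a fragment's mobility grows
#' between the weak and the strong field, the more its trajectory leans toward
#' the strong-field direction. Computed as
#' `dmu/dE * (E1 - E2)` with the derivative evaluated at the field midpoint
#' `(E1 + E2)/2` (second-order-accurate convention; the evaluation point only
#' matters when the derivative itself varies between E2 and E1).
#'
#' @inheritParams evaluate_mobility
#' @param E1 Strong field, V/cm.
#' @param E2 Weak field, V/cm; requires `E1 >= E2 > 0`.
#' @return Delta mu in cm^2/(V s); 0 when `E1 == E2`.
#' @export
delta_mobility <- function(model, E1, E2, fragment) {
  .check_number(E1, "E1", positive = TRUE)
  .check_number(E2, "E2", positive = TRUE)
  if (E1 < E2) stop_user("delta_mobility expects E1 >= E2 (strong field first)")
  if (E1 == E2) return(0)
  mobility_derivative(model, (E1 + E2) / 2, fragment) * (E1 - E2)
}

#' Synthetic device calibration table
#'
#' A packaged stand-in for a measured (E, length, mobility) calibration of a
#' pulsed-field gel device, for the five fragment lengths 0.5, 1, 2, 5 and
#' 10 kbp on a field grid spanning 5-134.6 V/cm. It is synthetic (the values
#' are not measurements) but is constructed to reproduce the qualitative
#' structure such calibrations show:
#'
#' * mobility increases with E (orientation) and decreases with length
#'   (friction) everywhere on the grid;
#' * the mobility gain between 59.5 and 22.4 V/cm grows with length over
#'   0.5-5 kbp, so the quasi-static deflection angles of those four fragments
#'   are distinct;
#' * the 5 and 10 kbp rows share the same strong/weak mobility *ratio*, so
#'   those two fragments co-migrate in the quasi-static limit and are only
#'   separated via their reorientation lag;
#' * the 10 kbp mobility at 59.5 V/cm is anchored to the value implied by a
#'   2.4 Hz reorientation frequency at that field
#'   (`mu = 2 f_or L / E = 2.74286e-5` cm^2/(V s)).
#'
#' Functional form per length: `mu(E) = mu59 * (p + (1 - p) h(E)/h(59.5))`
#' with `h(E) = E^2/(1 + 1e-3 E^2)`; `p` controls how strongly the row
#' responds to the field.
#'
#' @return A data frame with columns `E_V_per_cm`, `length_bp`,
#'   `mobility_cm2_per_Vs` (complete grid, 45 rows).
#' @seealso [mobility_model_table()]
#' @export
synthetic_mobility_table <- function() {
  E_grid <- c(5, 10, 22.4, 24.6, 29.1, 40, 59.5, 89.8, 134.6)
  lengths <- c(500, 1000, 2000, 5000, 10000)
  # field-response shape shared by all rows
  gamma <- 1e-3
  h <- function(E) E^2 / (1 + gamma * E^2)
  h59 <- h(59.5)
  # anchor: 10 kbp at 59.5 V/cm from f_or = 2.4 Hz
  mu59_10k <- 2 * 2.4 * (10000 * BP_CM) / 59.5
  mu59 <- c(`500` = 9.0e-5, `1000` = 8.6e-5, `2000` = 7.8e-5,
            `5000` = 7.0e-5, `10000` = mu59_10k)
  p <- c(`500` = 0.930, `1000` = 0.8076, `2000` = 0.615,
         `5000` = 0.2476, `10000` = 0.2476)
  grid <- expand.grid(E_V_per_cm = E_grid, length_bp = lengths,
                      KEEP.OUT.ATTRS = FALSE)
  key <- as.character(grid$length_bp)
  grid$mobility_cm2_per_Vs <- unname(
    mu59[key] * (p[key] + (1 - p[key]) * h(grid$E_V_per_cm) / h59))
  rownames(grid) <- NULL
  grid
}

#' Built-in synthetic mobility model
#'
#' [synthetic_mobility_table()] wrapped into a table model; the default
#' mobility model for simulations and the command-line runner.
#'
#' @param extrapolate Passed to [mobility_model_table()].
#' @return A table `mobility_model`.
#' @export
builtin_mobility_model <- function(extrapolate = FALSE) {
  mobility_model_table(synthetic_mobility_table(), extrapolate = extrapolate)
}

#' Read / write mobility calibration tables
#'
#' CSV with header `E_V_per_cm,length_bp,mobility_cm2_per_Vs`.
#'
#' @param path File path.
#' @return `read_mobility_table()` returns the data frame;
#'   `write_mobility_table()` returns `path` invisibly.
#' @export
read_mobility_table <- function(path) {
  if (!file.exists(path)) stop_user("no such calibration table: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("E_V_per_cm", "length_bp", "mobility_cm2_per_Vs")
  if (!all(need %in% names(tab)))
    stop_user("calibration CSV must have header ", paste(need, collapse = ","))
  tab[need]
}

#' @rdname read_mobility_table
#' @param table Data frame as in [mobility_model_table()].
#' @export
write_mobility_table <- function(table, path) {
  need <- c("E_V_per_cm", "length_bp", "mobility_cm2_per_Vs")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop_user("calibration table needs columns ", paste(need, collapse = ", "))
  write.csv(table[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a parametric mobility model as YAML
#'
#' The block carries `{mode, mu0, beta, gamma, kuhn_bp}`.
#'
#' @param path File path.
#' @return `read_mobility_model()` returns a parametric `mobility_model`.
#' @export
read_mobility_model <- function(path) {
  if (!file.exists(path)) stop_user("no such mobility model file: ", path)
  y <- yaml::read_yaml(path)
  if (!identical(y$mode, "parametric"))
    stop_user("mobility model YAML must have mode: parametric")
  mobility_model_parametric(
    mu0 = y$mu0, beta = y$beta %||% 0, gamma = y$gamma %||% 0,
    kuhn_bp = y$kuhn_bp %||% 300)
}

#' @rdname read_mobility_model
#' @param model A parametric `mobility_model`.
#' @export
write_mobility_model <- function(model, path) {
  if (!inherits(model, "parametric_mobility_model"))
    stop_user("only parametric models are written as YAML; use write_mobility_table() for tables")
  yaml::write_yaml(
    list(mode = "parametric", mu0 = model$mu0, beta = model$beta,
         gamma = model$gamma, kuhn_bp = model$kuhn_bp),
    path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
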