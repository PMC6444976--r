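#' Specify a DNA fragment by its length
#'
#' A fragment is identified by its length in base pairs; the contour length
#' used throughout the kinetics and trajectory models is derived from it at
#' 0.34 nm per base pair.
#'
#' @param length_bp Fragment length in base pairs (positive integer).
#' @param label Optional free-text label; defaults to e.g. `"2 kbp"`.
#'
#' @return An object of class `fragment_spec` with fields `length_bp`,
#'   `label` and `contour_length_cm` (`length_bp * 0.34e-7` exactly).
#' @examples
#' fr <- fragment_spec(10000)
#' fr$contour_length_cm  # 3.4e-4 cm
#' @export
fragment_spec <- function(length_bp, label = NULL) {
  .check_number(length_bp, "length_bp")
  if (length_bp < 1 || length_bp != round(length_bp))
    stop_user("length_bp must be a positive integer (got ", length_bp, ")")
  length_bp <- as.integer(round(length_bp))
  if (is.null(label)) {
    label <- if (length_bp %% 100 == 0) {
      paste0(length_bp / 1000, " kbp")
    } else {
      paste0(length_bp, " bp")
    }
  }
  structure(
    list(length_bp = length_bp, label = as.character(label),
         contour_length_cm = length_bp * BP_CM),
    class = "fragment_spec"
  )
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("<fragment_spec> %s (%d bp, contour %.3g cm)\n",
              x$label, x$length_bp, x$contour_length_cm))
  invisible(x)
}

.as_fragment <- function(x) {
  if (inherits(x, "fragment_spec")) return(x)
  if (.is_number(x)) return(fragment_spec(x))
  stop_user("expected a fragment_spec or a length in bp")
}

.as_fragment_list <- function(x) {
  if (inherits(x, "fragment_spec")) return(list(x))
  if (is.numeric(x)) return(lapply(x, fragment_spec))
  if (is.list(x)) return(lapply(x, .as_fragment))
  stop_user("expected fragment_spec objects or lengths in bp")
}
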