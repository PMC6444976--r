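# Shared constants and small internal helpers.

# Contour length of B-form dsDNA per base pair, in cm (0.34 nm/bp).
BP_CM <- 0.34e-7

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# User-facing errors (bad inputs, bad configs) carry their own condition class
# so the command-line front end can map them to exit status 1 rather than 2.
stop_user <- function(..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c("pulsegel_user_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!.is_number(x))
    stop_user(name, " must be a single finite number")
  if (positive && x <= 0) stop_user(name, " must be > 0")
  if (nonneg && x < 0) stop_user(name, " must be >= 0")
  invisible(x)
}
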