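#' Render a synthetic fluorescence image of fragment streams
#'
#' Generates a 16-bit grayscale micrograph stand-in for the separation
#' chamber: each stream is drawn as a straight ridge from the injection point
#' to its exit position on the collection edge, with a Gaussian cross-section,
#' on top of a constant-plus-gradient background; the whole frame is then
#' blurred by a Gaussian point-spread function and Poisson photon noise is
#' applied. Rows are y (down the collection line), columns are x (toward the
#' collection edge). The ground truth used for drawing is returned alongside,
#' so analysis results can be checked against it.
#'
#' @param streams Either a `stream_simulation` (per-fragment exit mean/sd and
#'   counts become ridge centre/width/brightness) or a data frame with
#'   columns `center_um`, `sigma_um` and optionally `amplitude`,
#'   `injection_y_um`, `label`.
#' @param image_shape `c(rows, cols)` of the image (default `c(1024, 1024)`,
#'   i.e. ~10 um pixels over the default 1 cm chamber).
#' @param chamber A [chamber_spec()] fixing the physical extent the frame
#'   covers.
#' @param psf_sigma_px Point-spread blur sigma in pixels (default 0.75; 0
#'   turns blurring off). Kept well below the stream width in pixels so the
#'   optical blur does not dominate the measured widths, as for a real
#'   epifluorescence microscope whose PSF (~1 um) is far narrower than the
#'   ~100 um bands; note an isotropic PSF widens a diagonal stream's
#'   y cross-section by `psf^2 (1 + tan^2 phi)`.
#' @param background `c(offset, gradient)` counts: constant level plus a
#'   linear ramp along x (default `c(100, 50)`).
#' @param amplitude Default ridge peak brightness in counts when `streams`
#'   does not carry one.
#' @param noise Apply Poisson noise (default TRUE).
#' @param noise_seed RNG seed for the noise; required when `noise = TRUE`.
#'
#' @return A `gel_image`: integer `image` matrix (0..65535, clipped with a
#'   warning on overflow), pixel pitches `um_per_px_y`/`um_per_px_x`, and the
#'   `ground_truth` data frame (`label`, `injection_y_um`, `center_um`,
#'   `sigma_um`, `amplitude`); stream centres are given at the collection
#'   edge, and the ridge centre at column x is
#'   `injection_y + (center - injection_y) * x / width`.
#' @seealso [process_image()], [extract_profile()], [write_gel_image()]
#' @export
render_image <- function(streams, image_shape = c(1024L, 1024L),
                         chamber = chamber_spec(), psf_sigma_px = 0.75,
                         background = c(100, 50), amplitude = 2000,
                         noise = TRUE, noise_seed = NULL) {
  stopifnot(inherits(chamber, "chamber_spec"))
  if (length(image_shape) != 2 || any(image_shape < 5))
    stop_user("image_shape must be c(rows, cols), each >= 5")
  .check_number(psf_sigma_px, "psf_sigma_px", nonneg = TRUE)

  gt <- .streams_ground_truth(streams, chamber, amplitude)
  ny <- as.integer(image_shape[1])
  nx <- as.integer(image_shape[2])
  H_um <- chamber$height_cm * 1e4
  W_um <- chamber$width_cm * 1e4
  ppy <- H_um / ny
  ppx <- W_um / nx
  ycoord <- (seq_len(ny) - 0.5) * ppy
  xcoord <- (seq_len(nx) - 0.5) * ppx

  img <- matrix(background[1] +
                  background[2] * rep(xcoord / W_um, each = ny),
                ny, nx)
  for (k in seq_len(nrow(gt))) {
    centre_line <- gt$injection_y_um[k] +
      (gt$center_um[k] - gt$injection_y_um[k]) * xcoord / W_um
    dev <- outer(ycoord, centre_line, `-`)
    img <- img + gt$amplitude[k] * exp(-dev^2 / (2 * gt$sigma_um[k]^2))
  }
  if (psf_sigma_px > 0) img <- .gauss_blur(img, psf_sigma_px)
  if (isTRUE(noise)) {
    if (is.null(noise_seed)) stop_user("noise_seed is required when noise = TRUE")
    set.seed(as.integer(noise_seed))
    img <- matrix(rpois(length(img), lambda = pmax(img, 0)), ny, nx)
  }
  if (any(img > 65535)) {
    warning("rendered intensities exceed 16-bit range; clipping to 65535")
    img[img > 65535] <- 65535
  }
  img[img < 0] <- 0
  structure(
    list(image = round(img), um_per_px_y = ppy, um_per_px_x = ppx,
         ground_truth = gt, chamber = chamber,
         background = background, psf_sigma_px = psf_sigma_px),
    class = "gel_image"
  )
}

.streams_ground_truth <- function(streams, chamber, amplitude) {
  inj_um <- chamber$injection_y_cm * 1e4
  if (inherits(streams, "stream_simulation")) {
    per <- streams$per_fragment
    gt <- do.call(rbind, lapply(names(per), function(nm) {
      p <- per[[nm]]
      if (p$n_collected < 2) return(NULL)
      data.frame(label = nm, injection_y_um = inj_um,
                 center_um = p$exit_mean_cm * 1e4,
                 sigma_um = p$exit_sd_cm * 1e4,
                 amplitude = amplitude * p$n_collected /
                   max(vapply(per, `[[`, 0, "n_collected")),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(gt) || !nrow(gt))
      gt <- data.frame(label = character(), injection_y_um = numeric(),
                       center_um = numeric(), sigma_um = numeric(),
                       amplitude = numeric())
    return(gt)
  }
  if (is.null(streams) ||
      (is.data.frame(streams) && nrow(streams) == 0)) {
    return(data.frame(label = character(), injection_y_um = numeric(),
                      center_um = numeric(), sigma_um = numeric(),
                      amplitude = numeric()))
  }
  if (!is.data.frame(streams) ||
      !all(c("center_um", "sigma_um") %in% names(streams)))
    stop_user("streams must be a stream_simulation or a data frame with center_um and sigma_um")
  if (any(streams$sigma_um <= 0)) stop_user("stream sigma_um must be > 0")
  data.frame(
    label = if ("label" %in% names(streams)) as.character(streams$label)
            else paste0("stream", seq_len(nrow(streams))),
    injection_y_um = if ("injection_y_um" %in% names(streams))
      streams$injection_y_um else inj_um,
    center_um = streams$center_um,
    sigma_um = streams$sigma_um,
    amplitude = if ("amplitude" %in% names(streams)) streams$amplitude
                else amplitude,
    stringsAsFactors = FALSE)
}

# Separable Gaussian blur with replicated edges (EBImage kernel).
.gauss_blur <- function(img, sigma_px, size = NULL) {
  if (is.null(size)) size <- 2L * ceiling(2.5 * sigma_px) + 1L
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  # pad by replication so FFT wrap-around cannot bleed across edges
  p <- (size - 1L) %/% 2L
  padded <- .pad_replicate(img, p)
  out <- EBImage::filter2(padded, brush, boundary = "circular")
  out[(p + 1):(p + nrow(img)), (p + 1):(p + ncol(img))]
}

.pad_replicate <- function(m, p) {
  ri <- c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p))
  ci <- c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p))
  m[ri, ci, drop = FALSE]
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image> %d x %d px (%.1f x %.1f um/px), %d stream(s)\n",
              nrow(x$image), ncol(x$image), x$um_per_px_y, x$um_per_px_x,
              nrow(x$ground_truth)))
  invisible(x)
}

#' Write / read a rendered image as 16-bit TIFF (+ JSON ground truth)
#'
#' @param img A `gel_image` from [render_image()].
#' @param tiff_path Output TIFF (16-bit grayscale).
#' @param sidecar_path Optional JSON path for the ground-truth table and
#'   pixel calibration (default: `tiff_path` with `.json` appended).
#' @return `tiff_path`, invisibly.
#' @export
write_gel_image <- function(img, tiff_path, sidecar_path = NULL) {
  stopifnot(inherits(img, "gel_image"))
  tiff::writeTIFF(img$image / 65535, tiff_path, bits.per.sample = 16L)
  if (is.null(sidecar_path)) sidecar_path <- paste0(tiff_path, ".json")
  jsonlite::write_json(
    list(um_per_px_y = img$um_per_px_y, um_per_px_x = img$um_per_px_x,
         background = img$background, psf_sigma_px = img$psf_sigma_px,
         ground_truth = img$ground_truth),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_gel_image
#' @param path TIFF file to read (8- or 16-bit grayscale).
#' @return `read_gel_matrix()` returns a numeric matrix in counts
#'   (0..65535 for 16-bit input).
#' @export
read_gel_matrix <- function(path) {
  if (!file.exists(path)) stop_user("no such image: ", path)
  a <- tiff::readTIFF(path, info = FALSE)
  if (length(dim(a)) == 3) a <- a[, , 1]
  round(a * 65535)
}
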