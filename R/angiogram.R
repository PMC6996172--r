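#' En-face OCT angiogram
#'
#' Container for one en-face OCT-A slab image plus acquisition metadata.
#' Pixels are an 8-bit-range grayscale matrix (values in \[0, 255\],
#' vessels bright), rows indexing the vertical (y) direction. The image is
#' square and covers `width_mm` x `width_mm` of retina centred on the
#' fovea; the mm coordinate frame has its origin at the image center with
#' pixel-center convention.
#'
#' @param pixels Numeric square matrix of intensities in \[0, 255\].
#' @param width_mm Physical scan width in mm (default 3.0).
#' @param layer `"DCP"` (deep capillary plexus) or `"SCP"` (superficial).
#' @param quality_score Device-reported integer quality score in \[0, 100\].
#' @param seg_error Logical metadata flag: B-scan segmentation error seen
#'   at acquisition review (B-scans themselves are not carried).
#' @param eye_id,subject_id,session_id Identifiers. `session_id` is free
#'   text; repeatability workflows use `"visit1_scan1"`, `"visit1_scan2"`,
#'   `"visit2_scan1"`.
#' @param artifacts Character vector of artifact labels already present
#'   (empty for a clean image); artifact injectors append to it.
#'
#' @return An object of class `enface_angiogram`: a list with fields
#'   `pixels`, `n_px`, `width_mm`, `layer`, `quality_score`, `seg_error`,
#'   `eye_id`, `subject_id`, `session_id`, `artifacts`.
#' @export
#' @examples
#' img <- enface_angiogram(matrix(128, 64, 64), width_mm = 3, layer = "DCP")
#' img
enface_angiogram <- function(pixels, width_mm = 3, layer = c("DCP", "SCP"),
                             quality_score = 60L, seg_error = FALSE,
                             eye_id = "eye01", subject_id = "subj01",
                             session_id = "visit1_scan1",
                             artifacts = character()) {
  layer <- match.arg(layer)
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels) || nrow(pixels) < 1) {
    abort("invalid geometry: `pixels` must be a non-empty square matrix",
          class = "deepangio_invalid_geometry")
  }
  if (!is.numeric(width_mm) || width_mm <= 0) {
    abort("invalid geometry: `width_mm` must be strictly positive",
          class = "deepangio_invalid_geometry")
  }
  if (quality_score < 0 || quality_score > 100) {
    abort("`quality_score` must be in [0, 100]")
  }
  pixels <- clamp(pixels, 0, 255)
  structure(
    list(
      pixels = pixels, n_px = nrow(pixels), width_mm = width_mm,
      layer = layer, quality_score = as.integer(quality_score),
      seg_error = isTRUE(seg_error), eye_id = eye_id,
      subject_id = subject_id, session_id = session_id,
      artifacts = as.character(artifacts)
    ),
    class = "enface_angiogram"
  )
}

pixel_size_mm <- function(img) img$width_mm / img$n_px

is_angiogram <- function(x) inherits(x, "enface_angiogram")

check_angiogram <- function(x, arg = "image") {
  if (!is_angiogram(x)) {
    abort(paste0("`", arg, "` must be an <enface_angiogram>"))
  }
  invisible(x)
}

check_same_geometry <- function(a, b) {
  if (a$n_px != b$n_px || !isTRUE(all.equal(a$width_mm, b$width_mm))) {
    abort("incompatible images: geometry (n_px, width_mm) differs",
          class = "deepangio_incompatible_images")
  }
  invisible(TRUE)
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf(
    "<enface_angiogram> %s  %d x %d px, %.2f mm (%.4f mm/px)\n",
    x$layer, x$n_px, x$n_px, x$width_mm, pixel_size_mm(x)
  ))
  cat(sprintf(
    "  eye %s / subject %s / session %s; quality %d; seg_error %s\n",
    x$eye_id, x$subject_id, x$session_id, x$quality_score, x$seg_error
  ))
  if (length(x$artifacts)) {
    cat("  artifacts:", paste(x$artifacts, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot an en-face angiogram
#'
#' Renders the angiogram as a grayscale raster in the mm coordinate
#' frame (origin at the fovea).
#'
#' @param img An [enface_angiogram()].
#' @return A ggplot object.
#' @export
plot_angiogram <- function(img) {
  check_angiogram(img)
  g <- pixel_grid_mm(img$n_px, img$width_mm)
  df <- tibble(
    x = as.vector(g$x), y = as.vector(g$y),
    intensity = as.vector(img$pixels)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)", fill = "intensity",
      title = sprintf("%s en-face angiogram (%s)", img$layer, img$eye_id)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.enface_angiogram <- function(object, ...) plot_angiogram(object)
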