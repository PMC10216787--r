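#' Acquisition geometry of a high-content imaging field
#'
#' Describes how one well is sampled by the microscope: the area of a single
#' field of view, the number of z-planes and their spacing, the pixel size,
#' and how many fields are acquired per well. The defaults reproduce a
#' spinning-disk high-content setup with a 40x water objective: a field of
#' 78,974.6 um^2 imaged as 15 planes with 25 um z-steps.
#'
#' Fields are assumed square, so the pixel grid side is
#' `round(sqrt(field_area) / pixel_size)`. The rasterised area
#' `(pixels * pixel_size)^2` must agree with `field_area` within 1%
#' (rounding slack); otherwise the geometry is rejected as inconsistent.
#'
#' @param field_area Area of one field of view in um^2.
#' @param n_planes Number of z-planes imaged per field.
#' @param z_step Distance between consecutive planes in um.
#' @param pixel_size Lateral pixel size in um/pixel.
#' @param n_fields Number of fields acquired per well.
#'
#' @return An object of class `acquisition_geometry`: a list with the five
#'   arguments plus `pixels`, the side length of the square pixel grid.
#' @examples
#' geom <- acquisition_geometry()
#' geom$pixels            # 937 at 0.3 um/pixel
#' geometry_from_pixels(192, pixel_size = 1, n_planes = 5)
#' @export
acquisition_geometry <- function(field_area = 78974.6, n_planes = 15,
                                 z_step = 25, pixel_size = 0.3,
                                 n_fields = 1) {
  vals <- c(field_area = field_area, n_planes = n_planes, z_step = z_step,
            pixel_size = pixel_size, n_fields = n_fields)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry parameters must be strictly positive and finite")
  if (n_planes < 1) stop("n_planes must be >= 1")
  pixels <- round(sqrt(field_area) / pixel_size)
  if (pixels < 1)
    stop("invalid geometry: field has zero pixels at this pixel size")
  raster_area <- (pixels * pixel_size)^2
  if (abs(raster_area - field_area) / field_area > 0.01)
    stop(sprintf(
      "inconsistent geometry: %d px of %g um give %.1f um^2, not %.1f um^2",
      pixels, pixel_size, raster_area, field_area))
  structure(list(field_area = field_area, n_planes = as.integer(n_planes),
                 z_step = z_step, pixel_size = pixel_size,
                 n_fields = as.integer(n_fields), pixels = as.integer(pixels)),
            class = "acquisition_geometry")
}

#' @rdname acquisition_geometry
#' @param pixels Side length of the square pixel grid.
#' @export
geometry_from_pixels <- function(pixels, pixel_size = 0.3, n_planes = 15,
                                 z_step = 25, n_fields = 1) {
  acquisition_geometry(field_area = (pixels * pixel_size)^2,
                       n_planes = n_planes, z_step = z_step,
                       pixel_size = pixel_size, n_fields = n_fields)
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "Acquisition geometry: %d x %d px (%.1f um^2) at %g um/px, %d plane(s) x %g um, %d field(s)/well\n",
    x$pixels, x$pixels, x$field_area, x$pixel_size, x$n_planes, x$z_step,
    x$n_fields))
  invisible(x)
}
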