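#' Three-channel z-stack for one imaged field
#'
#' Container for one field's fluorescence data: three named channels
#' (`hoechst`, `caspase`, `pi`), each a `pixels x pixels x n_planes`
#' non-negative array, plus the acquisition geometry and well/field
#' identifiers. Channels must share an identical shape.
#'
#' @param channels Named list of three numeric arrays
#'   (`hoechst`, `caspase`, `pi`), each `px x px x n_planes`.
#' @param geometry An [acquisition_geometry()].
#' @param well_id,field_id Identifiers carried into all downstream records.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, geometry, well_id = "W1", field_id = 1L) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  need <- c("hoechst", "caspase", "pi")
  if (!is.list(channels) || !all(need %in% names(channels)))
    stop("channels must be a named list with hoechst, caspase and pi")
  channels <- channels[need]
  dims <- lapply(channels, dim)
  ref <- dims[[1]]
  if (length(ref) != 3L || !all(vapply(dims, identical, logical(1), ref)))
    stop("all three channels must be 3-d arrays of identical shape")
  if (ref[1] != geometry$pixels || ref[2] != geometry$pixels ||
      ref[3] != geometry$n_planes)
    stop("channel shape does not match the acquisition geometry")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("intensities must be non-negative")
  structure(list(channels = channels, geometry = geometry,
                 well_id = well_id, field_id = field_id),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("Image stack: well %s field %s, 3 channels x %d plane(s) of %d x %d px\n",
              x$well_id, x$field_id, x$geometry$n_planes,
              x$geometry$pixels, x$geometry$pixels))
  if (!is.null(x$truth))
    cat(sprintf("  carries ground truth: %d nuclei, %d organoid(s)\n",
                nrow(x$truth$cells), nrow(x$truth$organoid_areas)))
  invisible(x)
}

#' Combine the three channels of one plane into a single image
#'
#' Organoid segmentation works on the combination of all three imaging
#' channels, so organoids are found whether their cells are Hoechst-bright,
#' caspase-bright or PI-bright. Each channel is first rescaled to a common
#' dynamic range (divided by its own maximum over the plane; all-zero
#' channels contribute zero) and the rescaled channels are summed. The
#' operation is deterministic.
#'
#' @param stack An [image_stack()].
#' @param plane Plane index (1-based).
#' @return A `pixels x pixels` non-negative matrix.
#' @export
combine_channels <- function(stack, plane) {
  stopifnot(inherits(stack, "image_stack"))
  if (plane < 1 || plane > stack$geometry$n_planes)
    stop("plane out of range")
  out <- matrix(0, stack$geometry$pixels, stack$geometry$pixels)
  for (ch in stack$channels) {
    pl <- ch[, , plane]
    m <- max(pl)
    if (m > 0) out <- out + pl / m
  }
  out
}
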