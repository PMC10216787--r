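#' Extract per-nucleus mean dye intensities
#'
#' For every labelled nucleus, computes the arithmetic mean of the raw
#' (unfiltered) Caspase 3/7 and PI channel pixels under the nucleus mask.
#' Nuclei whose mask region is empty are skipped with a warning.
#'
#' @param stack An [image_stack()].
#' @param nucleus_labels Nucleus label matrix for the plane.
#' @param plane Plane index the labels refer to.
#' @param nuclei Data frame from [segment_nuclei()] (or a ground-truth
#'   equivalent with `nucleus_id` and `organoid_id`).
#' @return Data frame of nucleus records: `nucleus_id`, `organoid_id`,
#'   `well_id`, `plane`, `area` (um^2), `mean_caspase`, `mean_pi`.
#' @export
extract_intensities <- function(stack, nucleus_labels, plane, nuclei) {
  stopifnot(inherits(stack, "image_stack"))
  if (!all(dim(nucleus_labels) == c(stack$geometry$pixels,
                                    stack$geometry$pixels)))
    stop("nucleus label shape does not match the stack")
  casp <- stack$channels$caspase[, , plane]
  pich <- stack$channels$pi[, , plane]
  lab <- nucleus_labels[nucleus_labels > 0]
  if (!length(lab) || !nrow(nuclei)) {
    return(data.frame(nucleus_id = integer(0), organoid_id = integer(0),
                      well_id = character(0), plane = integer(0),
                      area = numeric(0), mean_caspase = numeric(0),
                      mean_pi = numeric(0)))
  }
  mean_c <- tapply(casp[nucleus_labels > 0], lab, mean)
  mean_p <- tapply(pich[nucleus_labels > 0], lab, mean)
  have <- as.integer(names(mean_c))
  missing <- setdiff(nuclei$nucleus_id, have)
  if (length(missing))
    warning("skipping ", length(missing), " nucleus record(s) with empty mask")
  keep <- nuclei[nuclei$nucleus_id %in% have, , drop = FALSE]
  ord <- match(keep$nucleus_id, have)
  data.frame(nucleus_id = keep$nucleus_id,
             organoid_id = keep$organoid_id,
             well_id = stack$well_id,
             plane = plane,
             area = if ("area" %in% names(keep)) keep$area else
               as.numeric(tabulate(lab)[keep$nucleus_id]) *
                 stack$geometry$pixel_size^2,
             mean_caspase = as.numeric(mean_c)[ord],
             mean_pi = as.numeric(mean_p)[ord])
}

#' Run the full per-plane pipeline over one image stack
#'
#' For every plane of the field: combine the three channels, segment
#' organoids, filter on area, segment nuclei within organoids and extract
#' per-nucleus mean intensities. Organoid and nucleus ids are made unique
#' across planes; per the sampling design, intersections of one organoid
#' on multiple planes are counted as separate organoid records.
#'
#' @param stack An [image_stack()].
#' @param params Named list of pipeline parameters; recognized entries
#'   (with defaults): `gaussian_sigma` (2 px), `resize_radius` (2 px),
#'   `min_area` (250 um^2), `threshold` ("otsu"), `nucleus_sigma`
#'   (2.5 um), `tolerance` (0.05).
#' @return List with `organoids` (organoid records across planes: adds
#'   `well_id`, `field_id`, `plane`, `n_nuclei`) and `nuclei` (nucleus
#'   records).
#' @export
process_stack <- function(stack, params = list()) {
  stopifnot(inherits(stack, "image_stack"))
  p <- utils::modifyList(list(gaussian_sigma = 2, resize_radius = 2,
                              min_area = 250, threshold = "otsu",
                              nucleus_sigma = 2.5, tolerance = 0.05,
                              closing_radius = NULL),
                         params)
  if (is.null(p$closing_radius))
    p$closing_radius <- max(2L, ceiling(p$nucleus_sigma /
                                          stack$geometry$pixel_size) + 1L)
  orgs <- list(); nucs <- list()
  for (pl in seq_len(stack$geometry$n_planes)) {
    comb <- combine_channels(stack, pl)
    seg <- segment_organoids(comb, stack$geometry,
                             gaussian_sigma = p$gaussian_sigma,
                             resize_radius = p$resize_radius,
                             min_area = p$min_area, threshold = p$threshold,
                             closing_radius = p$closing_radius)
    if (!nrow(seg$organoids)) next
    nu <- segment_nuclei(stack$channels$hoechst[, , pl], seg$labels,
                         stack$geometry, nucleus_sigma = p$nucleus_sigma,
                         tolerance = p$tolerance)
    rec <- extract_intensities(stack, nu$labels, pl, nu$nuclei)
    counts <- table(factor(nu$nuclei$organoid_id,
                           levels = seg$organoids$organoid_id))
    od <- seg$organoids
    od$n_nuclei <- as.integer(counts)
    od$plane <- pl
    od$well_id <- stack$well_id
    od$field_id <- stack$field_id
    orgs[[length(orgs) + 1L]] <- od
    if (nrow(rec)) {
      rec$field_id <- stack$field_id
      nucs[[length(nucs) + 1L]] <- rec
    }
  }
  organoids <- if (length(orgs)) do.call(rbind, orgs) else
    data.frame(organoid_id = integer(0), area = numeric(0),
               centroid_x = numeric(0), centroid_y = numeric(0),
               on_border = logical(0), n_nuclei = integer(0),
               plane = integer(0), well_id = character(0),
               field_id = integer(0))
  nuclei <- if (length(nucs)) do.call(rbind, nucs) else
    data.frame(nucleus_id = integer(0), organoid_id = integer(0),
               well_id = character(0), plane = integer(0),
               area = numeric(0), mean_caspase = numeric(0),
               mean_pi = numeric(0), field_id = integer(0))
  # ids unique across planes/fields of the well
  if (nrow(organoids)) {
    key_o <- paste(organoids$field_id, organoids$plane,
                   organoids$organoid_id)
    organoids$organoid_uid <- match(key_o, unique(key_o))
  } else organoids$organoid_uid <- integer(0)
  if (nrow(nuclei)) {
    key_po <- paste(nuclei$field_id, nuclei$plane, nuclei$organoid_id)
    key_o <- paste(organoids$field_id, organoids$plane,
                   organoids$organoid_id)
    nuclei$organoid_uid <- organoids$organoid_uid[match(key_po, key_o)]
    key_n <- paste(nuclei$field_id, nuclei$plane, nuclei$nucleus_id)
    nuclei$nucleus_uid <- match(key_n, unique(key_n))
  } else {
    nuclei$organoid_uid <- integer(0); nuclei$nucleus_uid <- integer(0)
  }
  list(organoids = organoids, nuclei = nuclei)
}

#' Summarize one well's organoid load
#'
#' Aggregates the per-plane records of all processed fields of a well into
#' the three sampled load metrics: total nucleus count, mean organoid
#' cross-section area, and total organoid count (multiple plane
#' intersections of one organoid count separately). The sampled area is
#' `n_fields * field_area`.
#'
#' @param organoids,nuclei Record tables from [process_stack()] (rbind
#'   several fields' results for multi-field wells).
#' @param geometry The [acquisition_geometry()].
#' @param well_id Well identifier (defaults to the one in the records).
#' @return One-row data frame: `well_id`, `n_nuclei`, `mean_area`,
#'   `n_organoids`, `sampled_area`.
#' @export
quantify_well <- function(organoids, nuclei, geometry, well_id = NULL) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  n_fields <- length(unique(organoids$field_id))
  if (n_fields == 0 && nrow(organoids) == 0) {
    if (is.null(well_id)) stop("no fields processed for this well")
    n_fields <- geometry$n_fields
  }
  if (is.null(well_id))
    well_id <- if (nrow(organoids)) organoids$well_id[1] else NA_character_
  data.frame(well_id = well_id,
             n_nuclei = nrow(nuclei),
             mean_area = if (nrow(organoids)) mean(organoids$area) else
               NA_real_,
             n_organoids = nrow(organoids),
             sampled_area = geometry$n_fields * geometry$field_area)
}
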