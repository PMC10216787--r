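#' Segment organoids in one combined-channel plane
#'
#' Reproducible stand-in for the high-content instrument's organoid
#' detection: Gaussian blur (suppresses debris-derived fluorescence at the
#' organoid periphery), Otsu threshold, morphological closing and hole
#' filling, then a "region resize" (erosion followed by dilation of equal
#' radius, an opening that clips thin peripheral attachments), connected
#' components, and finally the area filter: regions below `min_area` um^2
#' (default 250, which removes single cells, small clumps and debris) are
#' never emitted. Regions touching the field border are retained but
#' flagged, since part of an organoid may simply lie outside the field.
#'
#' @param combined Combined-channel intensity matrix (see
#'   [combine_channels()]).
#' @param geometry The [acquisition_geometry()] (supplies the pixel size
#'   used to convert pixel counts to um^2).
#' @param gaussian_sigma Blur sigma in pixels (> 0).
#' @param resize_radius Radius in pixels of the erosion/dilation pair.
#' @param min_area Minimum organoid cross-section area in um^2.
#' @param threshold `"otsu"` or a numeric threshold on the blurred,
#'   max-normalized image (0-1 scale).
#' @param closing_radius Radius in pixels of the morphological closing
#'   that fuses the bright nuclei of one organoid into a single region;
#'   about the nucleus radius in pixels works well, and it must stay
#'   below half the organoid-to-organoid distance.
#' @return List with `labels` (integer matrix, 0 = background, regions
#'   numbered 1..n) and `organoids`, a data frame with one row per emitted
#'   region: `organoid_id`, `area` (um^2), `centroid_x`/`centroid_y` (um),
#'   `on_border`.
#' @export
segment_organoids <- function(combined, geometry, gaussian_sigma = 2,
                              resize_radius = 2, min_area = 250,
                              threshold = "otsu", closing_radius = 4) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  if (!is.numeric(gaussian_sigma) || gaussian_sigma <= 0)
    stop("gaussian_sigma must be positive")
  if (resize_radius < 0) stop("resize_radius must be non-negative")
  ps <- geometry$pixel_size
  empty <- list(labels = matrix(0L, nrow(combined), ncol(combined)),
                organoids = data.frame(organoid_id = integer(0),
                                       area = numeric(0),
                                       centroid_x = numeric(0),
                                       centroid_y = numeric(0),
                                       on_border = logical(0)))
  mx <- max(combined)
  if (mx <= 0) return(empty)

  sm <- EBImage::gblur(combined / mx, sigma = gaussian_sigma)
  sm[sm < 0] <- 0
  th <- if (identical(threshold, "otsu"))
    EBImage::otsu(EBImage::Image(sm), range = c(0, 1)) else threshold
  # guard against planes with no real foreground, where Otsu would split
  # the background noise itself: the threshold must clear the background
  # level (median + 6 * MAD of the blurred plane)
  th <- max(th, stats::median(sm) + 6 * stats::mad(sm))
  mask <- EBImage::Image(sm > th)
  if (sum(mask) == 0) return(empty)

  # closing bridges the gaps between the bright nuclei of one organoid so
  # the footprint is a single region; its radius must reach about half the
  # inter-nucleus spacing but stay below the organoid-to-organoid gap
  mask <- EBImage::closing(
    mask, EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc"))
  mask <- EBImage::fillHull(mask)
  if (resize_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(resize_radius) + 1L, "disc")
    mask <- EBImage::dilate(EBImage::erode(mask, brush), brush)
  }
  labels <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(labels) <- "integer"
  n <- max(labels)
  if (n == 0) return(empty)

  px_count <- tabulate(labels[labels > 0], nbins = n)
  area <- px_count * ps^2
  keep <- which(area >= min_area)
  if (!length(keep)) return(empty)

  relab <- integer(n)
  relab[keep] <- seq_along(keep)
  out_lab <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out_lab[pos] <- relab[labels[pos]]

  nr <- nrow(out_lab); nc <- ncol(out_lab)
  border_ids <- unique(c(out_lab[1, ], out_lab[nr, ], out_lab[, 1],
                         out_lab[, nc]))
  cx <- cy <- numeric(length(keep))
  idx <- which(out_lab > 0, arr.ind = TRUE)
  lab_at <- out_lab[out_lab > 0]
  cx <- tapply((idx[, 1] - 0.5) * ps, lab_at, mean)
  cy <- tapply((idx[, 2] - 0.5) * ps, lab_at, mean)
  list(labels = out_lab,
       organoids = data.frame(organoid_id = seq_along(keep),
                              area = area[keep],
                              centroid_x = as.numeric(cx),
                              centroid_y = as.numeric(cy),
                              on_border = seq_along(keep) %in% border_ids))
}

#' Segment nuclei within organoid regions of one plane
#'
#' Nuclei are searched only inside the organoid mask, via a
#' peak-seeded watershed on the lightly blurred Hoechst channel. Each
#' nucleus is assigned to exactly one organoid: the one containing its
#' centroid pixel, or (if rounding puts the centroid just outside every
#' region) the nearest organoid by boundary distance.
#'
#' @param hoechst Hoechst-channel intensity matrix for the plane.
#' @param organoid_labels Organoid label matrix from
#'   [segment_organoids()].
#' @param geometry The [acquisition_geometry()].
#' @param nucleus_sigma Expected nucleus blob sigma in um (sets the blur,
#'   the watershed neighbourhood and the minimum nucleus area).
#' @param tolerance Watershed intensity tolerance on the max-normalized
#'   image; peaks closer in height than this merge.
#' @return List with `labels` (nucleus label matrix) and `nuclei`, a data
#'   frame with `nucleus_id`, `organoid_id`, `area` (um^2),
#'   `centroid_x`/`centroid_y` (um).
#' @export
segment_nuclei <- function(hoechst, organoid_labels, geometry,
                           nucleus_sigma = 2.5, tolerance = 0.05) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  if (!all(dim(hoechst) == dim(organoid_labels)))
    stop("hoechst and organoid_labels shapes differ")
  ps <- geometry$pixel_size
  empty <- list(labels = matrix(0L, nrow(hoechst), ncol(hoechst)),
                nuclei = data.frame(nucleus_id = integer(0),
                                    organoid_id = integer(0),
                                    area = numeric(0),
                                    centroid_x = numeric(0),
                                    centroid_y = numeric(0)))
  inside <- organoid_labels > 0
  if (!any(inside) || max(hoechst) <= 0) return(empty)

  sigma_px <- nucleus_sigma / ps
  sm <- EBImage::gblur(hoechst / max(hoechst), sigma = max(1, sigma_px / 2))
  sm[!inside] <- 0
  labels <- EBImage::imageData(EBImage::watershed(
    EBImage::Image(sm), tolerance = tolerance,
    ext = max(1L, round(sigma_px))))
  storage.mode(labels) <- "integer"
  n <- max(labels)
  if (n == 0) return(empty)

  # drop fragments far smaller than a nucleus cross-section
  min_px <- max(4, pi * sigma_px^2 / 2)
  px_count <- tabulate(labels[labels > 0], nbins = n)
  keep <- which(px_count >= min_px)
  if (!length(keep)) return(empty)
  relab <- integer(n); relab[keep] <- seq_along(keep)
  out_lab <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out_lab[pos] <- relab[labels[pos]]

  idx <- which(out_lab > 0, arr.ind = TRUE)
  lab_at <- out_lab[out_lab > 0]
  cx_px <- tapply(idx[, 1], lab_at, mean)
  cy_px <- tapply(idx[, 2], lab_at, mean)
  org <- assign_to_organoid(cx_px, cy_px, organoid_labels)
  list(labels = out_lab,
       nuclei = data.frame(nucleus_id = seq_along(keep),
                           organoid_id = org,
                           area = px_count[keep] * ps^2,
                           centroid_x = (as.numeric(cx_px) - 0.5) * ps,
                           centroid_y = (as.numeric(cy_px) - 0.5) * ps))
}

# centroid-containment assignment with nearest-organoid fallback
assign_to_organoid <- function(cx_px, cy_px, organoid_labels) {
  ri <- pmin(pmax(round(cx_px), 1), nrow(organoid_labels))
  ci <- pmin(pmax(round(cy_px), 1), ncol(organoid_labels))
  org <- organoid_labels[cbind(ri, ci)]
  miss <- which(org == 0L)
  if (length(miss)) {
    opix <- which(organoid_labels > 0, arr.ind = TRUE)
    olab <- organoid_labels[organoid_labels > 0]
    for (m in miss) {
      d2 <- (opix[, 1] - cx_px[m])^2 + (opix[, 2] - cy_px[m])^2
      org[m] <- olab[which.min(d2)]
    }
  }
  as.integer(org)
}
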