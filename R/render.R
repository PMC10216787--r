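#' Render a synthetic scene into images and ground-truth labels
#'
#' Turns a [synthetic_scene()] into a three-channel z-stack plus per-plane
#' ground-truth label volumes. Each nucleus is drawn on its plane as an
#' isotropic 2D Gaussian blob (sigma from the scene, peak = the cell's
#' nominal channel intensity) with a linear plane-depth attenuation factor
#' `(1 - z_attenuation)^(plane - 1)`. The Hoechst channel is lit for every
#' nucleus; the Caspase and PI channels follow each cell's death mode.
#' Debris specks are drawn as bright discs in the Hoechst channel only and
#' carry no ground-truth label. Additive Gaussian background noise
#' (truncated at zero) is applied per the scene's `background` parameter.
#'
#' Ground truth: the nucleus label volume marks a disc of radius
#' `2 * nucleus_sigma` around each nucleus centre with its `cell_id`; the
#' organoid label volume marks the union of an organoid's nucleus discs
#' with its `organoid_id` (adjacent discs touch, so the footprint is
#' connected). Per-plane ground-truth organoid cross-section areas are
#' tabulated from the labels.
#'
#' Rendering is deterministic: the scene's seed drives the background
#' noise, so the same scene renders to bit-identical stacks every time.
#'
#' @param scene A [synthetic_scene()].
#' @param well_id,field_id Identifiers stamped on the returned stack.
#' @return An [image_stack()] with an extra `truth` element: a list with
#'   `organoid_labels` and `nucleus_labels` (integer arrays shaped like the
#'   channels), `cells` (the scene's cell table), `organoid_areas` (per
#'   organoid: largest cross-section area in um^2) and `plane_areas` (per
#'   organoid per plane).
#' @examples
#' geom <- geometry_from_pixels(128, pixel_size = 1, n_planes = 2)
#' sc <- synthetic_scene(geom, n_organoids = 1, nuclei_per_organoid = c(6, 6),
#'                       n_debris = 0, seed = 3)
#' st <- render_scene(sc)
#' range(st$channels$hoechst)
#' @export
render_scene <- function(scene, well_id = "W1", field_id = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  g <- scene$geometry
  px <- g$pixels
  if (px < 1) stop("invalid geometry: zero pixels")
  P <- g$n_planes
  ps <- g$pixel_size
  sigma_px <- scene$params$nucleus_sigma / ps
  atten <- (1 - scene$params$z_attenuation)^(seq_len(P) - 1)

  dims <- c(px, px, P)
  hoechst <- array(0, dims); caspase <- array(0, dims); pi_ch <- array(0, dims)
  org_lab <- array(0L, dims); nuc_lab <- array(0L, dims)

  w <- ceiling(4 * sigma_px)
  r_lab <- 2 * sigma_px
  for (i in seq_len(nrow(scene$cells))) {
    cl <- scene$cells[i, ]
    p <- cl$plane
    cx <- cl$x / ps + 0.5   # continuous pixel coords, centre of px 1 is 0.5
    cy <- cl$y / ps + 0.5
    ix <- max(1L, floor(cx - w)):min(px, ceiling(cx + w))
    iy <- max(1L, floor(cy - w)):min(px, ceiling(cy + w))
    if (!length(ix) || !length(iy)) next
    dx2 <- (ix - cx)^2
    dy2 <- (iy - cy)^2
    d2 <- outer(dx2, dy2, "+")
    blob <- exp(-d2 / (2 * sigma_px^2)) * atten[p]
    hoechst[ix, iy, p] <- hoechst[ix, iy, p] + cl$hoechst_mu * blob
    caspase[ix, iy, p] <- caspase[ix, iy, p] + cl$caspase_mu * blob
    pi_ch[ix, iy, p]   <- pi_ch[ix, iy, p]   + cl$pi_mu * blob
    disc <- d2 <= r_lab^2
    ol <- org_lab[ix, iy, p]; nl <- nuc_lab[ix, iy, p]
    ol[disc] <- cl$organoid_id
    nl[disc] <- cl$cell_id
    org_lab[ix, iy, p] <- ol; nuc_lab[ix, iy, p] <- nl
  }

  for (i in seq_len(nrow(scene$debris))) {
    db <- scene$debris[i, ]
    p <- db$plane
    cx <- db$x / ps + 0.5; cy <- db$y / ps + 0.5
    rpx <- db$radius / ps
    wd <- ceiling(rpx) + 1L
    ix <- max(1L, floor(cx - wd)):min(px, ceiling(cx + wd))
    iy <- max(1L, floor(cy - wd)):min(px, ceiling(cy + wd))
    if (!length(ix) || !length(iy)) next
    d2 <- outer((ix - cx)^2, (iy - cy)^2, "+")
    disc <- d2 <= rpx^2
    pl <- hoechst[ix, iy, p]
    pl[disc] <- pl[disc] + db$intensity * atten[p]
    hoechst[ix, iy, p] <- pl
  }

  bg <- scene$params$background
  if (any(bg > 0)) {
    set.seed(scene$rng_seed)
    n <- prod(dims)
    hoechst <- hoechst + pmax(0, stats::rnorm(n, bg[1], bg[2]))
    caspase <- caspase + pmax(0, stats::rnorm(n, bg[1], bg[2]))
    pi_ch   <- pi_ch   + pmax(0, stats::rnorm(n, bg[1], bg[2]))
  }

  plane_areas <- truth_plane_areas(org_lab, ps)
  organoid_areas <- if (nrow(plane_areas)) {
    agg <- stats::aggregate(area ~ organoid_id, plane_areas, max)
    names(agg)[2] <- "max_area"
    agg
  } else data.frame(organoid_id = integer(0), max_area = numeric(0))

  st <- image_stack(list(hoechst = hoechst, caspase = caspase, pi = pi_ch),
                    g, well_id = well_id, field_id = field_id)
  st$truth <- list(organoid_labels = org_lab, nucleus_labels = nuc_lab,
                   cells = scene$cells, plane_areas = plane_areas,
                   organoid_areas = organoid_areas)
  st
}

truth_plane_areas <- function(org_lab, pixel_size) {
  P <- dim(org_lab)[3]
  out <- vector("list", P)
  for (p in seq_len(P)) {
    tab <- table(org_lab[, , p][org_lab[, , p] > 0])
    if (length(tab))
      out[[p]] <- data.frame(organoid_id = as.integer(names(tab)),
                             plane = p,
                             area = as.numeric(tab) * pixel_size^2)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out)) do.call(rbind, out) else
    data.frame(organoid_id = integer(0), plane = integer(0),
               area = numeric(0))
}
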