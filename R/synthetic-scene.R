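#' Build a ground-truth synthetic organoid scene
#'
#' Constructs one field's worth of simulated biology: organoids as 3D
#' clusters of nuclei spread over neighbouring z-planes, each nucleus
#' carrying a death mode that determines its nominal Caspase 3/7 and
#' propidium iodide (PI) intensities, plus free-floating debris specks below
#' the organoid area filter. The scene is pure geometry and ground truth;
#' [render_scene()] turns it into images.
#'
#' Death modes map to dye intensities as in two-dye live/dead gating:
#' viable cells are low in both channels, apoptotic cells high Caspase / low
#' PI, necrotic cells low Caspase / high PI, late-apoptotic (secondary
#' necrotic) cells high in both. "Low" and "high" are lognormal
#' distributions whose arithmetic means are `intensity_low` and
#' `intensity_high` (default 10x apart, so gating is recoverable but the
#' channels still overlap in their tails).
#'
#' Nuclei are laid out on a hexagonal grid with spacing `4 * nucleus_sigma`
#' (centre-to-centre), so that the ground-truth nucleus discs of radius
#' `2 * nucleus_sigma` touch: the organoid footprint is connected while
#' individual nuclei remain separable. Organoids are placed with a
#' guaranteed gap between footprints and away from the field border.
#'
#' @param geometry An [acquisition_geometry()].
#' @param n_organoids Number of organoids in the field.
#' @param nuclei_per_organoid Length-2 integer range; each organoid's
#'   nucleus count is drawn uniformly from it.
#' @param death_probs Named probabilities for
#'   `c(viable, apoptotic, necrotic, late_apoptotic)`; must sum to 1.
#' @param intensity_low,intensity_high Arithmetic means of the lognormal
#'   "low" and "high" dye-intensity distributions (arbitrary units).
#' @param intensity_sdlog Log-scale SD of the intensity distributions.
#' @param hoechst_mean Mean nuclear Hoechst intensity (all nuclei).
#' @param nucleus_sigma Gaussian blob sigma in um (ground-truth nucleus
#'   disc radius is `2 * nucleus_sigma`).
#' @param n_debris Number of sub-threshold debris specks.
#' @param debris_area_range Range of debris areas in um^2; keep the upper
#'   end below the 250 um^2 organoid filter.
#' @param background Length-2 numeric `c(mean, sd)` of the additive
#'   background noise added at render time; `c(0, 0)` gives noiseless
#'   images.
#' @param z_attenuation Fractional intensity loss per plane of depth
#'   (default 2%), a linear stand-in for light scattering in the gel dome.
#' @param organoid_gap Minimum gap between organoid footprints in um.
#' @param seed Integer RNG seed; identical seeds give identical scenes and
#'   (through [render_scene()]) bit-identical images.
#'
#' @return An object of class `synthetic_scene`: a list with `geometry`,
#'   `cells` (one row per nucleus: ids, um coordinates, plane, death mode,
#'   nominal channel intensities), `organoids`, `debris`, `params` and
#'   `rng_seed`.
#' @seealso [render_scene()], [simulate_plate()]
#' @examples
#' geom <- geometry_from_pixels(160, pixel_size = 1, n_planes = 3)
#' sc <- synthetic_scene(geom, n_organoids = 2,
#'                       nuclei_per_organoid = c(8, 12), seed = 1)
#' table(sc$cells$death_mode)
#' @export
synthetic_scene <- function(geometry,
                            n_organoids = 5,
                            nuclei_per_organoid = c(10, 40),
                            death_probs = c(viable = 0.85, apoptotic = 0.05,
                                            necrotic = 0.05,
                                            late_apoptotic = 0.05),
                            intensity_low = 100,
                            intensity_high = 1000,
                            intensity_sdlog = 0.2,
                            hoechst_mean = 500,
                            nucleus_sigma = 2.5,
                            n_debris = 10,
                            debris_area_range = c(20, 150),
                            background = c(5, 2),
                            z_attenuation = 0.02,
                            organoid_gap = 15,
                            seed = 1L) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  if (abs(sum(death_probs) - 1) > 1e-8 || any(death_probs < 0))
    stop("death_probs must be non-negative and sum to 1")
  if (length(death_probs) != 4L)
    stop("death_probs must have 4 entries (viable, apoptotic, necrotic, late_apoptotic)")
  if (intensity_high < 5 * intensity_low)
    warning("intensity_high < 5 * intensity_low: gating recovery may degrade")
  if (n_organoids < 0 || n_debris < 0) stop("counts must be non-negative")
  if (seed >= 2^31 || seed < -2^31) stop("seed must fit a 32-bit integer")
  set.seed(seed)

  modes <- c("viable", "apoptotic", "necrotic", "late_apoptotic")
  side <- geometry$pixels * geometry$pixel_size   # field side, um
  spacing <- 4 * nucleus_sigma                    # nucleus grid spacing, um

  nuclei_per_organoid <- rep(nuclei_per_organoid, length.out = 2L)
  rng <- nuclei_per_organoid[1]:nuclei_per_organoid[2]
  n_nuc <- if (n_organoids == 0) integer(0) else
    if (length(rng) == 1L) rep(rng, n_organoids) else
      sample(rng, n_organoids, replace = TRUE)

  # spread each organoid over up to 3 neighbouring planes (a shallow dome
  # relative to the 25 um z-step), nuclei round-robin across its planes
  span <- pmin(3L, geometry$n_planes, pmax(1L, ceiling(n_nuc / 12)))
  per_plane_max <- as.numeric(ceiling(n_nuc / span))
  # footprint radius: outermost hex-grid nucleus plus its disc
  radius <- vapply(per_plane_max, function(n) {
    hp <- hex_positions(max(n, 1), spacing)
    sqrt(max(rowSums(hp^2))) + 2 * nucleus_sigma + 1
  }, numeric(1))

  centers <- place_centers(n_organoids, radius, side,
                           margin = radius + spacing, gap = organoid_gap)

  cells <- vector("list", n_organoids)
  organoids <- vector("list", n_organoids)
  for (k in seq_len(n_organoids)) {
    p0 <- sample.int(geometry$n_planes, 1)
    planes <- p0 + seq_len(span[k]) - ((span[k] + 1L) %/% 2L)
    planes <- ((planes - 1L) %% geometry$n_planes) + 1L
    plane_of <- rep(planes, length.out = n_nuc[k])
    pos <- matrix(0, n_nuc[k], 2)
    for (p in unique(plane_of)) {
      idx <- which(plane_of == p)
      hp <- hex_positions(length(idx), spacing)
      # small rotation per plane so stacked planes are not pixel-identical
      a <- stats::runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
      pos[idx, ] <- hp %*% rot
    }
    mode_k <- sample(modes, n_nuc[k], replace = TRUE, prob = death_probs)
    cells[[k]] <- data.frame(
      organoid_id = k,
      x = centers[k, 1] + pos[, 1],
      y = centers[k, 2] + pos[, 2],
      z = (plane_of - 1) * geometry$z_step,
      plane = plane_of,
      death_mode = mode_k,
      caspase_mu = draw_intensity(mode_k %in% c("apoptotic", "late_apoptotic"),
                                  intensity_low, intensity_high,
                                  intensity_sdlog),
      pi_mu = draw_intensity(mode_k %in% c("necrotic", "late_apoptotic"),
                             intensity_low, intensity_high, intensity_sdlog),
      hoechst_mu = stats::rlnorm(n_nuc[k],
                                 log(hoechst_mean) - intensity_sdlog^2 / 2,
                                 intensity_sdlog))
    organoids[[k]] <- data.frame(organoid_id = k, cx = centers[k, 1],
                                 cy = centers[k, 2], n_nuclei = n_nuc[k],
                                 radius = radius[k])
  }
  cells <- if (n_organoids > 0) do.call(rbind, cells) else
    data.frame(organoid_id = integer(0), x = numeric(0), y = numeric(0),
               z = numeric(0), plane = integer(0), death_mode = character(0),
               caspase_mu = numeric(0), pi_mu = numeric(0),
               hoechst_mu = numeric(0))
  if (nrow(cells)) cells <- cbind(cell_id = seq_len(nrow(cells)), cells)
  else cells <- cbind(cell_id = integer(0), cells)
  organoids <- if (n_organoids > 0) do.call(rbind, organoids) else
    data.frame(organoid_id = integer(0), cx = numeric(0), cy = numeric(0),
               n_nuclei = integer(0), radius = numeric(0))

  debris <- if (n_debris > 0) {
    area <- stats::runif(n_debris, debris_area_range[1], debris_area_range[2])
    r <- sqrt(area / pi)
    dpos <- place_debris(n_debris, r, side, centers, radius,
                         buffer = 2 * spacing)
    data.frame(x = dpos[, 1], y = dpos[, 2],
               plane = sample.int(geometry$n_planes, n_debris, replace = TRUE),
               radius = r, area = area,
               intensity = 1.5 * hoechst_mean)
  } else data.frame(x = numeric(0), y = numeric(0), plane = integer(0),
                    radius = numeric(0), area = numeric(0),
                    intensity = numeric(0))

  structure(list(geometry = geometry, cells = cells, organoids = organoids,
                 debris = debris,
                 params = list(nucleus_sigma = nucleus_sigma,
                               spacing = spacing,
                               intensity_low = intensity_low,
                               intensity_high = intensity_high,
                               intensity_sdlog = intensity_sdlog,
                               hoechst_mean = hoechst_mean,
                               background = background,
                               z_attenuation = z_attenuation,
                               death_probs = death_probs),
                 rng_seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d organoid(s), %d nuclei, %d debris speck(s), seed %d\n",
              nrow(x$organoids), nrow(x$cells), nrow(x$debris), x$rng_seed))
  print(x$geometry)
  invisible(x)
}

# hexagonal lattice positions around the origin, minimum pairwise distance
# = spacing, filled inside-out
hex_positions <- function(n, spacing) {
  if (n == 0) return(matrix(0, 0, 2))
  m <- ceiling(sqrt(n)) + 2L
  ij <- expand.grid(i = -m:m, j = -m:m)
  px <- (ij$i + 0.5 * (ij$j %% 2)) * spacing
  py <- ij$j * (sqrt(3) / 2) * spacing
  ord <- order(px^2 + py^2)
  cbind(px, py)[ord[seq_len(n)], , drop = FALSE]
}

# rejection-sample organoid centres: inside margins, pairwise footprint gap
place_centers <- function(n, radius, side, margin, gap) {
  if (n == 0) return(matrix(0, 0, 2))
  if (any(2 * margin >= side))
    stop("field too small for the requested organoids")
  centers <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in 1:5000) {
      cand <- stats::runif(2, margin[k], side - margin[k])
      prev <- seq_len(k - 1L)
      if (k == 1L || all(sqrt(colSums((t(centers[prev, , drop = FALSE]) -
                                        cand)^2)) >=
                         radius[prev] + radius[k] + gap)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("field too crowded: could not place organoid ", k)
    centers[k, ] <- cand
  }
  centers
}

# debris kept clear of organoid footprints and of each other, so specks
# never fuse with an organoid (or together) into a filter-passing region
place_debris <- function(n, r, side, centers, radius, buffer) {
  pos <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    for (try in 1:5000) {
      cand <- stats::runif(2, r[k] + 1, side - r[k] - 1)
      clear_org <- nrow(centers) == 0 ||
        all(sqrt(colSums((t(centers) - cand)^2)) >= radius + r[k] + buffer)
      prev <- seq_len(k - 1L)
      clear_deb <- k == 1L ||
        all(sqrt(colSums((t(pos[prev, , drop = FALSE]) - cand)^2)) >=
              r[prev] + r[k] + buffer)
      if (clear_org && clear_deb) break
      if (try == 5000) stop("could not place debris away from organoids")
    }
    pos[k, ] <- cand
  }
  pos
}

draw_intensity <- function(high, low_mean, high_mean, sdlog) {
  mu <- ifelse(high, high_mean, low_mean)
  stats::rlnorm(length(high), log(mu) - sdlog^2 / 2, sdlog)
}
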