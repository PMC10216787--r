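#' Read and validate a plate map
#'
#' A plate map assigns every well a treatment, dose, imaging/reading day
#' and control role. Required columns: `well`, `treatment`, `dose`,
#' `control_role`; optional: `plate`, `day`, `dose_unit`, `vehicle`.
#' `control_role` must be one of `untreated`, `vehicle_dmso`,
#' `vehicle_ethanol`, `staurosporine`, `none`. Duplicate wells are an
#' error naming the offending well(s). When a `vehicle` column is present
#' (`dmso`/`ethanol`/`none` per treated well), each treated well's vehicle
#' must exist among the plate's vehicle-control wells.
#'
#' @param path CSV file path.
#' @return Validated data frame of class `plate_map`.
#' @export
read_platemap <- function(path) {
  pm <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_platemap(pm)
}

#' @rdname read_platemap
#' @param platemap A data frame to validate in place of a file.
#' @export
validate_platemap <- function(platemap) {
  need <- c("well", "treatment", "dose", "control_role")
  miss <- setdiff(need, names(platemap))
  if (length(miss))
    stop("plate map is missing column(s): ", paste(miss, collapse = ", "))
  key <- if ("plate" %in% names(platemap))
    paste(platemap$plate, platemap$well) else platemap$well
  dup <- unique(platemap$well[duplicated(key)])
  if (length(dup))
    stop("duplicate well(s) in plate map: ", paste(dup, collapse = ", "))
  roles <- c("untreated", "vehicle_dmso", "vehicle_ethanol",
             "staurosporine", "none")
  bad <- setdiff(unique(platemap$control_role), roles)
  if (length(bad))
    stop("unknown control_role value(s): ", paste(bad, collapse = ", "))
  if (any(platemap$dose < 0)) stop("doses must be non-negative")
  if ("vehicle" %in% names(platemap)) {
    treated <- platemap$control_role == "none"
    for (v in setdiff(unique(platemap$vehicle[treated]), c("none", NA))) {
      if (!any(platemap$control_role == paste0("vehicle_", v)))
        stop("treated wells use vehicle '", v,
             "' but no vehicle_", v, " control well exists")
    }
  }
  class(platemap) <- c("plate_map", "data.frame")
  platemap
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are stored channel-major (all planes of hoechst, then caspase,
#' then pi) as 32-bit float TIFF. Because TIFF stores values in [0, 1],
#' intensities are divided by a global scale factor recorded in the JSON
#' sidecar (`<prefix>.json`) together with the geometry, identifiers and
#' channel order, and multiplied back on read. If the stack carries ground
#' truth, the label volumes are written as 16-bit label TIFFs
#' (`<prefix>_organoid_labels.tif`, `<prefix>_nucleus_labels.tif`).
#'
#' @param stack An [image_stack()].
#' @param prefix Output path prefix (without extension).
#' @param write_truth Also write ground-truth label TIFFs when available.
#' @return `write_image_stack()` returns the prefix invisibly;
#'   `read_image_stack()` returns an [image_stack()].
#' @export
write_image_stack <- function(stack, prefix, write_truth = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  g <- stack$geometry
  scale <- max(1, vapply(stack$channels, max, numeric(1)))
  pages <- list()
  for (ch in c("hoechst", "caspase", "pi"))
    for (p in seq_len(g$n_planes))
      pages[[length(pages) + 1L]] <- stack$channels[[ch]][, , p] / scale
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 32L,
                  reduce = TRUE)
  sidecar <- list(well_id = stack$well_id, field_id = stack$field_id,
                  channel_order = c("hoechst", "caspase", "pi"),
                  intensity_scale = scale,
                  geometry = list(field_area = g$field_area,
                                  n_planes = g$n_planes, z_step = g$z_step,
                                  pixel_size = g$pixel_size,
                                  n_fields = g$n_fields))
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (write_truth && !is.null(stack$truth)) {
    write_labels <- function(lab, path) {
      mx <- max(1, max(lab))
      pg <- lapply(seq_len(dim(lab)[3]), function(p) lab[, , p] / 65535)
      tiff::writeTIFF(pg, path, bits.per.sample = 16L, reduce = FALSE)
      invisible(mx)
    }
    write_labels(stack$truth$organoid_labels,
                 paste0(prefix, "_organoid_labels.tif"))
    write_labels(stack$truth$nucleus_labels,
                 paste0(prefix, "_nucleus_labels.tif"))
  }
  invisible(prefix)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  g <- do.call(acquisition_geometry, sidecar$geometry)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  P <- g$n_planes
  if (length(pages) != 3L * P)
    stop("expected ", 3L * P, " TIFF pages, found ", length(pages))
  mk <- function(off) {
    a <- array(0, c(g$pixels, g$pixels, P))
    for (p in seq_len(P)) a[, , p] <- pages[[off + p]] *
        sidecar$intensity_scale
    a
  }
  channels <- list(hoechst = mk(0L), caspase = mk(P), pi = mk(2L * P))
  image_stack(channels, g, well_id = sidecar$well_id,
              field_id = sidecar$field_id)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the analysis in one serializable list:
#' segmentation (`gaussian_sigma` px, `resize_radius` px, `min_area`
#' um^2, `threshold`, `nucleus_sigma` um, `tolerance`), gating (`scale`,
#' `angles`, `calibrate`, `coverage`, positive-control `margin`), QC
#' thresholds (`growth`, `cv`, `z`, `dmso`), and the RNG `seed`.
#' Configurations round-trip losslessly through JSON with
#' [write_config()] / [read_config()].
#'
#' @param ... Named overrides of any default entry (nested lists are
#'   merged).
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    segmentation = list(gaussian_sigma = 2, resize_radius = 2,
                        min_area = 250, threshold = "otsu",
                        nucleus_sigma = 2.5, tolerance = 0.05),
    gating = list(scale = "linear",
                  angles = list(apoptotic = 30, necrotic = 60),
                  calibrate = "none", coverage = 0.5, margin = 0.2),
    qc = list(growth = 1.5, cv = 0.22, z = 0.4, dmso = c(0.8, 1.2)),
    seed = 1L)
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' @rdname default_config
#' @param config A `run_config` list.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' @rdname default_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
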