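#' Viable-cell intensity thresholds from day-0 controls
#'
#' The viable gate is calibrated on untreated day-0 control nuclei: the
#' threshold in each channel is `mean + 2 * SD` of the nuclear mean
#' intensities, computed on the configured scale (`linear`, or `log` for
#' mean and SD of log10 intensities, in which case the returned thresholds
#' are in log10 units). A nucleus below both thresholds is called viable.
#'
#' @param records Data frame of nucleus records with `mean_caspase` and
#'   `mean_pi` (e.g. from [extract_intensities()]).
#' @param scale `"linear"` or `"log"`.
#' @return Named numeric vector `c(t_caspase, t_pi)` on the chosen scale.
#' @examples
#' r <- data.frame(mean_caspase = c(1, 2, 3), mean_pi = c(2, 4, 6))
#' fit_viable_thresholds(r)   # c(4, 8): mean + 2 * sample SD
#' @export
fit_viable_thresholds <- function(records, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (nrow(records) < 2)
    stop("at least 2 nuclei are required (SD undefined otherwise)")
  ca <- gate_transform(records$mean_caspase, scale)
  pi_ <- gate_transform(records$mean_pi, scale)
  c(t_caspase = mean(ca) + 2 * stats::sd(ca),
    t_pi = mean(pi_) + 2 * stats::sd(pi_))
}

gate_transform <- function(x, scale) {
  if (scale == "log") {
    if (any(x <= 0)) stop("log scale requires strictly positive intensities")
    log10(x)
  } else x
}

#' Fit the four-population gating model
#'
#' Dead cells (above either viable threshold) are split into apoptotic,
#' late-apoptotic and necrotic sectors by two straight gate lines anchored
#' at the intersection of the viable thresholds `(t_caspase, t_pi)`. The
#' line angles are measured in degrees from the caspase axis:
#' `theta_apoptotic` bounds the caspase-dominant (apoptotic) sector from
#' below and `theta_necrotic` bounds the PI-dominant (necrotic) sector
#' from above, so `0 < theta_apoptotic <= theta_necrotic < 90` and points
#' between the lines are late-apoptotic.
#'
#' Angles are either fixed (defaults 30 and 60 degrees) or calibrated on
#' day-10 untreated controls, whose dead-cell population spans all three
#' modes. Calibration works on the angular positions of dead cells about
#' the anchor: `"cluster"` (default when calibrating) partitions the
#' angles into three groups with a deterministic 1-D k-means (centers
#' initialised at the 1/6, 1/2, 5/6 angle quantiles) and places the gate
#' lines midway between adjacent group centers; `"quantile"` places them
#' at the quantiles bounding the central `coverage` fraction of the dead
#' cells. If the day-10 controls contain no dead cells, the default
#' angles are used with a warning.
#'
#' @param day10_controls Data frame of day-10 untreated-control nucleus
#'   records (may be `NULL` when `calibrate = "none"`).
#' @param thresholds Output of [fit_viable_thresholds()].
#' @param scale Intensity scale the thresholds were computed on.
#' @param angles Named vector `c(apoptotic, necrotic)` of fixed gate
#'   angles in degrees.
#' @param calibrate `"none"`, `"cluster"` or `"quantile"`.
#' @param coverage Central dead-cell fraction bounded by the lines in
#'   `"quantile"` mode.
#' @return An object of class `gating_model`.
#' @seealso [classify_nuclei()], [summarize_death()]
#' @export
fit_gate_lines <- function(day10_controls = NULL, thresholds,
                           scale = c("linear", "log"),
                           angles = c(apoptotic = 30, necrotic = 60),
                           calibrate = c("none", "cluster", "quantile"),
                           coverage = 0.5) {
  scale <- match.arg(scale)
  calibrate <- match.arg(calibrate)
  stopifnot(all(c("t_caspase", "t_pi") %in% names(thresholds)))
  theta <- c(apoptotic = unname(angles[["apoptotic"]]),
             necrotic = unname(angles[["necrotic"]]))
  provenance <- "fixed angles"
  if (calibrate != "none") {
    a <- dead_cell_angles(day10_controls, thresholds, scale)
    if (length(a) == 0) {
      warning("no dead cells in day-10 controls; keeping default angles")
    } else if (calibrate == "quantile") {
      q <- stats::quantile(a, c((1 - coverage) / 2, 1 - (1 - coverage) / 2),
                           names = FALSE)
      theta <- c(apoptotic = q[1], necrotic = q[2])
      provenance <- sprintf("quantile calibration (coverage %.2f, n = %d)",
                            coverage, length(a))
    } else {
      init <- stats::quantile(a, c(1 / 6, 1 / 2, 5 / 6), names = FALSE)
      km <- stats::kmeans(a, centers = matrix(init, 3, 1))
      cen <- sort(km$centers[, 1])
      theta <- c(apoptotic = mean(cen[1:2]), necrotic = mean(cen[2:3]))
      provenance <- sprintf("3-cluster calibration (n = %d)", length(a))
    }
  }
  if (!(theta[["apoptotic"]] > 0 && theta[["necrotic"]] < 90 &&
        theta[["apoptotic"]] <= theta[["necrotic"]]))
    stop("gate angles must satisfy 0 < apoptotic <= necrotic < 90")
  structure(list(t_caspase = unname(thresholds[["t_caspase"]]),
                 t_pi = unname(thresholds[["t_pi"]]),
                 theta_apoptotic = unname(theta[["apoptotic"]]),
                 theta_necrotic = unname(theta[["necrotic"]]),
                 scale = scale, calibration = provenance,
                 n_day10 = if (is.null(day10_controls)) 0L else
                   nrow(day10_controls)),
            class = "gating_model")
}

# angular position (degrees from the caspase axis) of dead cells about the
# threshold anchor; coordinates clipped at the anchor's axes
dead_cell_angles <- function(records, thresholds, scale) {
  if (is.null(records) || nrow(records) == 0) return(numeric(0))
  ca <- gate_transform(records$mean_caspase, scale)
  pi_ <- gate_transform(records$mean_pi, scale)
  dead <- ca > thresholds[["t_caspase"]] | pi_ > thresholds[["t_pi"]]
  dx <- pmax(ca[dead] - thresholds[["t_caspase"]], 0)
  dy <- pmax(pi_[dead] - thresholds[["t_pi"]], 0)
  atan2(dy, dx) * 180 / pi
}

#' Classify nuclei into the four death-gating populations
#'
#' A nucleus is `viable` iff its mean Caspase and mean PI intensities are
#' both at or below their thresholds (negative for both dyes). Dead
#' nuclei are subdivided by the angle of `(caspase - t_caspase,
#' pi - t_pi)` about the anchor, with coordinates clipped at zero so that
#' points exceeding only one threshold map onto the corresponding axis:
#' `apoptotic` below the apoptotic line (angle < `theta_apoptotic`,
#' caspase-dominant), `necrotic` above the necrotic line (angle >
#' `theta_necrotic`, PI-dominant), `late_apoptotic` between the lines
#' (inclusive).
#'
#' @param records Data frame with `mean_caspase`, `mean_pi`.
#' @param model A fitted [gating_model][fit_gate_lines()].
#' @return Factor with levels `viable`, `apoptotic`, `necrotic`,
#'   `late_apoptotic`, one per record row.
#' @export
classify_nuclei <- function(records, model) {
  if (!inherits(model, "gating_model")) stop("model must be a gating_model")
  ca <- gate_transform(records$mean_caspase, model$scale)
  pi_ <- gate_transform(records$mean_pi, model$scale)
  lev <- c("viable", "apoptotic", "necrotic", "late_apoptotic")
  if (!length(ca)) return(factor(character(0), levels = lev))
  viable <- ca <= model$t_caspase & pi_ <= model$t_pi
  dx <- pmax(ca - model$t_caspase, 0)
  dy <- pmax(pi_ - model$t_pi, 0)
  ang <- atan2(dy, dx) * 180 / pi
  cls <- ifelse(viable, "viable",
                ifelse(ang < model$theta_apoptotic, "apoptotic",
                       ifelse(ang > model$theta_necrotic, "necrotic",
                              "late_apoptotic")))
  factor(cls, levels = lev)
}

#' @export
predict.gating_model <- function(object, newdata, ...) {
  classify_nuclei(newdata, object)
}

#' @export
print.gating_model <- function(x, ...) {
  cat("Four-population death gating model\n")
  cat(sprintf("  viable thresholds (%s scale): caspase <= %.4g, PI <= %.4g\n",
              x$scale, x$t_caspase, x$t_pi))
  cat(sprintf("  gate lines from anchor: apoptotic %.1f deg, necrotic %.1f deg (%s)\n",
              x$theta_apoptotic, x$theta_necrotic, x$calibration))
  invisible(x)
}

#' Scatter plot of nuclei with gate overlays
#'
#' @param x A [gating_model][fit_gate_lines()].
#' @param records Optional nucleus records to draw, coloured by class.
#' @param ... Passed to [plot()].
#' @export
plot.gating_model <- function(x, records = NULL, ...) {
  cols <- c(viable = "#2c7bb6", apoptotic = "#1a9641",
            necrotic = "#d7191c", late_apoptotic = "#fdae61")
  if (!is.null(records) && nrow(records)) {
    ca <- gate_transform(records$mean_caspase, x$scale)
    pi_ <- gate_transform(records$mean_pi, x$scale)
    cls <- classify_nuclei(records, x)
    plot(ca, pi_, col = cols[as.character(cls)], pch = 16, cex = 0.5,
         xlab = "mean Caspase 3/7 intensity", ylab = "mean PI intensity",
         ...)
  } else {
    plot(NA, xlim = c(0, 2 * x$t_caspase), ylim = c(0, 2 * x$t_pi),
         xlab = "mean Caspase 3/7 intensity", ylab = "mean PI intensity",
         ...)
  }
  usr <- graphics::par("usr")
  graphics::segments(x$t_caspase, 0, x$t_caspase, x$t_pi, lty = 2)
  graphics::segments(0, x$t_pi, x$t_caspase, x$t_pi, lty = 2)
  for (th in c(x$theta_apoptotic, x$theta_necrotic)) {
    r <- max(usr[2] - x$t_caspase, usr[4] - x$t_pi) * 2
    graphics::segments(x$t_caspase, x$t_pi,
                       x$t_caspase + r * cos(th * pi / 180),
                       x$t_pi + r * sin(th * pi / 180))
  }
  invisible(x)
}

#' Per-well death-population counts
#'
#' Counts and fractions of the four populations for one well's nucleus
#' records. Classes are exhaustive and mutually exclusive, so counts sum
#' to the number of records and fractions to 1.
#'
#' @param records Nucleus records of one well.
#' @param model A fitted [gating_model][fit_gate_lines()].
#' @param well_id Optional well identifier (defaults to the records').
#' @return One-row data frame: `well_id`, `n_total`, `n_viable`,
#'   `n_apoptotic`, `n_necrotic`, `n_late`, and fractions `f_*`.
#' @export
summarize_death <- function(records, model, well_id = NULL) {
  cls <- classify_nuclei(records, model)
  n <- table(cls)
  total <- length(cls)
  if (is.null(well_id))
    well_id <- if (total && "well_id" %in% names(records))
      records$well_id[1] else NA_character_
  fr <- if (total) as.numeric(n) / total else rep(NA_real_, 4)
  data.frame(well_id = well_id, n_total = total,
             n_viable = as.integer(n[["viable"]]),
             n_apoptotic = as.integer(n[["apoptotic"]]),
             n_necrotic = as.integer(n[["necrotic"]]),
             n_late = as.integer(n[["late_apoptotic"]]),
             f_viable = fr[1], f_apoptotic = fr[2], f_necrotic = fr[3],
             f_late = fr[4])
}

#' Validate cell-death detection with the staurosporine positive control
#'
#' Staurosporine-exposed replicates must show substantially more dead
#' cells than untreated replicates for the gating read-out to be trusted.
#' The check passes iff the mean dead fraction (1 - viable fraction)
#' across staurosporine wells exceeds that of untreated wells by at least
#' `margin` (absolute).
#'
#' @param stauro_records,untreated_records Nucleus records of the
#'   positive-control and untreated wells (with `well_id`).
#' @param model A fitted [gating_model][fit_gate_lines()].
#' @param margin Required absolute difference in mean dead fraction.
#' @return List with `pass`, `dead_fraction_stauro`,
#'   `dead_fraction_untreated`, and the per-well fractions.
#' @export
validate_positive_control <- function(stauro_records, untreated_records,
                                      model, margin = 0.2) {
  if (!nrow(stauro_records) || !nrow(untreated_records))
    stop("both well sets must be non-empty")
  dead_frac <- function(records) {
    sp <- split(records, records$well_id)
    vapply(sp, function(r)
      1 - mean(classify_nuclei(r, model) == "viable"), numeric(1))
  }
  fs <- dead_frac(stauro_records)
  fu <- dead_frac(untreated_records)
  list(pass = mean(fs) - mean(fu) >= margin,
       dead_fraction_stauro = mean(fs),
       dead_fraction_untreated = mean(fu),
       per_well_stauro = fs, per_well_untreated = fu,
       margin = margin)
}
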