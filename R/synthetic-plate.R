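#' Four-parameter logistic dose-response function
#'
#' `v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)` — the
#' "log(inhibitor) vs response, variable slope" model. At `d = 0` the
#' response is `top` (the limit for positive `hill`); at `d = ic50` it is
#' the midpoint `(top + bottom) / 2`.
#'
#' @param dose Non-negative dose(s).
#' @param top,bottom Upper and lower asymptotes.
#' @param ic50 Dose of half-maximal effect (> 0).
#' @param hill Hill slope (> 0 for an inhibitor).
#' @return Response values, same length as `dose`.
#' @export
fourpl <- function(dose, top, bottom, ic50, hill) {
  if (ic50 <= 0) stop("ic50 must be positive")
  out <- bottom + (top - bottom) / (1 + (dose / ic50)^hill)
  out[dose == 0] <- top
  out
}

#' Ground truth for a simulated viability plate
#'
#' Defines the generative model of a whole-well viability experiment: a
#' plate layout (which well gets which treatment, dose and control role), a
#' true 4PL dose-response, multiplicative per-day growth of the untreated
#' signal, and lognormal well-to-well noise of a given coefficient of
#' variation.
#'
#' @param layout Data frame with columns `well`, `treatment`, `dose`,
#'   `control_role`; `control_role` is one of `untreated`, `vehicle_dmso`,
#'   `vehicle_ethanol`, `staurosporine`, `none`. At least one negative
#'   control (untreated or vehicle) and one positive control
#'   (staurosporine) are required.
#' @param true_4pl Named list `top, bottom, ic50, hill` of the true
#'   dose-response of normalized viability.
#' @param baseline Untreated well signal at day 0 (arbitrary luminescence
#'   units).
#' @param growth_rate Per-day multiplicative growth of the untreated
#'   signal; the default doubles viability over the 10-day exposure.
#' @param noise_cv Relative SD of replicate wells (lognormal noise);
#'   must be >= 0.
#' @param stauro_factor Residual signal fraction of staurosporine-killed
#'   wells at day 10.
#' @param seed Integer RNG seed.
#' @return Object of class `plate_truth`.
#' @export
plate_truth <- function(layout,
                        true_4pl = list(top = 1, bottom = 0.1, ic50 = 1,
                                        hill = 1),
                        baseline = 100,
                        growth_rate = 2^(1 / 10),
                        noise_cv = 0.1,
                        stauro_factor = 0.05,
                        seed = 1L) {
  need <- c("well", "treatment", "dose", "control_role")
  if (!all(need %in% names(layout)))
    stop("layout must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(layout$well))
    stop("duplicate wells in layout")
  if (any(layout$dose < 0)) stop("doses must be non-negative")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  roles <- layout$control_role
  if (!any(roles %in% c("untreated", "vehicle_dmso", "vehicle_ethanol")))
    stop("at least one negative-control well is required")
  if (!any(roles == "staurosporine"))
    stop("at least one positive-control (staurosporine) well is required")
  stopifnot(growth_rate > 0, baseline > 0)
  structure(list(layout = layout, true_4pl = true_4pl, baseline = baseline,
                 growth_rate = growth_rate, noise_cv = noise_cv,
                 stauro_factor = stauro_factor, rng_seed = as.integer(seed)),
            class = "plate_truth")
}

#' Simulate whole-well viability readings for a plate
#'
#' The untreated signal at day `d` is
#' `baseline * growth_rate^d * lognormal noise` (noise has mean 1 and
#' relative SD `noise_cv`; with `noise_cv = 0` readings are exact). Drug
#' exposure starts at day 0: before day 0 all wells read as untreated; at
#' later days a treated well's signal is scaled by the true 4PL response at
#' its dose, a staurosporine well by `stauro_factor`, and negative-control
#' wells are unscaled.
#'
#' @param truth A [plate_truth()].
#' @param timepoints Day offsets at which plates are read (default the
#'   seeding / exposure-start / exposure-end design `c(-4, 0, 10)`).
#' @param plate_id Identifier stamped on all rows.
#' @return Tidy data frame: `plate, well, day, treatment, dose,
#'   control_role, reading`.
#' @examples
#' lay <- data.frame(well = c("A1", "A2", "B1"),
#'                   treatment = c("none", "none", "drugX"),
#'                   dose = c(0, 0, 1),
#'                   control_role = c("untreated", "staurosporine", "none"))
#' tr <- plate_truth(lay, noise_cv = 0, seed = 2)
#' simulate_plate(tr, timepoints = c(0, 10))
#' @export
simulate_plate <- function(truth, timepoints = c(-4, 0, 10),
                           plate_id = "P1") {
  stopifnot(inherits(truth, "plate_truth"))
  set.seed(truth$rng_seed)
  lay <- truth$layout
  p4 <- truth$true_4pl
  sdlog <- sqrt(log(1 + truth$noise_cv^2))
  out <- vector("list", length(timepoints))
  for (j in seq_along(timepoints)) {
    d <- timepoints[j]
    base <- truth$baseline * truth$growth_rate^d
    fac <- rep(1, nrow(lay))
    if (d > 0) {
      treated <- lay$control_role == "none"
      fac[treated] <- fourpl(lay$dose[treated], p4$top, p4$bottom, p4$ic50,
                             p4$hill)
      fac[lay$control_role == "staurosporine"] <- truth$stauro_factor
    }
    noise <- if (truth$noise_cv > 0)
      stats::rlnorm(nrow(lay), -sdlog^2 / 2, sdlog) else 1
    out[[j]] <- data.frame(plate = plate_id, well = lay$well, day = d,
                           treatment = lay$treatment, dose = lay$dose,
                           control_role = lay$control_role,
                           reading = base * fac * noise)
  }
  do.call(rbind, out)
}
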