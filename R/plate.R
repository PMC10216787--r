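#' Normalize viability readings to vehicle controls
#'
#' Divides every reading by the mean of the vehicle (negative-control)
#' readings, so vehicle wells average 1.
#'
#' @param readings Numeric vector of well readings.
#' @param vehicle_readings Numeric vector of vehicle-well readings.
#' @return Normalized readings.
#' @export
normalize_viability <- function(readings, vehicle_readings) {
  m <- mean(vehicle_readings)
  if (!is.finite(m) || m <= 0)
    stop("vehicle mean must be positive")
  readings / m
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the log(inhibitor)-vs-response model with variable
#' slope, `v(d) = bottom + (top - bottom) / (1 + 10^(hill * (log10 d -
#' log10 ic50)))`, to normalized viability. Vehicle (dose 0) points are
#' excluded from the fit — they enter only through normalization. Starting
#' values come from the data: the asymptotes from the mean response at the
#' extreme doses, the IC50 from the dose whose response is closest to the
#' midpoint, and hill = 1. Non-convergence and unidentifiable (flat)
#' responses are reported via the `converged` flag, never as an error.
#'
#' @param dose Dose vector (non-negative; zeros are dropped).
#' @param response Normalized viability, same length.
#' @return Object of class `dose_response_fit` with elements `top`,
#'   `bottom`, `ic50`, `hill`, `rss`, `converged`, `note`, `data`.
#' @examples
#' d <- rep(10^seq(-2, 2, length.out = 8), each = 2)
#' y <- fourpl(d, 1, 0.05, 0.7, 1.2)
#' fit <- fit_dose_response(d, y)
#' coef(fit)
#' @export
fit_dose_response <- function(dose, response) {
  stopifnot(length(dose) == length(response))
  keep <- dose > 0 & is.finite(response)
  d <- dose[keep]; y <- response[keep]
  if (length(unique(d)) < 4)
    stop("at least 4 distinct nonzero doses are required")
  out <- list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
              hill = NA_real_, rss = NA_real_, converged = FALSE,
              note = "", data = data.frame(dose = d, response = y))
  class(out) <- "dose_response_fit"
  if (stats::sd(y) < 1e-8) {
    out$top <- out$bottom <- mean(y)
    out$rss <- sum((y - mean(y))^2)
    out$note <- "flat response: parameters unidentifiable"
    return(out)
  }
  ld <- log10(d)
  mu <- tapply(y, ld, mean)
  lds <- as.numeric(names(mu))
  top0 <- unname(mu[which.min(lds)])
  bottom0 <- unname(mu[which.max(lds)])
  mid <- (top0 + bottom0) / 2
  lic0 <- lds[which.min(abs(mu - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - lic))),
      start = list(top = top0, bottom = bottom0, lic = lic0, hill = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out$note <- paste("fit failed:", conditionMessage(fit))
    return(out)
  }
  cf <- stats::coef(fit)
  out$top <- unname(cf["top"]); out$bottom <- unname(cf["bottom"])
  out$ic50 <- 10^unname(cf["lic"]); out$hill <- unname(cf["hill"])
  out$rss <- sum(stats::resid(fit)^2)
  out$converged <- fit$convInfo$isConv %||% TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, ic50 = object$ic50,
    hill = object$hill)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose else
    if (is.data.frame(newdata)) newdata$dose else newdata
  fourpl(d, object$top, object$bottom, object$ic50, object$hill)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("4PL dose-response fit\n")
  if (x$converged) {
    cat(sprintf("  top %.4g  bottom %.4g  IC50 %.4g  hill %.4g  (RSS %.3g)\n",
                x$top, x$bottom, x$ic50, x$hill, x$rss))
  } else {
    cat("  not converged", if (nzchar(x$note)) paste0(" - ", x$note), "\n")
  }
  invisible(x)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  plot(x$data$dose, x$data$response, log = "x", xlab = "dose",
       ylab = "normalized viability", ...)
  if (x$converged) {
    dd <- 10^seq(log10(min(x$data$dose)), log10(max(x$data$dose)),
                 length.out = 200)
    graphics::lines(dd, predict(x, dd))
  }
  invisible(x)
}

#' Plate acceptance quality control
#'
#' Computes the four plate-level quality metrics on raw readings and their
#' pass/fail verdicts:
#' \itemize{
#'   \item growth ratio = mean(day-10 untreated) / mean(day-0 untreated);
#'     rule: >= 1.5 (only actively proliferating cultures are
#'     interpretable);
#'   \item CV = sample SD / mean of day-10 negative-control readings;
#'     rule: < 0.22;
#'   \item Z-factor = `1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`
#'     from day-10 negative vs staurosporine positive controls; rule:
#'     > 0.4; marked not-applicable if positives are missing;
#'   \item DMSO effect = mean(DMSO vehicle) / mean(untreated) on day 10;
#'     rule: within [0.8, 1.2]; not-applicable without DMSO wells.
#' }
#' The overall verdict passes iff every applicable rule passes. Boundary
#' conventions follow the printed rules: growth and DMSO inclusive, CV
#' and Z-factor strict.
#'
#' @param readings Data frame with columns `well`, `day`, `reading` and
#'   `control_role` (the latter may instead be joined from `platemap` by
#'   `well`).
#' @param platemap Optional platemap data frame (`well`, `control_role`,
#'   ...) used to annotate `readings`.
#' @param thresholds Named list overriding the rule thresholds
#'   (`growth`, `cv`, `z`, `dmso` = length-2 bounds).
#' @param day0,day10 Day values identifying the baseline and endpoint
#'   reads.
#' @return Object of class `plate_qc`: metrics, per-rule verdicts
#'   (`TRUE`/`FALSE`/`NA` for not-applicable) and the overall `pass`.
#' @examples
#' r <- data.frame(well = sprintf("A%d", 1:9),
#'                 day = rep(c(0, 10, 10), each = 3),
#'                 reading = c(100, 95, 105, 190, 200, 210, 9, 10, 11),
#'                 control_role = rep(c("untreated", "untreated",
#'                                      "staurosporine"), each = 3))
#' compute_qc(r)
#' @export
compute_qc <- function(readings, platemap = NULL,
                       thresholds = list(growth = 1.5, cv = 0.22, z = 0.4,
                                         dmso = c(0.8, 1.2)),
                       day0 = 0, day10 = 10) {
  need <- c("well", "day", "reading")
  if (!all(need %in% names(readings)))
    stop("readings must have columns: ", paste(need, collapse = ", "))
  if (!"control_role" %in% names(readings)) {
    if (is.null(platemap))
      stop("control_role missing: supply it in readings or via platemap")
    readings$control_role <-
      platemap$control_role[match(readings$well, platemap$well)]
  }
  th <- utils::modifyList(list(growth = 1.5, cv = 0.22, z = 0.4,
                               dmso = c(0.8, 1.2)), thresholds)
  neg_roles <- c("untreated", "vehicle_dmso", "vehicle_ethanol")
  r0u <- readings$reading[readings$day == day0 &
                            readings$control_role == "untreated"]
  r10u <- readings$reading[readings$day == day10 &
                             readings$control_role == "untreated"]
  r10n <- readings$reading[readings$day == day10 &
                             readings$control_role %in% neg_roles]
  r10p <- readings$reading[readings$day == day10 &
                             readings$control_role == "staurosporine"]
  r10d <- readings$reading[readings$day == day10 &
                             readings$control_role == "vehicle_dmso"]
  if (!length(r0u) || !length(r10u))
    stop("untreated controls required on both day ", day0, " and day ",
         day10)

  growth_ratio <- mean(r10u) / mean(r0u)
  cv <- stats::sd(r10n) / mean(r10n)
  z_factor <- if (length(r10p) >= 2 && length(r10n) >= 2)
    1 - 3 * (stats::sd(r10p) + stats::sd(r10n)) /
      abs(mean(r10p) - mean(r10n)) else NA_real_
  dmso_effect <- if (length(r10d)) mean(r10d) / mean(r10u) else NA_real_

  verdicts <- c(
    growth = growth_ratio >= th$growth,
    cv = cv < th$cv,
    z_factor = if (is.na(z_factor)) NA else z_factor > th$z,
    dmso = if (is.na(dmso_effect)) NA else
      dmso_effect >= th$dmso[1] && dmso_effect <= th$dmso[2])
  structure(list(growth_ratio = growth_ratio, cv = cv, z_factor = z_factor,
                 dmso_effect = dmso_effect, thresholds = th,
                 verdicts = verdicts,
                 pass = all(verdicts[!is.na(verdicts)])),
            class = "plate_qc")
}

#' @export
print.plate_qc <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else if (v) "pass" else "FAIL"
  cat("Plate quality control\n")
  cat(sprintf("  growth ratio day10/day0: %.3f (rule >= %.2f): %s\n",
              x$growth_ratio, x$thresholds$growth, fmt(x$verdicts["growth"])))
  cat(sprintf("  CV of negative controls: %.3f (rule < %.2f): %s\n",
              x$cv, x$thresholds$cv, fmt(x$verdicts["cv"])))
  cat(sprintf("  Z-factor:                %s (rule > %.2f): %s\n",
              ifelse(is.na(x$z_factor), "n/a", sprintf("%.3f", x$z_factor)),
              x$thresholds$z, fmt(x$verdicts["z_factor"])))
  cat(sprintf("  DMSO effect:             %s (rule %.2f-%.2f): %s\n",
              ifelse(is.na(x$dmso_effect), "n/a",
                     sprintf("%.3f", x$dmso_effect)),
              x$thresholds$dmso[1], x$thresholds$dmso[2],
              fmt(x$verdicts["dmso"])))
  cat(if (x$pass) "  overall: PASS\n" else "  overall: FAIL\n")
  invisible(x)
}
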