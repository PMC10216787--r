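#' Normalize organoid-load metrics to the day-0 baseline
#'
#' Tumor growth under treatment is expressed as a fold change: each
#' day-10 well's load metric divided by the pooled mean of the day-0
#' control wells for the same metric.
#'
#' @param day10_wells,day0_wells Data frames of well-load rows (see
#'   [quantify_well()]) or any table containing `well_id` and the metric
#'   column.
#' @param metric Column name to normalize (`"n_nuclei"`, `"mean_area"` or
#'   `"n_organoids"`).
#' @return Data frame `well_id`, `fold_change`.
#' @export
normalize_growth <- function(day10_wells, day0_wells, metric = "n_nuclei") {
  if (!metric %in% names(day10_wells) || !metric %in% names(day0_wells))
    stop("metric column '", metric, "' not found")
  base <- mean(day0_wells[[metric]])
  if (!is.finite(base) || base <= 0)
    stop("day-0 mean of '", metric, "' must be positive")
  data.frame(well_id = day10_wells$well_id,
             fold_change = day10_wells[[metric]] / base)
}

#' Compare treated growth to untreated controls
#'
#' Two-sided unpaired t-test (Welch by default; set `var_equal = TRUE`
#' for the pooled-variance test) of treated vs untreated day-10 fold
#' changes, with Bonferroni adjustment over the `n_comparisons` doses
#' tested against the same controls.
#'
#' @param treated_folds,untreated_folds Numeric fold-change vectors
#'   (>= 2 wells each).
#' @param n_comparisons Number of simultaneous dose comparisons for the
#'   Bonferroni correction.
#' @param metric,dose Annotations copied into the output row.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param alpha Significance level applied to the adjusted p-value.
#' @return One-row data frame: `metric`, `dose`, `fold_change_treated`,
#'   `fold_change_untreated`, `t`, `df`, `p_value`, `adjusted_p`,
#'   `significant`.
#' @export
compare_to_untreated <- function(treated_folds, untreated_folds,
                                 n_comparisons = 1, metric = NA_character_,
                                 dose = NA_real_, var_equal = FALSE,
                                 alpha = 0.05) {
  if (length(treated_folds) < 2 || length(untreated_folds) < 2)
    stop("each group needs at least 2 wells")
  tt <- stats::t.test(treated_folds, untreated_folds,
                      var.equal = var_equal)
  p_adj <- min(1, tt$p.value * n_comparisons)
  data.frame(metric = metric, dose = dose,
             fold_change_treated = mean(treated_folds),
             fold_change_untreated = mean(untreated_folds),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, adjusted_p = p_adj,
             significant = p_adj < alpha)
}

#' Dose-by-dose growth comparison for one load metric
#'
#' Convenience wrapper: normalizes all day-10 wells to the day-0 control
#' mean and runs [compare_to_untreated()] for every dose against the
#' untreated day-10 wells, Bonferroni-corrected over the number of doses.
#'
#' @param day10_wells Well-load table with `well_id`, `dose`,
#'   `control_role` and the metric column.
#' @param day0_wells Day-0 control well-load table.
#' @param metric Load metric column name.
#' @param var_equal Passed to [compare_to_untreated()].
#' @return Data frame with one row per dose.
#' @export
compare_doses <- function(day10_wells, day0_wells, metric = "n_nuclei",
                          var_equal = FALSE) {
  folds <- normalize_growth(day10_wells, day0_wells, metric)$fold_change
  untreated <- day10_wells$control_role %in%
    c("untreated", "vehicle_dmso", "vehicle_ethanol")
  treated <- day10_wells$control_role == "none"
  doses <- sort(unique(day10_wells$dose[treated]))
  out <- lapply(doses, function(d) {
    compare_to_untreated(folds[treated & day10_wells$dose == d],
                         folds[untreated], n_comparisons = length(doses),
                         metric = metric, dose = d, var_equal = var_equal)
  })
  do.call(rbind, out)
}
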