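#' Run the full imaging drug-test pipeline on one experiment
#'
#' End-to-end orchestration: per-plane segmentation and intensity
#' extraction for every field (`segment`), well-load aggregation,
#' control-calibrated death gating (`gate`), growth statistics versus
#' untreated controls (`load-stats`) and, when whole-well readings are
#' supplied, plate quality control (`plate-qc`). A failing stage halts the
#' run with the stage named. All outputs are written as CSV into
#' `out_dir`, stamped with the configuration hash and seed, alongside a
#' `gating_model.json` sidecar and a `provenance.json` recording every
#' parameter and the package version; two runs with the same inputs and
#' configuration produce byte-identical tables.
#'
#' @param stacks Either a named list of [image_stack()] objects or a
#'   directory containing `<well>_<field>.tif` stacks with JSON sidecars
#'   (see [write_image_stack()]).
#' @param platemap Plate map data frame (see [read_platemap()]); must
#'   contain a `day` column giving each well's imaging day.
#' @param readings Optional whole-well viability table (`well`, `day`,
#'   `reading`); enables the plate-QC stage.
#' @param config A [default_config()] list.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return (Invisibly) a list with `organoids`, `nuclei`, `well_loads`,
#'   `gating`, `death_counts`, `positive_control`, `growth`, `qc` and
#'   `provenance`.
#' @export
run_pipeline <- function(stacks, platemap, readings = NULL,
                         config = default_config(), out_dir = NULL) {
  platemap <- validate_platemap(as.data.frame(platemap))
  if (!"day" %in% names(platemap))
    stop("stage segment failed: platemap needs a 'day' column")
  hash <- config_hash(config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  res <- stage("segment", {
    if (is.character(stacks)) stacks <- load_stack_dir(stacks)
    unknown <- setdiff(vapply(stacks, `[[`, "", "well_id"), platemap$well)
    if (length(unknown))
      stop("stack well(s) not in plate map: ",
           paste(unique(unknown), collapse = ", "))
    per <- lapply(stacks, process_stack, params = config$segmentation)
    list(stacks = stacks,
         organoids = do.call(rbind, lapply(per, `[[`, "organoids")),
         nuclei = do.call(rbind, lapply(per, `[[`, "nuclei")))
  })

  well_loads <- stage("quantify", {
    wells <- unique(vapply(res$stacks, `[[`, "", "well_id"))
    geom_of <- function(w) res$stacks[[which(
      vapply(res$stacks, `[[`, "", "well_id") == w)[1]]]$geometry
    do.call(rbind, lapply(wells, function(w)
      quantify_well(res$organoids[res$organoids$well_id == w, ],
                    res$nuclei[res$nuclei$well_id == w, ],
                    geom_of(w), well_id = w)))
  })

  gating <- stage("gate", {
    day_of <- platemap$day[match(res$nuclei$well_id, platemap$well)]
    role_of <- platemap$control_role[match(res$nuclei$well_id,
                                           platemap$well)]
    day0 <- res$nuclei[day_of == 0 & role_of == "untreated", ]
    day10 <- res$nuclei[day_of == 10 & role_of == "untreated", ]
    if (nrow(day0) < 2)
      stop("need day-0 untreated control nuclei to calibrate thresholds")
    thr <- fit_viable_thresholds(day0, scale = config$gating$scale)
    model <- fit_gate_lines(day10, thr, scale = config$gating$scale,
                            angles = config$gating$angles,
                            calibrate = config$gating$calibrate,
                            coverage = config$gating$coverage)
    cls <- classify_nuclei(res$nuclei, model)
    counts <- do.call(rbind, lapply(split(res$nuclei, res$nuclei$well_id),
                                    summarize_death, model = model))
    stauro <- res$nuclei[role_of == "staurosporine", ]
    pc <- if (nrow(stauro) && nrow(day10))
      validate_positive_control(stauro, day10, model,
                                margin = config$gating$margin) else NULL
    list(model = model, class = as.character(cls), counts = counts,
         positive_control = pc)
  })
  res$nuclei$class <- gating$class

  growth <- stage("load-stats", {
    pm <- platemap[match(well_loads$well_id, platemap$well), ]
    d10 <- cbind(well_loads, dose = pm$dose,
                 control_role = pm$control_role)[pm$day == 10, ]
    d0 <- well_loads[pm$day == 0 & pm$control_role == "untreated", ]
    if (nrow(d0) && nrow(d10) &&
        sum(d10$control_role == "untreated") >= 2 &&
        length(unique(d10$dose[d10$control_role == "none"])) >= 1) {
      do.call(rbind, lapply(c("n_nuclei", "mean_area", "n_organoids"),
                            function(m) compare_doses(d10, d0, metric = m)))
    } else NULL
  })

  qc <- if (!is.null(readings)) stage("plate-qc", {
    compute_qc(readings, platemap = platemap, thresholds = config$qc)
  }) else NULL

  provenance <- list(package = "organoscreen",
                     version = as.character(utils::packageVersion(
                       "organoscreen")),
                     config = unclass(config), config_hash = hash,
                     seed = config$seed,
                     n_stacks = length(res$stacks),
                     stages = c("segment", "quantify", "gate", "load-stats",
                                if (!is.null(qc)) "plate-qc"))

  out <- list(organoids = res$organoids, nuclei = res$nuclei,
              well_loads = well_loads, gating = gating$model,
              death_counts = gating$counts,
              positive_control = gating$positive_control,
              growth = growth, qc = qc, provenance = provenance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) {
      if (is.null(df) || !nrow(df)) return(df)
      df$config_hash <- hash; df$seed <- config$seed; df
    }
    wr <- function(df, name) if (!is.null(df))
      utils::write.csv(stamp(df), file.path(out_dir, name),
                       row.names = FALSE)
    wr(res$organoids, "organoids.csv")
    wr(res$nuclei, "nuclei.csv")
    wr(well_loads, "well_loads.csv")
    wr(gating$counts, "death_counts.csv")
    wr(growth, "growth_comparisons.csv")
    jsonlite::write_json(unclass(gating$model),
                         file.path(out_dir, "gating_model.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(qc))
      jsonlite::write_json(unclass(qc), file.path(out_dir, "plate_qc.json"),
                           auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

load_stack_dir <- function(dir) {
  sidecars <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  sidecars <- sidecars[!grepl("provenance|gating_model|plate_qc", sidecars)]
  if (!length(sidecars)) stop("no image stacks found in ", dir)
  lapply(sub("\\.json$", "", sidecars), read_image_stack)
}
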