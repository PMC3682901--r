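# Per-case orchestration of the recurrence-analysis workflow: register the
# follow-up to the planning CT (or apply a manual override), carry the
# recurrence structure into the planning frame, voxelize, compute per-plan
# dose statistics and isodose overlaps, classify the location relative to
# the margin-expanded boost, and emit a tabular report.

#' Read a case configuration
#'
#' A single structured YAML file per case; all analysis defaults (80%
#' isodose, 10/15/20 mm margins, 0.95 containment threshold, seed 0) can be
#' overridden there. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path YAML file.
#' @return An object of class `CaseConfig`.
#' @export
read_case_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  case_config(raw, base_dir = base)
}

#' Construct a case configuration from a list
#'
#' @param x named list with fields `patient_id`, `planning_ct`,
#'   `followup_ct`, `structures`, `plans`, and optional `analysis` /
#'   `registration` blocks.
#' @param base_dir directory against which relative paths are resolved.
#' @return An object of class `CaseConfig`.
#' @export
case_config <- function(x, base_dir = ".") {
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  }
  cfg <- list(
    patient_id = as.character(x$patient_id %||% "case"),
    planning_ct = resolve(x$planning_ct),
    followup_ct = resolve(unlist(x$followup_ct)),
    structures = list(
      planning = resolve(x$structures$planning),
      followup = resolve(x$structures$followup %||% x$structures$planning),
      recurrence = x$structures$recurrence %||% "Recurrence",
      boost = x$structures$boost %||% "Boost",
      ptv = x$structures$ptv %||% "PTV"
    ),
    plans = lapply(x$plans, function(p) list(
      label = p$label,
      dose = resolve(p$dose),
      fractions = as.integer(p$fractions %||% NA_integer_),
      prescribed_gy = as.numeric(p$prescribed_gy)
    )),
    analysis = list(
      isodose_pct = x$analysis$isodose_pct %||% 80,
      margins_mm = as.numeric(unlist(x$analysis$margins_mm %||%
                                       c(10, 15, 20))),
      containment_threshold = x$analysis$containment_threshold %||% 0.95,
      dvh_bin_gy = x$analysis$dvh_bin_gy %||% 0.1,
      max_level = x$analysis$max_level %||% 3L,
      voxel_tolerance = x$analysis$voxel_tolerance %||% 0.005
    ),
    registration = list(
      seed = x$registration$seed %||% 0L,
      bins = x$registration$bins %||% 50L,
      sampling_fraction = x$registration$sampling_fraction %||% 0.25,
      pyramid_levels = x$registration$pyramid_levels %||% 3L,
      max_iterations = x$registration$max_iterations %||% 200L,
      hint_deg = x$registration$hint_deg,
      override_transform = resolve(x$registration$override_transform)
    )
  )
  if (is.null(cfg$planning_ct)) stop("case config: `planning_ct` is required")
  if (length(cfg$followup_ct) < 1L)
    stop("case config: at least one follow-up CT is required")
  if (length(cfg$plans) < 1L)
    stop("case config: at least one plan is required")
  for (p in cfg$plans)
    if (!is.null(p$prescribed_gy) && !is.na(p$prescribed_gy) &&
        p$prescribed_gy <= 0)
      stop("case config: prescribed dose must be positive")
  structure(cfg, class = "CaseConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# centroid of an ROI's contour vertices (rotation-point choice for
# structure-guided registration)
roi_centroid <- function(r) {
  v <- do.call(rbind, r$contours)
  colMeans(v)
}

#' Run the full recurrence analysis for one case
#'
#' Executes, per the semi-automated workflow: rigid registration of the
#' first follow-up CT to the planning CT (skipped when a manual override
#' transform is configured), point-wise transfer of the recurrence contours
#' into the planning frame, subvoxel voxelization on each plan's dose grid,
#' per-plan descriptive dose statistics and DVH (base and boost plans are
#' analyzed separately, as sequentially applied plans must be), overlap with
#' the configured isodose volume, and the location classification against
#' the margin-expanded boost. A plan whose dose grid is a composite sum plan
#' is flagged and skipped (its per-plan columns stay empty) rather than
#' mis-attributed.
#'
#' @param config a `CaseConfig`, or path to a YAML case file.
#' @return An object of class `RecurrenceReport`.
#' @export
run_case <- function(config) {
  if (is.character(config)) config <- read_case_config(config)
  warnings_log <- character(0)
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  planning <- collect(read_ct_series(config$planning_ct), "read_planning_ct")
  if (length(config$followup_ct) > 1L)
    warnings_log <- c(warnings_log,
                      "[read_followup_ct] multiple follow-up CTs configured; analyzing the first")
  followup <- collect(read_ct_series(config$followup_ct[1L]),
                      "read_followup_ct")
  plan_structs <- collect(
    read_rtstruct(config$structures$planning, planning$frame_of_reference),
    "read_structures")
  fu_structs <- if (identical(config$structures$followup,
                              config$structures$planning)) plan_structs
    else collect(read_rtstruct(config$structures$followup,
                               followup$frame_of_reference),
                 "read_structures")
  rec_roi <- fu_structs[[config$structures$recurrence]]
  if (is.null(rec_roi))
    stop("[read_structures] recurrence structure '",
         config$structures$recurrence, "' not found")
  boost_roi <- plan_structs[[config$structures$boost]]
  ptv_roi <- plan_structs[[config$structures$ptv]]

  # --- registration (or manual override) ------------------------------------
  reg <- NULL
  if (!is.null(config$registration$override_transform)) {
    transform <- collect(
      read_transform(config$registration$override_transform), "registration")
    transform_source <- "manual_override"
  } else {
    params <- registration_params(
      bins = config$registration$bins,
      sampling_fraction = config$registration$sampling_fraction,
      pyramid_levels = config$registration$pyramid_levels,
      max_iterations = config$registration$max_iterations,
      seed = config$registration$seed)
    init <- collect(preinitialize(planning, followup,
                                  hint = config$registration$hint_deg),
                    "registration")
    if (!is.null(ptv_roi) && length(ptv_roi$contours) > 0L) {
      rp <- roi_centroid(ptv_roi)  # register about the prescription target
      init$rpx <- rp[1L]; init$rpy <- rp[2L]; init$rpz <- rp[3L]
    }
    reg <- collect(register_rigid(planning, followup, init, params),
                   "registration")
    transform <- reg$transform
    transform_source <- "automatic"
  }
  rec_planning <- collect(transform_roi(rec_roi, rt_invert(transform)),
                          "transform_roi")

  # --- per-plan dose statistics ---------------------------------------------
  plan_results <- list()
  analysis_grid <- NULL
  for (p in config$plans) {
    entry <- list(label = p$label, fractions = p$fractions,
                  prescribed_gy = p$prescribed_gy,
                  stats = NULL, dvh = NULL, overlap = NULL, skipped = FALSE)
    dose <- collect(read_rtdose(p$dose), paste0("read_dose_", p$label))
    if ("sum_plan" %in% dose$flags) {
      warnings_log <- c(warnings_log, sprintf(
        "[dose_%s] composite sum plan (%s): per-plan analysis skipped",
        p$label, dose$summation_type))
      entry$skipped <- TRUE
      plan_results[[p$label]] <- entry
      next
    }
    stage <- paste0("dose_stats_", p$label)
    mask <- collect(voxelize(rec_planning, dose,
                             max_level = config$analysis$max_level,
                             tolerance = config$analysis$voxel_tolerance),
                    stage)
    samples <- collect(sample_dose(dose, mask), stage)
    thr <- config$analysis$isodose_pct / 100 * p$prescribed_gy
    entry$stats <- collect(dose_stats(samples, thr), stage)
    entry$dvh <- collect(compute_dvh(samples, config$analysis$dvh_bin_gy),
                         stage)
    iso <- collect(isodose_mask(dose, config$analysis$isodose_pct,
                                p$prescribed_gy), stage)
    entry$overlap <- collect(
      overlap(mask, iso, sprintf("%g%% isodose (%s)",
                                 config$analysis$isodose_pct, p$label)),
      stage)
    entry$voxelization_level <- mask$level
    if (is.null(analysis_grid)) analysis_grid <- dose
    plan_results[[p$label]] <- entry
  }

  # --- location classification ----------------------------------------------
  classification <- NULL
  if (!is.null(boost_roi) && length(boost_roi$contours) > 0L &&
      !is.null(analysis_grid)) {
    stage <- "classification"
    rec_mask <- collect(voxelize(rec_planning, analysis_grid,
                                 max_level = config$analysis$max_level,
                                 tolerance = config$analysis$voxel_tolerance),
                        stage)
    boost_mask <- collect(voxelize(boost_roi, analysis_grid,
                                   max_level = config$analysis$max_level,
                                   tolerance =
                                     config$analysis$voxel_tolerance),
                          stage)
    classification <- collect(
      classify_location(rec_mask, boost_mask,
                        margins_mm = config$analysis$margins_mm,
                        containment_threshold =
                          config$analysis$containment_threshold),
      stage)
  } else {
    warnings_log <- c(warnings_log,
                      "[classification] no boost structure or analyzable plan; classification skipped")
  }
  for (r in list(rec_roi)) # structure-level flags surface in the report
    if (length(r$flags))
      warnings_log <- c(warnings_log,
                        sprintf("[read_structures] '%s' flagged: %s", r$name,
                                paste(r$flags, collapse = ", ")))
  structure(list(
    patient_id = config$patient_id,
    transform = transform,
    transform_source = transform_source,
    registration = reg,
    plans = plan_results,
    classification = classification,
    analysis = config$analysis,
    warnings = warnings_log
  ), class = "RecurrenceReport")
}

#' @export
print.RecurrenceReport <- function(x, ...) {
  cat("<RecurrenceReport> patient", x$patient_id, "\n")
  cat("  transform:", x$transform_source, "\n")
  for (p in x$plans) {
    if (p$skipped || is.null(p$stats)) {
      cat(sprintf("  plan %-6s: not analyzable (sum plan or missing)\n",
                  p$label))
      next
    }
    cat(sprintf(
      "  plan %-6s: vol %.2f ml | in isodose %.2f ml (%.0f%%) | min/med/max %.2f/%.2f/%.2f Gy\n",
      p$label, p$stats$recurrence_vol_ml, p$stats$vol_in_isodose_ml,
      p$overlap$overlap_pct, p$stats$min_gy, p$stats$median_gy,
      p$stats$max_gy))
  }
  if (!is.null(x$classification)) print(x$classification)
  if (length(x$warnings))
    cat("  warnings:\n", paste0("   - ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

# flatten a report to one named row (NA for unavailable entries)
report_row <- function(report) {
  fmt2 <- function(v) if (is.null(v) || length(v) == 0L || is.na(v))
    NA_real_ else round(v, 2)
  row <- list(patient_id = report$patient_id)
  for (lab in names(report$plans)) {
    p <- report$plans[[lab]]
    pre <- paste0(lab, "_")
    row[[paste0("fx_", lab)]] <- if (is.null(p$fractions) ||
                                     is.na(p$fractions)) NA_integer_
                                 else p$fractions
    s <- p$stats
    row[[paste0(pre, "recurrence_vol_ml")]] <- fmt2(s$recurrence_vol_ml)
    row[[paste0(pre, "vol_in_isodose_ml")]] <- fmt2(s$vol_in_isodose_ml)
    row[[paste0(pre, "min_gy")]] <- fmt2(s$min_gy)
    row[[paste0(pre, "max_gy")]] <- fmt2(s$max_gy)
    row[[paste0(pre, "median_gy")]] <- fmt2(s$median_gy)
    row[[paste0(pre, "pct_in_isodose")]] <-
      fmt2(if (is.null(p$overlap)) NULL else p$overlap$overlap_pct)
  }
  cl <- report$classification
  if (!is.null(cl)) {
    for (i in seq_along(cl$labels)) {
      key <- gsub("[+]", "_plus_", cl$labels[i])
      row[[paste0("in_", key)]] <- as.integer(cl$member[i])
      row[[paste0("coverage_", key)]] <- round(cl$coverage[i], 4)
    }
    row$outfield_vol_ml <- fmt2(cl$outfield_vol_ml)
    row$max_extension_cm <- fmt2(cl$max_extension_cm)
    row$max_extension_axial_cm <- fmt2(cl$max_extension_axial_cm)
  }
  tr <- report$transform
  for (k in c("tx", "ty", "tz", "rpx", "rpy", "rpz", "rx", "ry", "rz"))
    row[[paste0("transform_", k)]] <- round(tr[[k]], 4)
  row$transform_source <- report$transform_source
  row$n_warnings <- length(report$warnings)
  row
}

#' Write a recurrence report to CSV or JSON
#'
#' One row per case with the per-plan dose-statistic columns (recurrence
#' volume, volume in the configured isodose, min/max/median dose), the
#' percentage of the recurrence inside each plan's isodose volume, the
#' shell-membership flags with their coverage fractions, and the transform
#' used. Values are serialized with fixed precision (2 decimals for ml and
#' Gy); unavailable entries are explicit nulls, never dropped.
#'
#' @param report a `RecurrenceReport`.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  row <- report_row(report)
  if (format == "csv") {
    vals <- mapply(function(name, v) {
      if (length(v) == 0L || is.na(v)) return("")
      if (is.integer(v)) return(as.character(v))
      if (is.numeric(v))
        return(formatC(v, format = "f",
                       digits = if (grepl("^(coverage_|transform_)", name))
                         4 else 2))
      as.character(v)
    }, names(row), row)
    con <- file(path, "wb") # binary mode: byte-identical across platforms
    writeLines(c(paste(names(row), collapse = ","),
                 paste(vals, collapse = ",")), con, sep = "\n")
    close(con)
  } else {
    jsonlite::write_json(c(row, list(warnings = report$warnings)), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
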