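#' @include synth-oximetry.R synth-survival.R em.R longmodel.R stats.R
NULL

.VOLUME_COLS <- c("mouse_id", "tumor_id", "group", "day", "volume_mm3")
.OXI_COLS <- c("mouse_id", "tumor_id", "group", "day", "so2", "thb_normalized")
.ARMS <- c(ctrl = "control", control = "control",
           bev = "treated", treated = "treated")

#' Read a longitudinal tumor-volume table
#'
#' Reads and validates the CSV data contract for volumes: header columns
#' mouse_id, tumor_id, group, day, volume_mm3; group is the closed vocabulary
#' Ctrl/Bev (or control/treated), matched case-insensitively; days and
#' volumes numeric; duplicated (tumor, day) observations are rejected. Rows
#' come back grouped by tumor and sorted by day, with a normalized `arm`
#' column.
#'
#' @param path CSV file path.
#' @return data.frame (mouse_id, tumor_id, group, arm, day, volume_mm3).
#' @export
readVolumeTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.VOLUME_COLS, names(tab))
  if (length(missing_cols))
    stop("volume table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("day", "volume_mm3")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric ", col, " at row ", bad[1L])
    tab[[col]] <- v
  }
  if (any(tab$volume_mm3 < 0))
    stop("negative volume at row ", which(tab$volume_mm3 < 0)[1L])
  g <- tolower(tab$group)
  bad <- which(!g %in% names(.ARMS))
  if (length(bad))
    stop("unknown group '", tab$group[bad[1L]], "' at row ", bad[1L],
         "; allowed: Ctrl, Bev (control, treated)")
  dup <- which(duplicated(tab[c("tumor_id", "day")]))
  if (length(dup))
    stop("duplicated (tumor_id, day) observation at row ", dup[1L])
  tab$arm <- unname(.ARMS[g])
  tab <- tab[order(tab$mouse_id, tab$tumor_id, tab$day), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a longitudinal tumor-volume table
#'
#' @param cohort data.frame with the volume-table columns (a simulated
#'   cohort's `arm` is written as the `group` column when none is present).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeVolumeTable <- function(cohort, path) {
  if (!"group" %in% names(cohort) && "arm" %in% names(cohort))
    cohort$group <- cohort$arm
  missing_cols <- setdiff(.VOLUME_COLS, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  write.csv(cohort[.VOLUME_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a longitudinal oximetry table
#'
#' CSV contract for oximetry records: mouse_id, tumor_id, group, day, so2
#' (unitless, in `[0, 1]`), thb_normalized (unitless).
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readOximetryTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.OXI_COLS, names(tab))
  if (length(missing_cols))
    stop("oximetry table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("day", "so2", "thb_normalized")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) stop("non-numeric ", col, " at row ", bad[1L])
    tab[[col]] <- v
  }
  if (any(tab$so2 < 0 | tab$so2 > 1))
    stop("so2 outside [0, 1] at row ", which(tab$so2 < 0 | tab$so2 > 1)[1L])
  dup <- which(duplicated(tab[c("tumor_id", "day")]))
  if (length(dup)) stop("duplicated (tumor_id, day) observation at row ", dup[1L])
  tab[order(tab$mouse_id, tab$tumor_id, tab$day), , drop = FALSE]
}

#' @rdname readOximetryTable
#' @param tab oximetry data.frame to write.
#' @param path output CSV path.
#' @export
writeOximetryTable <- function(tab, path) {
  missing_cols <- setdiff(.OXI_COLS, names(tab))
  if (length(missing_cols))
    stop("table is missing column(s): ", paste(missing_cols, collapse = ", "))
  write.csv(tab[.OXI_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the knobs of a full synthetic or file-based pipeline run. In
#' synthetic mode (the default) every input is generated from the three
#' simulator configurations; in file mode, paths to volume and oximetry CSVs
#' replace the generators.
#'
#' @param growth,oximetry,survival simulator configurations.
#' @param volume_path,oximetry_path optional CSV paths (real-data mode).
#' @param classifier_method "em" or "threshold".
#' @param level classification level, "mouse" or "tumor".
#' @param threshold slope threshold (cube-root mm/day).
#' @param knot_day knot of the piecewise longitudinal model.
#' @param seed master seed recorded in all outputs.
#' @param outdir output directory (created if absent).
#' @return list of class `PipelineConfig`.
#' @seealso [runPipeline()]
#' @export
pipelineConfig <- function(growth = growthSimConfig(),
                           oximetry = oximetrySimConfig(),
                           survival = survivalSimConfig(),
                           volume_path = NULL, oximetry_path = NULL,
                           classifier_method = c("em", "threshold"),
                           level = c("mouse", "tumor"),
                           threshold = 0.05, knot_day = 21,
                           seed = 1L, outdir = tempfile("patox_run_")) {
  classifier_method <- match.arg(classifier_method)
  level <- match.arg(level)
  for (p in c(volume_path, oximetry_path))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  structure(list(growth = growth, oximetry = oximetry, survival = survival,
                 volume_path = volume_path, oximetry_path = oximetry_path,
                 classifier_method = classifier_method, level = level,
                 threshold = threshold, knot_day = knot_day,
                 seed = as.integer(seed), outdir = outdir),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — input generation (or loading), responder
#' classification, longitudinal growth and piecewise oximetry models,
#' endpoint statistics and survival analysis — writing every artifact
#' (volume/oximetry/label CSVs, fit summaries, Kaplan-Meier curves, predicted
#' trajectories, run manifest) under `config$outdir`. A stage error aborts
#' the run naming the stage; artifacts of completed stages are preserved.
#' Reruns with an identical configuration and seed reproduce identical
#' outputs.
#'
#' @param config a [pipelineConfig()].
#' @return list: manifest (config hash, seed, package version, per-file md5
#'   checksums, warnings), labels ([AllocationState-class] or threshold
#'   labels), growth_fit and oximetry_fit ([LmmFit-class]), slope_change
#'   test, endpoint tests, survival test.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig"))
    stop("'config' must come from pipelineConfig()")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)

  cohort <- .stage("data", {
    if (!is.null(config$volume_path)) readVolumeTable(config$volume_path)
    else {
      ch <- simulateGrowthCohort(config$growth, seed = config$seed)
      writeVolumeTable(ch, file.path(config$outdir, "volumes.csv"))
      ch
    }
  })
  oxi <- .stage("data", {
    if (!is.null(config$oximetry_path)) readOximetryTable(config$oximetry_path)
    else if (!is.null(cohort$true_group)) {
      ox <- simulateOximetryTrajectories(config$oximetry, cohort,
                                         seed = config$seed + 1L)
      writeOximetryTable(ox, file.path(config$outdir, "oximetry.csv"))
      ox
    } else NULL
  })

  alloc <- .stage("classify", {
    if (config$classifier_method == "em")
      emAllocate(cohort, level = config$level, threshold = config$threshold)
    else {
      treated <- cohort[cohort$arm == "treated", , drop = FALSE]
      sl <- fitGrowthSlopes(treated, config$level)
      labs <- setNames(thresholdClassify(sl$slope, config$threshold),
                       sl$unit_id)
      new("AllocationState", labels = labs, iteration = 0L,
          objective = 0, trace = numeric(0), params = list(),
          converged = TRUE, level = config$level)
    }
  })
  labels <- allocationLabels(alloc)
  lab_df <- data.frame(unit_id = names(labels), label = unname(labels),
                       stringsAsFactors = FALSE)
  write.csv(lab_df, file.path(config$outdir, "labels.csv"),
            row.names = FALSE, quote = FALSE)

  # analysis groups: control arm keeps "control"; treated units get labels
  unit_of <- if (config$level == "mouse") cohort$mouse_id else cohort$tumor_id
  cohort$group <- ifelse(cohort$arm == "control", "control",
                         unname(labels[unit_of]))
  fits <- .stage("longmodel", {
    growth_fit <- fitLmm(cohort, "cube_root_volume")
    oxi_fit <- NULL; slope_change <- NULL
    if (!is.null(oxi)) {
      unit_oxi <- if (config$level == "mouse") oxi$mouse_id else oxi$tumor_id
      oxi$group <- ifelse(unit_oxi %in% names(labels),
                          unname(labels[unit_oxi]), "control")
      oxi_fit <- fitLmm(oxi, "so2", piecewise = TRUE, knot = config$knot_day)
      if (all(c("responder", "control") %in% oxi_fit@spec$groups))
        slope_change <- testSlopeChange(oxi_fit, "responder", "control")
      traj <- predictGroupTrajectories(oxi_fit)
      write.csv(traj, file.path(config$outdir, "so2_trajectories.csv"),
                row.names = FALSE, quote = FALSE)
    }
    list(growth = growth_fit, oximetry = oxi_fit, slope_change = slope_change)
  })
  if (is.null(fits$slope_change))
    warnings_log <- c(warnings_log,
                      "no responder group: slope-change contrast skipped")

  endpoint <- .stage("stats", {
    res <- NULL
    if (!is.null(oxi)) {
      last <- oxi[oxi$day == max(oxi$day), , drop = FALSE]
      gs <- split(last$so2, last$group)
      gs <- gs[lengths(gs) >= 2L]
      if (length(gs) >= 2L) {
        pairs <- utils::combn(names(gs), 2L, simplify = FALSE)
        res <- do.call(rbind, lapply(pairs, function(p) {
          tt <- ttestAuto(gs[[p[1L]]], gs[[p[2L]]])
          data.frame(test = "so2_endpoint", group1 = p[1L], group2 = p[2L],
                     estimate = tt$mean_x - tt$mean_y, method = tt$method,
                     p_value = tt$p_value, stringsAsFactors = FALSE)
        }))
        write.csv(res, file.path(config$outdir, "endpoint_tests.csv"),
                  row.names = FALSE, quote = FALSE)
      }
    }
    res
  })

  surv_res <- .stage("survival", {
    st <- simulateSurvival(cohort, config$survival)
    write.csv(st, file.path(config$outdir, "survival.csv"),
              row.names = FALSE, quote = FALSE)
    if (length(unique(st$group)) >= 2L && sum(st$event) > 0L) {
      lr <- logrankTest(st$time_days, st$event, st$group)
      write.csv(lr$km, file.path(config$outdir, "km_curves.csv"),
                row.names = FALSE, quote = FALSE)
      lr
    } else {
      warnings_log <- c(warnings_log,
                        "survival: fewer than 2 groups or no events; log-rank skipped")
      NULL
    }
  })

  manifest <- .stage("manifest", {
    cfg_json <- file.path(config$outdir, "config.json")
    write_json(list(seed = config$seed, level = config$level,
                    classifier_method = config$classifier_method,
                    threshold = config$threshold, knot_day = config$knot_day,
                    growth = unclass(config$growth),
                    oximetry = unclass(config$oximetry),
                    survival = unclass(config$survival)),
               cfg_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- list.files(config$outdir, pattern = "\\.(csv|json)$",
                        full.names = TRUE)
    files <- setdiff(files, file.path(config$outdir, "manifest.json"))
    cs <- md5sum(files)
    names(cs) <- basename(files)
    man <- list(config_hash = unname(md5sum(cfg_json)),
                seed = config$seed,
                package_version = as.character(packageVersion("patox")),
                checksums = as.list(cs),
                warnings = warnings_log)
    write_json(man, file.path(config$outdir, "manifest.json"),
               auto_unbox = TRUE, pretty = TRUE)
    man
  })

  list(manifest = manifest, labels = alloc, growth_fit = fits$growth,
       oximetry_fit = fits$oximetry, slope_change = fits$slope_change,
       endpoint_tests = endpoint, survival_test = surv_res,
       outdir = config$outdir)
}
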