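#' Read an SUV volume from NIfTI
#'
#' Reads a NIfTI (.nii / .nii.gz) file already expressed in SUV units and
#' returns an \code{\link{suv_volume}} with voxel spacing taken from the
#' header. Negative voxel values and non-positive spacings are rejected: SUV
#' is non-negative by definition, so a negative value indicates the file is
#' not an SUV volume. No SUV conversion (dose / weight / decay arithmetic) is
#' performed.
#'
#' @param path NIfTI file path.
#' @return An \code{\link{suv_volume}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  vals <- array(as.numeric(vals), dim(vals))  # drop NIfTI header attributes
  if (length(dim(vals)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(vals)), " dimensions: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or non-positive voxel spacing in NIfTI header: ", path)
  if (any(vals < 0))
    stop(sprintf("negative voxel value (%.4g) in %s: not an SUV volume",
                 min(vals), path))
  suv_volume(vals, sp)
}

#' Write an SUV volume (or mask) to NIfTI
#'
#' @param volume an \code{\link{suv_volume}} or \code{\link{voi_mask}} (masks
#'   are written as 0/1 volumes).
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path) {
  vals <- if (inherits(volume, "voi_mask")) volume$mask + 0 else volume$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask from a 0/1 NIfTI volume
#'
#' @param path NIfTI file path.
#' @param method provenance tag to record on the mask (default
#'   \code{"manual"}, the user-supplied override path).
#' @return A \code{\link{voi_mask}}.
#' @export
read_mask <- function(path, method = "manual") {
  if (!file.exists(path)) stop("cannot read mask: file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (!all(vals %in% c(0, 1)))
    stop("mask file must contain only 0/1 values: ", path)
  voi_mask(vals > 0, RNifti::pixdim(img)[1:3], method = method,
           params = list(file = path))
}

cohort_columns <- c("patient_id", "age", "gender", "smoking_status",
                    "pack_years", "stage", "egfr", "kras")

#' Read a patient cohort table from CSV
#'
#' Schema: \code{patient_id, age, gender (male/female), smoking_status
#' (never/former/current), pack_years, stage, egfr (pos/neg/NA), kras
#' (pos/neg/NA)}, optionally followed by lesion-metric columns
#' (\code{diameter, suv_max, suv_mean, suv_sd, mtv, tlg, inv_cov, auc_csh,
#' heterogeneity_eligible}). Categories are validated with row-level error
#' messages naming the offending line; empty strings and "NA" are normalized
#' to missing.
#'
#' @param path CSV file path.
#' @return A \code{cohort_table}.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cannot read cohort: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols))
    stop("cohort CSV lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.na(df$smoking_status) &
                 !df$smoking_status %in% c("never", "former", "current"))
  if (length(bad))
    stop(sprintf("row %d: smoking_status '%s' not one of never/former/current",
                 bad[1] + 1L, df$smoking_status[bad[1]]))
  for (col in c("age", "pack_years")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad))
      stop(sprintf("row %d: non-numeric %s '%s'", bad[1] + 1L, col,
                   df[[col]][bad[1]]))
    df[[col]] <- v
  }
  for (col in c("egfr", "kras")) {
    bad <- which(!is.na(df[[col]]) & !df[[col]] %in% c("pos", "neg"))
    if (length(bad))
      stop(sprintf("row %d: %s '%s' not one of pos/neg/NA", bad[1] + 1L, col,
                   df[[col]][bad[1]]))
  }
  for (m in c("diameter", "suv_max", "suv_mean", "suv_sd", "mtv", "tlg",
              "inv_cov", "auc_csh"))
    if (is.null(df[[m]])) df[[m]] <- NA_real_
  if (is.null(df$heterogeneity_eligible))
    df$heterogeneity_eligible <- !is.na(df$diameter) & df$diameter >= 10
  message(sprintf("read %d patient records from %s", nrow(df), path))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#' @param cohort a \code{cohort_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Exactly one of \code{cohort_csv} (real inputs) or \code{simulation} (a
#' \code{\link{cohort_spec}}) must be supplied. Can also be loaded from a
#' YAML file via \code{path}.
#'
#' @param cohort_csv path to a cohort CSV (real-input mode).
#' @param simulation a \code{\link{cohort_spec}} (simulation mode).
#' @param n_phantoms in simulation mode, how many patients additionally get
#'   an image-based measurement chain (phantom -> segmentation -> metrics);
#'   0 disables it.
#' @param segmentation \code{"petedge"} or \code{"threshold"}.
#' @param threshold_fraction fraction of local SUVmax for threshold mode.
#' @param n_thresholds CSH threshold count.
#' @param output_dir directory for result files.
#' @param seed integer seed governing every random draw of the run.
#' @param path optional YAML file; its fields override the other arguments.
#' @return A validated list of class \code{run_config}.
#' @export
run_config <- function(cohort_csv = NULL, simulation = NULL, n_phantoms = 0,
                       segmentation = c("petedge", "threshold"),
                       threshold_fraction = 0.42, n_thresholds = 1000,
                       output_dir = "pethet_results", seed = 1L, path = NULL) {
  if (!is.null(path)) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$cohort_csv)) cohort_csv <- cfg$cohort_csv
    if (!is.null(cfg$simulation)) simulation <- do.call(cohort_spec, cfg$simulation)
    for (nm in c("n_phantoms", "segmentation", "threshold_fraction",
                 "n_thresholds", "output_dir", "seed"))
      if (!is.null(cfg[[nm]])) assign(nm, cfg[[nm]])
  }
  segmentation <- match.arg(segmentation)
  if (is.null(cohort_csv) == is.null(simulation))
    stop("exactly one of 'cohort_csv' (real inputs) or 'simulation' must be given")
  if (!is.null(cohort_csv) && !file.exists(cohort_csv))
    stop("cohort_csv not found: ", cohort_csv)
  structure(list(cohort_csv = cohort_csv, simulation = simulation,
                 n_phantoms = n_phantoms, segmentation = segmentation,
                 threshold_fraction = threshold_fraction,
                 n_thresholds = n_thresholds, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

measure_patient_phantom <- function(row, config, seed) {
  # one small per-patient phantom: lesion matching the sampled metrics,
  # centred in the right lung, segmented and measured end to end
  d <- min(max(row$diameter, 6), 36)
  row$diameter <- d
  spacing <- 2
  half <- ceiling((d / 2 + 14) / spacing)
  gs <- c(2 * half + 21, 2 * half + 21, 2 * half + 21)
  center <- gs * spacing / 2 - c(gs[1] * spacing / 4, 0, 0)
  les <- lesion_from_metrics(row, center)
  ph <- generate_phantom(phantom_spec(grid_shape = gs, voxel_spacing = spacing,
                                      noise_sigma = 0.05, lesions = list(les),
                                      seed = seed))
  mask <- if (config$segmentation == "petedge") {
    petedge_segment(ph$volume, center)
  } else {
    threshold_segment(ph$volume, center, config$threshold_fraction)
  }
  lesion_metrics(ph$volume, mask, n_thresholds = config$n_thresholds)
}

#' Run the full pipeline
#'
#' Simulation mode: generates the cohort, optionally re-measures the first
#' \code{n_phantoms} patients through the image chain (phantom, gradient or
#' threshold segmentation, metric extraction), then runs the statistical
#' battery: summary tables, univariate screens for EGFR and KRAS, and the
#' multivariate logistic model. Real-input mode reads the cohort CSV and runs
#' the same statistics. All outputs are written under
#' \code{config$output_dir}: \code{cohort.csv}, \code{summary_*.csv},
#' \code{univariate_<gene>.csv}, \code{multivariate_egfr.csv},
#' \code{results.json} and \code{run_log.txt} (seed and provenance).
#' Deterministic for a fixed \code{config$seed}.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with the cohort and every result table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("pethet pipeline run, seed %d", config$seed),
                 sprintf("mode: %s",
                         if (is.null(config$simulation)) "real inputs" else "simulation"),
                 sprintf("segmentation: %s", config$segmentation))
  stage <- "cohort"
  result <- tryCatch({
    if (is.null(config$simulation)) {
      cohort <- read_cohort(config$cohort_csv)
    } else {
      spec <- config$simulation
      spec$seed <- config$seed
      cohort <- generate_cohort(spec)
      if (config$n_phantoms > 0) {
        stage <- "phantom measurement"
        k <- min(config$n_phantoms, nrow(cohort))
        for (i in seq_len(k)) {
          met <- tryCatch(
            measure_patient_phantom(cohort[i, ], config,
                                    seed = config$seed + i),
            error = function(e) NULL)  # low-contrast lesion: keep drawn metrics
          if (is.null(met)) next
          for (f in c("diameter", "suv_max", "suv_mean", "suv_sd", "mtv",
                      "tlg", "inv_cov", "auc_csh"))
            cohort[[f]][i] <- met[[f]]
          cohort$heterogeneity_eligible[i] <- met$heterogeneity_eligible
        }
        log_lines <- c(log_lines,
                       sprintf("image-based metrics for %d patients (%s)", k,
                               config$segmentation))
      }
    }
    write_cohort(cohort, file.path(config$output_dir, "cohort.csv"))

    stage <- "summary"
    summ <- summarize_cohort(cohort)
    for (nm in names(summ))
      utils::write.csv(summ[[nm]],
                       file.path(config$output_dir, paste0("summary_", nm, ".csv")),
                       row.names = FALSE)
    stage <- "univariate screen"
    uni <- list(egfr = univariate_scan(cohort, "egfr"),
                kras = univariate_scan(cohort, "kras"))
    for (g in names(uni))
      utils::write.csv(uni[[g]],
                       file.path(config$output_dir,
                                 paste0("univariate_", g, ".csv")),
                       row.names = FALSE)
    stage <- "multivariate model"
    multi <- suppressWarnings(multivariate_logistic(cohort, "egfr"))
    utils::write.csv(multi, file.path(config$output_dir, "multivariate_egfr.csv"),
                     row.names = FALSE)
    stage <- "json export"
    jsonlite::write_json(
      list(seed = config$seed, prevalence = summ$prevalence,
           univariate = uni, multivariate = multi),
      file.path(config$output_dir, "results.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
    list(cohort = cohort, summary = summ, univariate = uni,
         multivariate = multi)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  log_lines <- c(log_lines, sprintf("completed %s", format(Sys.time())))
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  invisible(result)
}
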