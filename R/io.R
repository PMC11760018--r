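#' Write a synthetic cohort dataset to disk
#'
#' Serializes a [generate_cohort()] result in the pipeline's input formats:
#' one CSV per (patient, variable) with columns `time_s,value` (missing
#' samples as empty fields), a `metadata.csv` with the patient records, a
#' `config.yaml` echo of the generator settings, and a `manifest.json`
#' listing every path plus the generating seed.
#'
#' @param data a `"cohort_data"` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort_dataset <- function(data, dir) {
  stopifnot(inherits(data, "cohort_data"))
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(data$records, meta_path, row.names = FALSE)
  series_files <- list()
  for (pid in names(data$series)) {
    for (v in names(data$series[[pid]])) {
      x <- data$series[[pid]][[v]]
      dt <- attr(x, "dt") %||% data$config$dt
      df <- data.frame(time_s = (seq_along(x) - 1L) * dt,
                       value = as.numeric(x))
      rel <- file.path("series", sprintf("%s_%s.csv", pid, v))
      utils::write.csv(df, file.path(dir, rel), row.names = FALSE,
                       na = "")
      series_files[[length(series_files) + 1L]] <-
        list(patient_id = pid, variable = v, path = rel)
    }
  }
  cfg <- unclass(data$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  manifest <- list(metadata = "metadata.csv", config = "config.yaml",
                   seed = data$seed, dt = data$config$dt,
                   series = series_files)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Generate a synthetic cohort dataset and write it to disk
#'
#' Convenience wrapper: [generate_cohort()] followed by
#' [write_cohort_dataset()]. The same `config` and `seed` always produce
#' byte-identical output files.
#'
#' @inheritParams generate_cohort
#' @param dir output directory.
#' @return Invisibly, the in-memory `"cohort_data"` object.
#' @export
generate_cohort_dataset <- function(config = cohort_config(), dir,
                                    seed = 1L) {
  data <- generate_cohort(config, seed = seed)
  write_cohort_dataset(data, dir)
  invisible(data)
}

#' Read a cohort dataset from a manifest
#'
#' Loads and validates a dataset written by [write_cohort_dataset()] (or any
#' dataset in the same layout): patient metadata plus per-(patient, variable)
#' time-series files. Rejects duplicate patient ids and series whose time
#' grid is not uniform at the expected step; a listed series file that is
#' absent drops that variable for that patient with a warning rather than
#' failing the record.
#'
#' @param manifest_path path to `manifest.json`, or to the dataset directory
#'   containing it.
#' @return A `"cohort_data"` object (`config` is the YAML echo, unclassed).
#' @export
read_dataset <- function(manifest_path) {
  if (dir.exists(manifest_path)) {
    manifest_path <- file.path(manifest_path, "manifest.json")
  }
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  root <- dirname(manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  records <- utils::read.csv(file.path(root, manifest$metadata),
                             stringsAsFactors = FALSE)
  if (anyDuplicated(records$patient_id)) {
    stop("duplicate patient_id in metadata: ",
         records$patient_id[duplicated(records$patient_id)][1L])
  }
  if (any(records$endpoint_time <= records$extubation_time)) {
    stop("endpoint_time must exceed extubation_time for every record")
  }
  dt <- manifest$dt %||% 5
  series <- stats::setNames(vector("list", nrow(records)),
                            records$patient_id)
  for (entry in manifest$series) {
    path <- file.path(root, entry$path)
    if (!file.exists(path)) {
      warning("series file missing, variable marked unavailable: ",
              entry$path)
      next
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("time_s", "value") %in% names(df))) {
      stop("malformed series file (need time_s,value): ", entry$path)
    }
    steps <- diff(df$time_s)
    if (length(steps) && any(abs(steps - dt) > 1e-6)) {
      bad <- which(abs(steps - dt) > 1e-6)[1L]
      stop(sprintf("non-uniform sampling grid in %s at line %d", entry$path,
                   bad + 2L))
    }
    x <- df$value
    attr(x, "dt") <- dt
    attr(x, "variable") <- entry$variable
    series[[entry$patient_id]][[entry$variable]] <- x
  }
  cfg <- tryCatch(yaml::read_yaml(file.path(root, manifest$config)),
                  error = function(e) NULL)
  structure(list(records = records, series = series, config = cfg,
                 seed = manifest$seed),
            class = "cohort_data")
}
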