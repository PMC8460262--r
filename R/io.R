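# Plain-text readers and writers: pupil traces and landmark tracks as CSV,
# spatial maps as (voxel_index, value) CSV, trial bundles as a directory of
# CSVs, configs as YAML, reports as JSON. Voxel <-> flat index mapping uses
# mask scan order with x fastest, then y, then z (R array order), 1-based.

#' Write / read a pupil trace CSV
#'
#' Columns `time_s, diameter`; sampling interval recovered from the time
#' column.
#' @param trace a `PupilTrace`.
#' @param path file path.
#' @export
write_pupil_csv <- function(trace, path) {
  stopifnot(inherits(trace, "PupilTrace"))
  df <- data.frame(time_s = (seq_along(trace$values) - 1) * trace$dt,
                   diameter = trace$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pupil_csv
#' @param normalized flag stored on the reconstructed trace.
#' @export
read_pupil_csv <- function(path, normalized = FALSE) {
  df <- read_checked_csv(path, c("time_s", "diameter"))
  if (nrow(df) < 2) stop("pupil CSV ", path, " has fewer than 2 rows")
  dt <- df$time_s[2] - df$time_s[1]
  new_pupil_trace(df$diameter, dt = dt, normalized = normalized)
}

#' Write / read a landmark track CSV
#'
#' Columns `frame, x1, y1, ..., x4, y4`; frame rate and eye size are stored as
#' `# key: value` header comments.
#' @param series a `LandmarkSeries`.
#' @param path file path.
#' @export
write_landmarks_csv <- function(series, path) {
  stopifnot(inherits(series, "LandmarkSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fps: %.10g", attr(series, "fps")),
               sprintf("# eye_size: %.10g", attr(series, "eye_size"))), con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  meta <- function(lines, key) {
    ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
    if (length(ln) != 1) stop("landmark CSV ", path, " lacks '# ", key, ":' header")
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", ln))
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame", "x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("landmark CSV ", path, " missing columns: ",
         paste(missing, collapse = ", "))
  }
  structure(df, fps = meta(hdr, "fps"), eye_size = meta(hdr, "eye_size"),
            class = c("LandmarkSeries", "data.frame"))
}

#' Write / read a spatial map CSV
#'
#' Columns `voxel_index, value`, `voxel_index` being the 1-based position in
#' mask scan order (x fastest, then y, then z).
#' @param map a `SpatialMap`.
#' @param path file path.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "SpatialMap"))
  utils::write.csv(data.frame(voxel_index = seq_along(map$values),
                              value = map$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @param geometry the map's `BrainGeometry`.
#' @param kind map kind (default `"correlation"`).
#' @export
read_map_csv <- function(path, geometry, kind = "correlation") {
  df <- read_checked_csv(path, c("voxel_index", "value"))
  if (nrow(df) != geometry$n_voxels) {
    stop("map CSV ", path, " has ", nrow(df), " voxels; geometry expects ",
         geometry$n_voxels)
  }
  if (any(df$voxel_index != seq_len(nrow(df)))) {
    bad <- which(df$voxel_index != seq_len(nrow(df)))[1]
    stop("map CSV ", path, " voxel_index out of order at row ", bad)
  }
  new_spatial_map(df$value, geometry, kind)
}

#' Write / read a trial bundle
#'
#' A directory holding `fmri.csv` (`n_voxels x T`, no header), `pupil.csv`
#' (`time_s, diameter`), and `meta.yaml` (subject id, TR, geometry shape and
#' mask rule).
#' @param trial a `Trial` with a geometry.
#' @param dir bundle directory (created if needed).
#' @export
write_trial_bundle <- function(trial, dir) {
  stopifnot(inherits(trial, "Trial"), !is.null(trial$geometry))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(trial$fmri, file.path(dir, "fmri.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write_pupil_csv(new_pupil_trace(trial$pupil, trial$tr),
                  file.path(dir, "pupil.csv"))
  yaml::write_yaml(list(subject_id = trial$subject_id, tr = trial$tr,
                        shape = as.integer(trial$geometry$shape),
                        mask_rule = trial$geometry$mask_rule),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_trial_bundle
#' @export
read_trial_bundle <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  geom <- generate_geometry(unlist(meta$shape), meta$mask_rule)
  fmri <- as.matrix(utils::read.table(file.path(dir, "fmri.csv"), sep = ","))
  dimnames(fmri) <- NULL
  pupil <- read_pupil_csv(file.path(dir, "pupil.csv"))
  new_trial(meta$subject_id, fmri, pupil$values, meta$tr, geom)
}

#' Write / read a pipeline config as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  vecs <- c("shape", "n_trials_per_state", "bandpass", "k_range", "methods")
  for (v in intersect(vecs, names(raw))) raw[[v]] <- unlist(raw[[v]])
  do.call(pipeline_config, raw)
}

#' Write a pipeline report as JSON
#' @param report a [run_pipeline()] result.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}

#' Write / read cluster labels CSV (`trial_id, label, stability`)
#' @param trial_ids character vector.
#' @param labels,stability parallel vectors.
#' @param path file path.
#' @export
write_labels_csv <- function(trial_ids, labels, stability, path) {
  utils::write.csv(data.frame(trial_id = trial_ids, label = labels,
                              stability = stability),
                   path, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
#' @noRd
read_checked_csv <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("malformed CSV ", path, ": ",
                                          conditionMessage(e)))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("CSV ", path, " missing columns: ", paste(missing, collapse = ", "))
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop("CSV ", path, " has a malformed value in column '", col,
           "' at data row ", bad[1])
    }
    df[[col]] <- v
  }
  df
}
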