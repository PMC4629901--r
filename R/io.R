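#' Serialize conditions and geometry to YAML
#'
#' Structured-text round trip for the two configuration objects, so runs
#' can be reproduced from files.
#'
#' @param x a [cell_conditions()] or [tissue_geometry()].
#' @param path file path.
#' @return `path`, invisibly; readers return the reconstructed object.
#' @export
write_conditions_yaml <- function(x, path) {
  stopifnot(inherits(x, "cell_conditions"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname write_conditions_yaml
#' @export
read_conditions_yaml <- function(path) {
  do.call(cell_conditions, yaml::read_yaml(path))
}

#' @rdname write_conditions_yaml
#' @export
write_geometry_yaml <- function(x, path) {
  stopifnot(inherits(x, "tissue_geometry"))
  yaml::write_yaml(x[c("width", "height", "h", "border_x",
                       "iso_strip_width")], path)
  invisible(path)
}

#' @rdname write_conditions_yaml
#' @export
read_geometry_yaml <- function(path) {
  do.call(tissue_geometry, yaml::read_yaml(path))
}

#' Run manifest
#'
#' Provenance record emitted alongside simulation outputs: configuration
#' hash, package version, the condition and geometry used, the files
#' written, wall time and completion status. Deterministic inputs produce
#' identical hashes.
#'
#' @param conditions a [cell_conditions()].
#' @param geometry a [tissue_geometry()] (or `NULL` for cell-only runs).
#' @param outputs character vector of files written.
#' @param status completion status string.
#' @param wall_time_s elapsed seconds.
#' @param extra named list of additional fields (protocol parameters etc.).
#' @return a named list of class `run_manifest`.
#' @export
run_manifest <- function(conditions, geometry = NULL, outputs = character(0),
                         status = "completed", wall_time_s = NA,
                         extra = list()) {
  m <- list(
    config_hash = digest::digest(list(unclass(conditions),
                                      if (!is.null(geometry))
                                        unclass(geometry), extra)),
    package_version = as.character(utils::packageVersion("anisoblock")),
    conditions = unclass(conditions),
    geometry = if (!is.null(geometry))
      geometry[c("width", "height", "h", "border_x", "iso_strip_width")],
    outputs = outputs, status = status, wall_time_s = wall_time_s,
    extra = extra)
  class(m) <- "run_manifest"
  m
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' Export a space-time record as plain text
#'
#' `write_record_traces()` writes the dense site traces as tidy CSV
#' (`time`, `node`, `V`); `write_record_frames()` writes the frame stack as
#' a plain matrix text file (one frame per block) for external plotting.
#'
#' @param record a `space_time_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_record_traces <- function(record, path) {
  if (is.null(record$traces)) abort("record has no site traces")
  write.csv(record$traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record_traces
#' @export
write_record_frames <- function(record, path) {
  if (is.null(record$frames)) abort("record has no frames")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d nodes x %d frames, nx=%d ny=%d",
                     nrow(record$frames), ncol(record$frames),
                     record$geometry$nx, record$geometry$ny), con)
  for (k in seq_len(ncol(record$frames))) {
    writeLines(sprintf("# t = %g", record$frame_times[k]), con)
    writeLines(paste(format(record$frames[, k], digits = 6),
                     collapse = " "), con)
  }
  invisible(path)
}
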