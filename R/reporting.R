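# Output helpers shared by the analysis drivers: CSV/JSON writers and a run
# manifest recording enough to reproduce a run exactly.

#' Write a data.frame as CSV
#'
#' Comma-separated, header row, UTF-8, no row names. Monetary columns are
#' kept at full precision; rounding to whole pounds is a presentation
#' concern.
#'
#' @param x A data.frame.
#' @param path Output path (directories are created as needed).
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Checksum of a canonicalized parameter configuration
#'
#' MD5 of the canonical JSON serialization of the parameter set, so two runs
#' with identical configurations produce identical checksums.
#'
#' @param ps An `scs_params` object.
#' @return Character MD5 checksum.
#' @export
config_checksum <- function(ps) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  doc <- list(schema_version = ps$schema_version,
              values = as.list(ps$values[order(names(ps$values))]))
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA, na = "null")
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records package version, configuration checksum, seed, timestamp and the
#' analysis stage into `manifest.json` in the output directory.
#'
#' @param out_dir Output directory.
#' @param ps An `scs_params` object.
#' @param stage Name of the analysis stage.
#' @param seed Integer seed, or `NULL` for deterministic stages.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(out_dir, ps, stage, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool_version = as.character(utils::packageVersion("scscea")),
    config_checksum = config_checksum(ps),
    seed = if (is.null(seed)) NA else seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage = stage
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(manifest)
}

#' Export a Markov trace as CSV
#'
#' One row per cycle: cycle index, end time, the seven state occupancies,
#' undiscounted and discounted cycle cost, discounted cycle QALYs, and the
#' five event counts.
#'
#' @param lt An `scs_long_term` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(lt, path) {
  write_result_csv(lt$trace, path)
}
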