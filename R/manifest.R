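#' Write a run manifest
#'
#' A JSON snapshot emitted alongside every pipeline run: the full study
#' configuration, the master seed, MD5 digests of the input files, the
#' package version and a timestamp.  Re-running with the configuration and
#' seed recorded in a manifest reproduces the outputs exactly.
#'
#' @param config a [study_config()].
#' @param inputs named character vector of input file paths to digest.
#' @param path output path for the manifest JSON.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, inputs, path) {
  stopifnot(inherits(config, "study_config"))
  digests <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(
    package = "coldRR",
    version = as.character(utils::packageVersion("coldRR")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input_md5 = as.list(digests))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
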