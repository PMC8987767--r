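# Config and manifest plumbing shared by the user-facing readers and the
# command-line interface.

read_config_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path),
          class = "cytovag_error_validation")
  }
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    "yaml" = ,
    "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(paste0("Unsupported config format \".", ext,
                 "\"; use YAML or JSON."),
          class = "cytovag_error_validation"))
  if (!is.list(vals)) {
    abort("Config file must contain a mapping of field names to values.",
          class = "cytovag_error_validation")
  }
  vals
}

#' Write a run manifest
#'
#' Records what a run did — command, configuration snapshot, seed, input and
#' output paths, package version and timestamp — as JSON next to the run's
#' outputs, so any stochastic artifact can be regenerated bit-identically
#' from its manifest.
#'
#' @param path Output JSON path.
#' @param command Name of the command or function that produced the outputs.
#' @param seed Integer seed used for the run (or `NULL`).
#' @param config Configuration list/object snapshot (stored as-is).
#' @param inputs,outputs Character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed = NULL, config = list(),
                           inputs = character(), outputs = character()) {
  manifest <- list(
    command = command,
    seed = seed,
    config = strip_classes(config),
    inputs = as.character(inputs),
    outputs = as.character(outputs),
    package = "cytovag",
    version = as.character(packageVersion("cytovag")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# drop S3 classes recursively so configs serialise as plain JSON mappings
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}

#' Read a run manifest
#'
#' @param path Path to a manifest JSON written by [write_manifest()].
#' @return A list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
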