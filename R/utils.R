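# Shared helpers: atomic JSON persistence, checksums, path handling.

#' Read a YAML or JSON mapping from disk
#'
#' JSON parse is attempted first, then YAML; the file extension is advisory
#' only, since workflow and job files in the wild mix extensions freely.
#'
#' @param path file to read
#' @return the parsed structure (named list for a mapping)
#' @keywords internal
read_yaml_or_json <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) NULL
  )
  if (is.null(parsed)) {
    parsed <- tryCatch(
      yaml::yaml.load(txt),
      error = function(e) {
        cwl_abort("parse_error",
                  sprintf("cannot parse '%s' as JSON or YAML: %s",
                          path, conditionMessage(e)))
      }
    )
  }
  if (is.null(parsed)) {
    cwl_abort("parse_error", sprintf("'%s' is empty", path))
  }
  parsed
}

# Write JSON atomically: temp file in the target directory, then rename.
# rename(2) within one filesystem is atomic, which is what gives the
# run-state store its one-transaction-per-transition crash consistency.
atomic_write_json <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' SHA-1 checksum of a file in CWL "sha1$<hex>" form
#' @param path file to hash
#' @return character scalar "sha1$<hex>"
#' @export
file_checksum <- function(path) {
  paste0("sha1$", digest::digest(file = path, algo = "sha1"))
}

content_hash <- function(path) {
  digest::digest(file = path, algo = "sha1")
}

# Absolute, normalized path; the file need not exist yet.
abs_path <- function(path, relative_to = getwd()) {
  if (!grepl("^/", path)) path <- file.path(relative_to, path)
  normalizePath(path, mustWork = FALSE)
}

timestamp_now <- function() {
  as.numeric(Sys.time())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar string check used throughout the parsers
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# A CWL File value literal: list(class = "File", path = ...)
is_file_value <- function(v) {
  is.list(v) && identical(v$class, "File") && is_string(v$path %||% v$location)
}

file_value_path <- function(v) v$path %||% v$location
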