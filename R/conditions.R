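#' @keywords internal
"_PACKAGE"

# Classed conditions used across the engine. Every engine error carries class
# c("cwldag_<kind>", "cwldag_error", "error", "condition") so callers can
# catch a specific failure kind without string matching.

cwl_abort <- function(kind, message, ...) {
  data <- list(...)
  cond <- structure(
    class = c(paste0("cwldag_", kind), "cwldag_error", "error", "condition"),
    c(list(message = message, call = NULL), data)
  )
  stop(cond)
}

#' Diagnostics
#'
#' Validation operations return diagnostics rather than throwing: a data frame
#' with one row per finding, columns `level` ("error" or "warning"), `code`
#' (a stable machine-readable tag) and `message`.
#'
#' @param level "error" or "warning"
#' @param code stable machine-readable tag
#' @param message human-readable description
#' @return a one-row diagnostics data frame
#' @keywords internal
diagnostic <- function(level, code, message) {
  data.frame(level = level, code = code, message = message,
             stringsAsFactors = FALSE)
}

no_diagnostics <- function() {
  data.frame(level = character(), code = character(), message = character(),
             stringsAsFactors = FALSE)
}

bind_diagnostics <- function(...) {
  do.call(rbind, c(list(no_diagnostics()), Filter(Negate(is.null), list(...))))
}

has_errors <- function(diags) {
  nrow(diags) > 0L && any(diags$level == "error")
}
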