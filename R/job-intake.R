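# Job files: one YAML/JSON mapping per requested run, carrying the three
# mandatory fields (workflow, output_folder, uid) plus workflow-specific
# input values. Files are discovered from a watched jobs folder, validated
# against the workflow they name, and registered by uid.

MANDATORY_JOB_FIELDS <- c("workflow", "output_folder", "uid")

#' Parse a job file into a run request
#'
#' A job file is a JSON or YAML mapping with three mandatory fields —
#' `workflow` (path to the CWL descriptor to run), `output_folder` (where
#' delivered outputs go) and `uid` (the unique run identifier) — and any
#' number of further keys, which are taken verbatim as workflow input values
#' (File values as `{class: File, path: ...}`). Relative `workflow` and
#' `output_folder` paths are resolved against the job file's directory.
#'
#' @param path job file path
#' @return a `job_descriptor`: uid, workflow_path, output_folder, inputs,
#'   submitted_at, source_file
#' @export
parse_job_file <- function(path) {
  obj <- read_yaml_or_json(path)
  if (!is.list(obj) || is.null(names(obj)))
    cwl_abort("parse_error", sprintf("job file '%s' is not a mapping", path))
  for (f in MANDATORY_JOB_FIELDS) {
    if (!is_string(obj[[f]]) || !nzchar(obj[[f]]))
      cwl_abort("missing_mandatory_field",
                sprintf("job file '%s' lacks mandatory field '%s'", path, f),
                field = f)
  }
  job_dir <- dirname(normalizePath(path))
  inputs <- obj[setdiff(names(obj), MANDATORY_JOB_FIELDS)]
  structure(list(
    uid = obj$uid,
    workflow_path = abs_path(obj$workflow, job_dir),
    output_folder = abs_path(obj$output_folder, job_dir),
    inputs = inputs,
    submitted_at = timestamp_now(),
    source_file = normalizePath(path)
  ), class = "job_descriptor")
}

#' @export
print.job_descriptor <- function(x, ...) {
  cat(sprintf("<job_descriptor> uid '%s'\n  workflow: %s\n  output_folder: %s\n  inputs: %s\n",
              x$uid, x$workflow_path, x$output_folder,
              paste(names(x$inputs), collapse = ", ")))
  invisible(x)
}

# does a concrete job value fit a declared workflow input type?
value_matches_type <- function(value, tp) {
  if (tp$array) {
    if (!is.list(value) && !(is.atomic(value) && length(value) >= 0L)) return(FALSE)
    items <- if (is.list(value)) value else as.list(value)
    return(all(vapply(items, value_matches_type, logical(1),
                      tp = cwl_type(tp$base))))
  }
  switch(tp$base,
    File = is_file_value(value),
    string = is_string(value),
    boolean = is.logical(value) && length(value) == 1L,
    int = ,
    long = is.numeric(value) && length(value) == 1L &&
      abs(value - round(value)) < 1e-9,
    float = ,
    double = is.numeric(value) && length(value) == 1L,
    FALSE)
}

#' Validate a job against its workflow
#'
#' Checks that every required workflow input (non-optional, no default) has a
#' value of compatible type and that every File value's path exists. Extra
#' job keys that match no workflow input yield warning-level diagnostics, not
#' errors, so job files stay forward-compatible with workflow edits.
#'
#' @param job a `job_descriptor`
#' @param doc the `cwl_document` (Workflow) loaded from `job$workflow_path`
#' @return a diagnostics data frame
#' @export
validate_job <- function(job, doc) {
  stopifnot(inherits(job, "job_descriptor"), inherits(doc, "cwl_document"))
  wf <- doc$body
  diags <- no_diagnostics()
  for (iid in names(wf$inputs)) {
    p <- wf$inputs[[iid]]
    v <- job$inputs[[iid]]
    if (is.null(v)) {
      if (!p$type$optional && is.null(p$default_value))
        diags <- bind_diagnostics(diags, diagnostic(
          "error", "missing-input",
          sprintf("required workflow input '%s' has no value in the job", iid)))
      next
    }
    if (!value_matches_type(v, p$type)) {
      diags <- bind_diagnostics(diags, diagnostic(
        "error", "input-type-mismatch",
        sprintf("job value for input '%s' does not match declared type %s",
                iid, type_label(p$type))))
      next
    }
    for (fv in collect_file_values(v)) {
      fp <- abs_path(file_value_path(fv), dirname(job$source_file))
      if (!file.exists(fp))
        diags <- bind_diagnostics(diags, diagnostic(
          "error", "missing-file",
          sprintf("input '%s': file '%s' does not exist", iid, fp)))
    }
  }
  for (extra in setdiff(names(job$inputs), names(wf$inputs))) {
    diags <- bind_diagnostics(diags, diagnostic(
      "warning", "unknown-job-key",
      sprintf("job key '%s' matches no workflow input; ignored", extra)))
  }
  diags
}

collect_file_values <- function(v) {
  if (is_file_value(v)) return(list(v))
  if (is.list(v) && is.null(names(v)))
    return(unlist(lapply(v, collect_file_values), recursive = FALSE))
  list()
}

#' Scan a jobs folder for new run requests
#'
#' Reads every regular file in `folder`, skipping uids already present in the
#' run-state store. Files that fail to parse (or lack a mandatory field) are
#' recorded in the store as rejected runs keyed by content hash, so a broken
#' file is reported exactly once until its content changes; a later edit
#' makes it eligible again. Job files are never mutated or deleted.
#'
#' @param folder jobs folder to scan
#' @param store a run-state store from [run_store()]
#' @return list of `job_descriptor` for newly discovered jobs
#' @export
scan_jobs_folder <- function(folder, store) {
  stopifnot(dir.exists(folder))
  files <- sort(list.files(folder, full.names = TRUE))
  files <- files[!dir.exists(files)]
  found <- list()
  for (f in files) {
    hash <- content_hash(f)
    if (store_has_rejection(store, hash)) next
    job <- tryCatch(parse_job_file(f), error = function(e) e)
    if (inherits(job, "error")) {
      store_record_rejection(store, hash, source_file = f,
                             reason = conditionMessage(job))
      next
    }
    if (store_has_run(store, job$uid)) {
      # same uid seen before: if it is this very file, it is simply already
      # registered; a different file with the same uid is a collision
      existing <- store_load_run(store, job$uid)
      if (!identical(existing$job$source_file, job$source_file)) {
        store_record_rejection(store, hash, source_file = f,
                               reason = sprintf("duplicate uid '%s'", job$uid))
      }
      next
    }
    store_register_run(store, job)
    found[[length(found) + 1L]] <- job
  }
  found
}
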