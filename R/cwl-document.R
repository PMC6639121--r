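# Loading and validation of CWL v1.0 documents (CommandLineTool / Workflow)
# for the supported subset. The parser is fail-closed: every key it does not
# consume raises an unsupported-feature error naming the key, so no part of a
# document is ever silently dropped.

SUPPORTED_CWL_VERSION <- "v1.0"
SCALAR_TYPES <- c("string", "int", "long", "float", "double", "boolean")
SUPPORTED_REQUIREMENTS <- c("DockerRequirement", "ResourceRequirement",
                            "EnvVarRequirement")

# --- type descriptors -------------------------------------------------------

# A parsed CWL type: base scalar or File (or "stdout" for captured streams),
# with array/optional flags. Only the two-member union ["null", T] is
# accepted as optionality; all other unions are rejected to keep type
# checking decidable without schema-salad.
cwl_type <- function(base, array = FALSE, optional = FALSE) {
  list(base = base, array = array, optional = optional)
}

parse_cwl_type <- function(spec, where, output = FALSE) {
  if (is_string(spec)) {
    optional <- grepl("\\?$", spec)
    spec <- sub("\\?$", "", spec)
    array <- grepl("\\[\\]$", spec)
    spec <- sub("\\[\\]$", "", spec)
    if (identical(spec, "stdout")) {
      if (!output)
        cwl_abort("unsupported_feature",
                  sprintf("type 'stdout' is only valid for outputs (%s)", where))
      return(cwl_type("stdout"))
    }
    if (!spec %in% c("File", SCALAR_TYPES))
      cwl_abort("unsupported_feature",
                sprintf("unsupported type '%s' at %s", spec, where),
                feature = spec)
    return(cwl_type(spec, array = array, optional = optional))
  }
  if (is.list(spec) && is.null(names(spec))) {
    # union: only ["null", T]
    if (length(spec) == 2L && identical(spec[[1]], "null")) {
      inner <- parse_cwl_type(spec[[2]], where, output = output)
      inner$optional <- TRUE
      return(inner)
    }
    cwl_abort("unsupported_feature",
              sprintf("unsupported type union at %s (only [\"null\", T] is accepted)",
                      where),
              feature = "union")
  }
  if (is.list(spec) && identical(spec$type, "array")) {
    items <- spec$items
    if (!is_string(items) || !items %in% c("File", SCALAR_TYPES))
      cwl_abort("unsupported_feature",
                sprintf("unsupported array item type at %s", where),
                feature = "array-items")
    return(cwl_type(items, array = TRUE))
  }
  cwl_abort("unsupported_feature",
            sprintf("unsupported type expression at %s", where),
            feature = "type")
}

type_label <- function(tp) {
  lbl <- tp$base
  if (tp$array) lbl <- paste0(lbl, "[]")
  if (tp$optional) lbl <- paste0(lbl, "?")
  lbl
}

# File<->File, same scalar<->same scalar, X<->optional-X; stdout-captured
# outputs are File-valued on the wire.
types_compatible <- function(src, dst) {
  src_base <- if (src$base == "stdout") "File" else src$base
  dst_base <- if (dst$base == "stdout") "File" else dst$base
  identical(src_base, dst_base) && identical(src$array, dst$array)
}

# --- key-consumption guard --------------------------------------------------

reject_unknown_keys <- function(obj, allowed, where) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra) > 0L)
    cwl_abort("unsupported_feature",
              sprintf("unsupported key(s) %s in %s",
                      paste(sprintf("'%s'", extra), collapse = ", "), where),
              feature = extra[[1]])
  invisible(obj)
}

# --- bindings ---------------------------------------------------------------

parse_command_binding <- function(spec, where) {
  if (is_string(spec)) {          # plain-string argument: a literal token
    return(list(position = 0L, prefix = NULL, separate = TRUE,
                item_separator = NULL, value_from = spec))
  }
  reject_unknown_keys(spec, c("position", "prefix", "separate",
                              "itemSeparator", "valueFrom"), where)
  list(position = as.integer(spec$position %||% 0L),
       prefix = spec$prefix,
       separate = if (is.null(spec$separate)) TRUE else isTRUE(spec$separate),
       item_separator = spec$itemSeparator,
       value_from = spec$valueFrom)
}

parse_output_binding <- function(spec, where) {
  reject_unknown_keys(spec, "glob", where)
  if (!is_string(spec$glob))
    cwl_abort("invalid_document", sprintf("outputBinding at %s needs a glob", where))
  if (grepl("^/", spec$glob))
    cwl_abort("invalid_document",
              sprintf("absolute glob '%s' at %s: globs are relative to the working directory",
                      spec$glob, where))
  list(glob = spec$glob, capture = "files")
}

# --- IO parameters ----------------------------------------------------------

# inputs/outputs are accepted in both CWL forms: a mapping id -> spec, or a
# list of specs each carrying an `id` field. Returned as a named list keyed
# (and ordered) by id.
as_id_map <- function(obj, where) {
  if (is.null(obj) || length(obj) == 0L) return(stats::setNames(list(), character()))
  if (!is.null(names(obj)) && all(nzchar(names(obj)))) return(as.list(obj))
  out <- list()
  for (el in obj) {
    if (is_string(el)) el <- list(id = el, spec_is_bare = TRUE)
    if (!is.list(el) || !is_string(el$id))
      cwl_abort("invalid_document", sprintf("entry without id in %s", where))
    id <- sub("^#", "", el$id)
    if (id %in% names(out))
      cwl_abort("invalid_document", sprintf("duplicate id '%s' in %s", id, where))
    el$id <- NULL
    out[[id]] <- el
  }
  out
}

parse_io_parameter <- function(id, spec, direction, where) {
  if (is_string(spec) || (is.list(spec) && is.null(names(spec))))
    spec <- list(type = spec)     # bare type shorthand
  allowed <- c("type", "doc", "label", "default",
               if (direction == "input") "inputBinding" else c("outputBinding", "outputSource"))
  reject_unknown_keys(spec, allowed, sprintf("%s '%s'", where, id))
  tp <- parse_cwl_type(spec$type, sprintf("%s '%s'", where, id),
                       output = direction == "output")
  binding <- NULL
  if (direction == "input" && !is.null(spec$inputBinding))
    binding <- parse_command_binding(spec$inputBinding,
                                     sprintf("inputBinding of '%s'", id))
  out_binding <- NULL
  if (direction == "output") {
    if (tp$base == "stdout") {
      out_binding <- list(glob = NULL, capture = "stdout")
    } else if (!is.null(spec$outputBinding)) {
      out_binding <- parse_output_binding(spec$outputBinding,
                                          sprintf("outputBinding of '%s'", id))
    }
  }
  list(id = id, type = tp,
       default_value = spec$default,
       input_binding = binding,
       output_binding = out_binding,
       output_source = spec$outputSource,
       doc = spec$doc)
}

parse_io_set <- function(obj, direction, where) {
  m <- as_id_map(obj, where)
  out <- list()
  for (id in names(m)) {
    if (id %in% names(out))
      cwl_abort("invalid_document", sprintf("duplicate id '%s' in %s", id, where))
    out[[id]] <- parse_io_parameter(id, m[[id]], direction, where)
  }
  out
}

# --- requirements -----------------------------------------------------------

parse_requirements <- function(obj, where) {
  if (is.null(obj) || length(obj) == 0L) return(list())
  entries <- if (is.null(names(obj))) {
    lapply(obj, function(el) el)
  } else {
    lapply(names(obj), function(k) c(list(class = k), obj[[k]]))
  }
  out <- list()
  for (el in entries) {
    kind <- el$class
    if (!is_string(kind) || !kind %in% SUPPORTED_REQUIREMENTS)
      cwl_abort("unsupported_feature",
                sprintf("unsupported requirement '%s' in %s",
                        kind %||% "<unnamed>", where),
                feature = kind %||% "<unnamed>")
    payload <- el[setdiff(names(el), "class")]
    if (kind == "DockerRequirement") {
      image <- payload$dockerPull %||% payload$dockerImageId
      if (!is_string(image) || !nzchar(image))
        cwl_abort("invalid_document",
                  sprintf("DockerRequirement in %s has no image identifier", where))
      payload$image <- image
    }
    out[[kind]] <- payload
  }
  out
}

# --- CommandLineTool --------------------------------------------------------

parse_tool <- function(obj, source_path, where) {
  reject_unknown_keys(obj, c("cwlVersion", "class", "id", "label", "doc",
                             "baseCommand", "arguments", "inputs", "outputs",
                             "stdin", "stdout", "stderr",
                             "requirements", "hints"),
                      where)
  base_command <- obj$baseCommand
  if (is.null(base_command)) base_command <- character()
  base_command <- vapply(as.list(base_command), function(x) {
    if (!is_string(x) && !is.numeric(x))
      cwl_abort("invalid_document", sprintf("non-scalar baseCommand token in %s", where))
    as.character(x)
  }, character(1))
  arguments <- lapply(seq_along(obj$arguments %||% list()), function(i)
    parse_command_binding(obj$arguments[[i]], sprintf("argument %d of %s", i, where)))
  inputs <- parse_io_set(obj$inputs, "input", sprintf("inputs of %s", where))
  outputs <- parse_io_set(obj$outputs, "output", sprintf("outputs of %s", where))
  if (length(base_command) == 0L && length(arguments) == 0L)
    cwl_abort("invalid_document",
              sprintf("%s has neither baseCommand nor arguments", where))
  reqs <- parse_requirements(obj$requirements, where)
  hints <- parse_requirements(obj$hints, where)
  structure(list(
    base_command = base_command,
    arguments = arguments,
    inputs = inputs,
    outputs = outputs,
    stdin_ref = obj$stdin,
    stdout_name = obj$stdout,
    stderr_name = obj$stderr,
    requirements = utils::modifyList(hints, reqs)
  ), class = "cwl_tool")
}

# --- Workflow ---------------------------------------------------------------

parse_step <- function(id, spec, base_dir, depth, where) {
  reject_unknown_keys(spec, c("run", "in", "out", "doc", "label"),
                      sprintf("step '%s'", id))
  run <- spec$run
  run_ref <- NULL
  if (is_string(run)) {
    run_path <- if (grepl("^/", run)) run else file.path(base_dir, run)
    if (!file.exists(run_path))
      cwl_abort("unresolved_reference",
                sprintf("step '%s': run target '%s' does not exist", id, run),
                reference = run)
    run_ref <- normalizePath(run_path)
    tool_doc <- load_document(run_ref, .depth = depth + 1L)
    tool <- tool_doc$body
  } else if (is.list(run)) {
    inner <- parse_document(run, source_path = NULL, base_dir = base_dir,
                            depth = depth + 1L, require_version = FALSE,
                            where = sprintf("inline run of step '%s'", id))
    tool <- inner$body
  } else {
    cwl_abort("invalid_document", sprintf("step '%s' has no run target", id))
  }

  in_raw <- as_id_map(spec[["in"]], sprintf("in of step '%s'", id))
  in_bindings <- list()
  for (iid in names(in_raw)) {
    b <- in_raw[[iid]]
    if (is_string(b)) b <- list(source = b)
    if (isTRUE(b$spec_is_bare)) b <- list()      # list-form entry "id" only
    reject_unknown_keys(b, c("source", "default", "spec_is_bare"),
                        sprintf("step '%s' input '%s'", id, iid))
    if (!is.null(b$source) && !is_string(b$source))
      cwl_abort("unsupported_feature",
                sprintf("step '%s' input '%s': multi-source links are not supported",
                        id, iid),
                feature = "MultipleInputFeature")
    in_bindings[[iid]] <- list(source = b$source, default = b$default)
  }

  out_raw <- spec$out %||% list()
  out_ids <- vapply(as.list(out_raw), function(o) {
    if (is.list(o)) o <- o$id
    if (!is_string(o))
      cwl_abort("invalid_document", sprintf("step '%s': malformed out entry", id))
    sub("^#", "", o)
  }, character(1))
  bad <- setdiff(out_ids, names(tool$outputs))
  if (length(bad) > 0L)
    cwl_abort("unresolved_reference",
              sprintf("step '%s' declares out id(s) %s not produced by its tool",
                      id, paste(sprintf("'%s'", bad), collapse = ", ")),
              reference = bad[[1]])

  list(id = id, run_ref = run_ref, tool = tool,
       in_bindings = in_bindings, out_ids = out_ids)
}

parse_workflow <- function(obj, source_path, base_dir, depth, where) {
  reject_unknown_keys(obj, c("cwlVersion", "class", "id", "label", "doc",
                             "inputs", "outputs", "steps",
                             "requirements", "hints"),
                      where)
  if (!is.null(obj$requirements) || !is.null(obj$hints)) {
    # workflow-level process requirements (SubworkflowFeature, Scatter, JS)
    # are exactly the features outside the subset
    kinds <- c(names(obj$requirements),
               vapply(obj$requirements %||% list(), function(r)
                 r$class %||% "", character(1)))
    cwl_abort("unsupported_feature",
              sprintf("workflow-level requirements are not supported (%s)",
                      paste(setdiff(kinds, ""), collapse = ", ")),
              feature = "workflow-requirements")
  }
  inputs <- parse_io_set(obj$inputs, "input", sprintf("inputs of %s", where))
  outputs <- parse_io_set(obj$outputs, "output", sprintf("outputs of %s", where))
  for (oid in names(outputs)) {
    if (!is_string(outputs[[oid]]$output_source))
      cwl_abort("invalid_document",
                sprintf("workflow output '%s' lacks an outputSource", oid))
  }
  steps_raw <- as_id_map(obj$steps, sprintf("steps of %s", where))
  if (length(steps_raw) == 0L)
    cwl_abort("invalid_document", sprintf("%s has no steps", where))
  for (sid in names(steps_raw)) {
    if (is.list(steps_raw[[sid]]) && !is.null(steps_raw[[sid]]$scatter))
      cwl_abort("unsupported_feature",
                sprintf("step '%s' uses scatter", sid), feature = "scatter")
  }
  steps <- lapply(names(steps_raw), function(sid)
    parse_step(sid, steps_raw[[sid]], base_dir, depth, where))
  names(steps) <- vapply(steps, `[[`, character(1), "id")
  structure(list(inputs = inputs, outputs = outputs, steps = steps),
            class = "cwl_workflow")
}

# --- top-level dispatch -----------------------------------------------------

parse_document <- function(obj, source_path, base_dir, depth = 1L,
                           require_version = TRUE, where = "document") {
  if (!is.list(obj) || is.null(names(obj)))
    cwl_abort("parse_error", sprintf("%s is not a mapping", where))
  version <- obj$cwlVersion
  if (require_version || !is.null(version)) {
    if (!identical(version, SUPPORTED_CWL_VERSION))
      cwl_abort("version_error",
                sprintf("%s declares cwlVersion '%s'; only '%s' is supported",
                        where, version %||% "<missing>", SUPPORTED_CWL_VERSION))
  }
  kind <- obj$class
  if (!is_string(kind) || !kind %in% c("CommandLineTool", "Workflow"))
    cwl_abort("unsupported_feature",
              sprintf("%s has class '%s'; expected CommandLineTool or Workflow",
                      where, kind %||% "<missing>"),
              feature = kind %||% "<missing>")
  if (kind == "Workflow" && depth > 1L)
    cwl_abort("unsupported_feature",
              sprintf("nested workflow used as a step run target (%s)", where),
              feature = "SubworkflowFeature")
  doc_id <- sub("^#", "", obj$id %||%
                  if (!is.null(source_path))
                    tools::file_path_sans_ext(basename(source_path)) else "main")
  body <- if (kind == "CommandLineTool") {
    parse_tool(obj, source_path, where)
  } else {
    parse_workflow(obj, source_path, base_dir, depth, where)
  }
  structure(list(class_kind = kind,
                 cwl_version = SUPPORTED_CWL_VERSION,
                 id = doc_id,
                 source_path = source_path,
                 body = body),
            class = "cwl_document")
}

#' Load a CWL v1.0 document
#'
#' Reads a CommandLineTool or Workflow descriptor from YAML or JSON and
#' returns the fully resolved internal representation. `run:` file references
#' in workflow steps are loaded recursively, relative to the referring
#' document's directory. Features outside the supported subset (scatter,
#' JavaScript expressions, nested workflows, schema-salad types, unknown
#' requirement kinds) are rejected with an error naming the feature.
#'
#' @param path path to a `.cwl`/`.yml`/`.yaml`/`.json` file
#' @param .depth internal recursion depth for `run:` resolution
#' @return a `cwl_document` with fields `class_kind`, `cwl_version`, `id`,
#'   `source_path` and `body` (a `cwl_tool` or `cwl_workflow`)
#' @export
load_document <- function(path, .depth = 1L) {
  if (!file.exists(path))
    cwl_abort("parse_error", sprintf("file '%s' does not exist", path))
  obj <- read_yaml_or_json(path)
  parse_document(obj, source_path = normalizePath(path),
                 base_dir = dirname(normalizePath(path)), depth = .depth,
                 where = sprintf("document '%s'", basename(path)))
}

#' @export
print.cwl_document <- function(x, ...) {
  cat(sprintf("<cwl_document> %s '%s' (cwl %s)\n",
              x$class_kind, x$id, x$cwl_version))
  if (x$class_kind == "Workflow") {
    cat(sprintf("  steps: %s\n", paste(names(x$body$steps), collapse = ", ")))
    cat(sprintf("  inputs: %d  outputs: %d\n",
                length(x$body$inputs), length(x$body$outputs)))
  } else {
    cat(sprintf("  baseCommand: %s\n", paste(x$body$base_command, collapse = " ")))
    cat(sprintf("  inputs: %d  outputs: %d\n",
                length(x$body$inputs), length(x$body$outputs)))
  }
  invisible(x)
}

# --- reference resolution helpers ------------------------------------------

# A source reference is "workflow_input_id" or "step_id/output_id".
resolve_source <- function(ref, wf) {
  if (grepl("/", ref)) {
    parts <- strsplit(ref, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) return(NULL)
    step <- wf$steps[[parts[[1]]]]
    if (is.null(step) || !parts[[2]] %in% step$out_ids) return(NULL)
    out_param <- step$tool$outputs[[parts[[2]]]]
    list(kind = "step", step_id = parts[[1]], output_id = parts[[2]],
         type = out_param$type)
  } else {
    inp <- wf$inputs[[ref]]
    if (is.null(inp)) return(NULL)
    list(kind = "input", input_id = ref, type = inp$type)
  }
}

#' Check workflow connectivity and type compatibility
#'
#' Verifies that every step input source and workflow outputSource resolves
#' within the workflow and that the wire types are compatible (File to File,
#' same scalar to same scalar, a type to its optional form). Findings are
#' returned as diagnostics, never thrown.
#'
#' @param doc a `cwl_document` of class_kind Workflow
#' @return a diagnostics data frame (zero rows when the workflow is clean)
#' @export
validate_connectivity <- function(doc) {
  stopifnot(inherits(doc, "cwl_document"), doc$class_kind == "Workflow")
  wf <- doc$body
  diags <- no_diagnostics()
  for (step in wf$steps) {
    for (iid in names(step$in_bindings)) {
      b <- step$in_bindings[[iid]]
      target <- step$tool$inputs[[iid]]
      if (is.null(target)) {
        diags <- bind_diagnostics(diags, diagnostic(
          "error", "unknown-step-input",
          sprintf("step '%s' wires input '%s' which its tool does not declare",
                  step$id, iid)))
        next
      }
      if (is.null(b$source)) next    # constant default; type left to runtime
      src <- resolve_source(b$source, wf)
      if (is.null(src)) {
        diags <- bind_diagnostics(diags, diagnostic(
          "error", "unresolved-source",
          sprintf("step '%s' input '%s' references '%s' which does not resolve",
                  step$id, iid, b$source)))
        next
      }
      if (!types_compatible(src$type, target$type)) {
        diags <- bind_diagnostics(diags, diagnostic(
          "error", "type-mismatch",
          sprintf("step '%s' input '%s': source '%s' has type %s, expected %s",
                  step$id, iid, b$source, type_label(src$type),
                  type_label(target$type))))
      }
    }
  }
  for (oid in names(wf$outputs)) {
    op <- wf$outputs[[oid]]
    src <- resolve_source(op$output_source, wf)
    if (is.null(src)) {
      diags <- bind_diagnostics(diags, diagnostic(
        "error", "unresolved-source",
        sprintf("workflow output '%s' references '%s' which does not resolve",
                oid, op$output_source)))
    } else if (!types_compatible(src$type, op$type)) {
      diags <- bind_diagnostics(diags, diagnostic(
        "error", "type-mismatch",
        sprintf("workflow output '%s': source '%s' has type %s, expected %s",
                oid, op$output_source, type_label(src$type),
                type_label(op$type))))
    }
  }
  diags
}

# --- canonical serialization ------------------------------------------------

type_to_cwl <- function(tp) {
  base <- if (tp$array) list(type = "array", items = tp$base) else tp$base
  if (tp$optional) list("null", base) else base
}

binding_to_cwl <- function(b) {
  out <- list(position = b$position)
  if (!is.null(b$prefix)) out$prefix <- b$prefix
  if (!isTRUE(b$separate)) out$separate <- FALSE
  if (!is.null(b$item_separator)) out$itemSeparator <- b$item_separator
  if (!is.null(b$value_from)) out$valueFrom <- b$value_from
  out
}

io_to_cwl <- function(p, direction) {
  out <- list(type = type_to_cwl(p$type))
  if (p$type$base == "stdout") out$type <- "stdout"
  if (!is.null(p$default_value)) out$default <- p$default_value
  if (!is.null(p$input_binding)) out$inputBinding <- binding_to_cwl(p$input_binding)
  if (!is.null(p$output_binding) && p$output_binding$capture == "files")
    out$outputBinding <- list(glob = p$output_binding$glob)
  if (!is.null(p$output_source)) out$outputSource <- p$output_source
  if (!is.null(p$doc)) out$doc <- p$doc
  out
}

io_set_to_cwl <- function(params, direction) {
  ids <- sort(names(params))
  stats::setNames(lapply(ids, function(id) io_to_cwl(params[[id]], direction)), ids)
}

tool_to_cwl <- function(tool, top = TRUE) {
  out <- list(class = "CommandLineTool")
  if (top) out <- c(list(cwlVersion = SUPPORTED_CWL_VERSION), out)
  if (length(tool$base_command) > 0L) out$baseCommand <- as.list(tool$base_command)
  if (length(tool$arguments) > 0L)
    out$arguments <- lapply(tool$arguments, binding_to_cwl)
  out$inputs <- io_set_to_cwl(tool$inputs, "input")
  out$outputs <- io_set_to_cwl(tool$outputs, "output")
  if (!is.null(tool$stdin_ref)) out$stdin <- tool$stdin_ref
  if (!is.null(tool$stdout_name)) out$stdout <- tool$stdout_name
  if (!is.null(tool$stderr_name)) out$stderr <- tool$stderr_name
  if (length(tool$requirements) > 0L) {
    reqs <- tool$requirements
    out$requirements <- lapply(sort(names(reqs)), function(k) {
      payload <- reqs[[k]]
      payload$image <- NULL
      c(list(class = k), payload)
    })
  }
  out
}

workflow_to_cwl <- function(wf, top = TRUE) {
  out <- list(class = "Workflow")
  if (top) out <- c(list(cwlVersion = SUPPORTED_CWL_VERSION), out)
  out$inputs <- io_set_to_cwl(wf$inputs, "input")
  out$outputs <- io_set_to_cwl(wf$outputs, "output")
  out$steps <- stats::setNames(lapply(wf$steps, function(step) {
    ins <- stats::setNames(lapply(sort(names(step$in_bindings)), function(iid) {
      b <- step$in_bindings[[iid]]
      if (!is.null(b$source) && is.null(b$default)) b$source
      else Filter(Negate(is.null), list(source = b$source, default = b$default))
    }), sort(names(step$in_bindings)))
    # run targets are inlined so the serialized form is self-contained
    list(run = tool_to_cwl(step$tool, top = FALSE),
         `in` = ins,
         out = as.list(sort(step$out_ids)))
  }), names(wf$steps))
  out
}

document_to_cwl <- function(doc) {
  if (doc$class_kind == "CommandLineTool") tool_to_cwl(doc$body)
  else workflow_to_cwl(doc$body)
}

#' Serialize a loaded document to canonical JSON
#'
#' The canonical form is self-contained (step `run` targets are inlined),
#' key-ordered, and stable: loading the written file yields a representation
#' structurally equal to the original (see [document_signature()]).
#'
#' @param doc a `cwl_document`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_document <- function(doc, path) {
  atomic_write_json(document_to_cwl(doc), path)
}

#' Structural signature of a document
#'
#' Strips provenance fields (source paths, `run:` file references) so that
#' documents loaded from different serializations of the same content compare
#' equal with `identical()`.
#'
#' @param doc a `cwl_document`
#' @return a plain list
#' @export
document_signature <- function(doc) {
  strip <- function(x) {
    if (is.list(x)) {
      x[["source_path"]] <- NULL
      x[["run_ref"]] <- NULL
      if (!is.null(names(x)) && all(nzchar(names(x))))
        x <- x[order(names(x))]    # key order in the source file is irrelevant
      lapply(x, strip)
    } else x
  }
  sig <- strip(unclass(doc))
  sig$id <- NULL                     # ids default from the file name
  sig
}

# Content digest of a workflow document; a changed workflow invalidates
# resume of a persisted run.
document_digest <- function(doc) {
  digest::digest(document_signature(doc), algo = "sha1")
}
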