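# Execution of a single step: evaluate restricted parameter references, bind
# the command line per the CWL v1.0 rules, stage input files into an
# isolated working directory, run the process, and collect typed outputs.

PARAM_REF_RE <- "\\$\\(([A-Za-z_][A-Za-z0-9_]*(?:\\.[A-Za-z0-9_]+)*)\\)"

#' Evaluate restricted CWL parameter references
#'
#' Supports the reference grammar `$(inputs.<id>)`, `$(inputs.<id>.path)`,
#' `$(inputs.<id>.basename)`, `$(runtime.outdir)`, `$(runtime.cores)` and
#' `$(self...)`. A string that is exactly one reference returns the
#' referenced value with its native type; references embedded in longer text
#' are string-interpolated; text without references passes through
#' unchanged. JavaScript expressions (`${...}`) are outside the supported
#' subset and raise an unsupported-expression error.
#'
#' @param expr the text to evaluate
#' @param context named list with elements `inputs`, `runtime` and
#'   optionally `self`
#' @return the evaluated value
#' @export
eval_param_ref <- function(expr, context) {
  if (!is_string(expr)) return(expr)
  if (grepl("${", expr, fixed = TRUE))
    cwl_abort("unsupported_expression",
              sprintf("JavaScript expressions are not supported: %s", expr))
  lookup <- function(ref) {
    parts <- strsplit(ref, ".", fixed = TRUE)[[1]]
    v <- context
    for (p in parts) {
      if (is_file_value(v) && p == "basename") {
        v <- basename(file_value_path(v)); next
      }
      if (is_file_value(v) && p == "path") {
        v <- file_value_path(v); next
      }
      if (!is.list(v) || is.null(v[[p]]))
        cwl_abort("unknown_reference",
                  sprintf("unknown parameter reference '$(%s)'", ref),
                  reference = ref)
      v <- v[[p]]
    }
    v
  }
  m <- gregexpr(PARAM_REF_RE, expr)[[1]]
  if (m[[1]] == -1L) return(expr)
  refs <- regmatches(expr, gregexpr(PARAM_REF_RE, expr))[[1]]
  inner <- sub("^\\$\\(", "", sub("\\)$", "", refs))
  if (length(refs) == 1L && identical(refs, expr)) {
    v <- lookup(inner)
    if (is_file_value(v)) v <- file_value_path(v)
    return(v)
  }
  out <- expr
  for (i in seq_along(refs)) {
    v <- lookup(inner[[i]])
    if (is_file_value(v)) v <- file_value_path(v)
    out <- sub(refs[[i]], as.character(v), out, fixed = TRUE)
  }
  out
}

# --- command-line binding ---------------------------------------------------

value_to_string <- function(v) {
  if (is_file_value(v)) return(file_value_path(v))
  if (is.logical(v)) return(tolower(as.character(v)))
  if (is.numeric(v)) return(format(v, scientific = FALSE, trim = TRUE))
  as.character(v)
}

# Tokens contributed by one binding for one value, per the CWL v1.0 rules:
# boolean true emits the prefix alone, false and null emit nothing; arrays
# joined by itemSeparator form one token, otherwise the prefix is emitted
# once followed by the elements; separate=FALSE concatenates prefix and
# value into a single token.
binding_tokens <- function(binding, value, type, context) {
  if (!is.null(binding$value_from)) {
    ctx <- context
    ctx$self <- value
    value <- eval_param_ref(binding$value_from, ctx)
  }
  if (is.null(value)) return(character())
  prefix <- binding$prefix
  sep <- isTRUE(binding$separate)
  with_prefix <- function(tokens) {
    if (is.null(prefix)) return(tokens)
    if (length(tokens) == 0L) return(prefix)
    if (sep) c(prefix, tokens) else c(paste0(prefix, tokens[[1]]),
                                      tokens[-1])
  }
  if (is.logical(value) && length(value) == 1L && !is_file_value(value)) {
    if (isTRUE(value)) return(if (is.null(prefix)) character() else prefix)
    return(character())
  }
  is_array_value <- (is.list(value) && !is_file_value(value) &&
                       is.null(names(value))) ||
    (is.atomic(value) && length(value) > 1L)
  if (is_array_value) {
    items <- if (is.list(value)) value else as.list(value)
    if (length(items) == 0L) return(character())
    strs <- vapply(items, value_to_string, character(1))
    if (!is.null(binding$item_separator))
      return(with_prefix(paste(strs, collapse = binding$item_separator)))
    return(with_prefix(strs))
  }
  with_prefix(value_to_string(value))
}

#' Bind a tool invocation to a concrete command line
#'
#' Implements the CWL v1.0 CommandLineTool binding algorithm for the
#' supported subset: `argv` is the base command followed by the bound tokens
#' of all arguments and inputs, sorted by binding position; position ties
#' are broken deterministically (arguments by their declaration index, then
#' inputs by id, lexicographically). Also resolves stdin/stdout/stderr
#' redirections and prepares the wrapped container invocation when the tool
#' carries a DockerRequirement.
#'
#' @param tool a `cwl_tool`
#' @param values named list of concrete input values (File values staged)
#' @param workdir the step working directory
#' @param runtime optional runtime context overrides (outdir, cores)
#' @return a `command_plan`: argv, stdin_path, stdout_path, stderr_path,
#'   env, workdir, container_argv
#' @export
bind_command_line <- function(tool, values, workdir,
                              runtime = list()) {
  stopifnot(inherits(tool, "cwl_tool"))
  runtime <- utils::modifyList(list(outdir = workdir, cores = 1L), runtime)
  context <- list(inputs = values, runtime = runtime)

  # required-input / type checks
  for (iid in names(tool$inputs)) {
    p <- tool$inputs[[iid]]
    v <- values[[iid]] %||% p$default_value
    if (is.null(v)) {
      if (!p$type$optional)
        cwl_abort("missing_required_input",
                  sprintf("no value for required input '%s'", iid), input = iid)
      next
    }
    if (!value_matches_type(v, p$type))
      cwl_abort("type_mismatch",
                sprintf("value for input '%s' does not match type %s",
                        iid, type_label(p$type)), input = iid)
  }

  entries <- list()
  for (i in seq_along(tool$arguments)) {
    b <- tool$arguments[[i]]
    entries[[length(entries) + 1L]] <- list(
      position = b$position, class_rank = 0L, key = sprintf("%06d", i),
      binding = b, value = NULL)
  }
  for (iid in names(tool$inputs)) {
    p <- tool$inputs[[iid]]
    if (is.null(p$input_binding)) next
    v <- values[[iid]] %||% p$default_value
    entries[[length(entries) + 1L]] <- list(
      position = p$input_binding$position, class_rank = 1L, key = iid,
      binding = p$input_binding, value = v, type = p$type)
  }
  ord <- order(vapply(entries, `[[`, integer(1), "position"),
               vapply(entries, `[[`, integer(1), "class_rank"),
               vapply(entries, `[[`, character(1), "key"))
  tokens <- unlist(lapply(entries[ord], function(e)
    binding_tokens(e$binding, e$value, e$type, context)), use.names = FALSE)
  argv <- c(tool$base_command, as.character(tokens %||% character()))
  if (length(argv) == 0L)
    cwl_abort("invalid_document", "binding produced an empty command line")

  stdin_path <- NULL
  if (!is.null(tool$stdin_ref)) {
    v <- eval_param_ref(tool$stdin_ref, context)
    stdin_path <- if (is_file_value(v)) file_value_path(v) else as.character(v)
  }
  stdout_name <- tool$stdout_name
  if (is.null(stdout_name) && any(vapply(tool$outputs, function(o)
    identical(o$output_binding$capture, "stdout"), logical(1))))
    stdout_name <- "step.stdout"      # default name when capture is declared
  stdout_path <- if (!is.null(stdout_name))
    file.path(workdir, eval_param_ref(stdout_name, context))
  stderr_path <- if (!is.null(tool$stderr_name))
    file.path(workdir, eval_param_ref(tool$stderr_name, context))

  env <- character()
  if (!is.null(tool$requirements$EnvVarRequirement)) {
    envdef <- tool$requirements$EnvVarRequirement$envDef %||% list()
    env <- vapply(names(envdef), function(k)
      as.character(eval_param_ref(envdef[[k]], context)), character(1))
    names(env) <- names(envdef)
  }

  plan <- structure(list(argv = argv,
                         stdin_path = stdin_path,
                         stdout_path = stdout_path,
                         stderr_path = stderr_path,
                         env = env,
                         workdir = workdir,
                         container_argv = NULL), class = "command_plan")
  docker <- tool$requirements$DockerRequirement
  if (!is.null(docker))
    plan$container_argv <- build_container_argv(plan, docker, "docker")
  plan
}

#' @export
print.command_plan <- function(x, ...) {
  cat("<command_plan>", paste(shQuote(x$argv), collapse = " "), "\n")
  if (!is.null(x$stdin_path)) cat("  stdin <", x$stdin_path, "\n")
  if (!is.null(x$stdout_path)) cat("  stdout >", x$stdout_path, "\n")
  invisible(x)
}

#' Construct a container-wrapped invocation
#'
#' Pure construction: builds the full `docker run` / `singularity exec`
#' argument vector (bind-mounting the working directory) without executing
#' anything. Whether the wrapped or the plain command is executed is decided
#' by the engine configuration (`container_mode`).
#'
#' @param plan a `command_plan`
#' @param req DockerRequirement payload (must carry `image`)
#' @param engine "docker" or "singularity"
#' @return character vector: the wrapped argv
#' @export
build_container_argv <- function(plan, req, engine = c("docker", "singularity")) {
  engine <- match.arg(engine)
  image <- req$image %||% req$dockerPull %||% req$dockerImageId
  stopifnot(is_string(image), nzchar(image))
  if (engine == "docker") {
    c("docker", "run", "--rm",
      "-v", paste0(plan$workdir, ":", plan$workdir),
      "-w", plan$workdir,
      image, plan$argv)
  } else {
    c("singularity", "exec",
      "--bind", paste0(plan$workdir, ":", plan$workdir),
      "--pwd", plan$workdir,
      paste0("docker://", image), plan$argv)
  }
}

# --- staging ----------------------------------------------------------------

#' Stage step input files into a working directory
#'
#' File values are made readable from the step's context by symlinking into
#' `workdir` (copy fallback when linking fails); returned values have File
#' paths rewritten to the staged locations and gain a `basename` field.
#' Scalars pass through untouched.
#'
#' @param job_values named list of concrete input values
#' @param workdir fresh per-(run, task) working directory
#' @return the mapping with File paths rewritten
#' @export
stage_step <- function(job_values, workdir) {
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  stage_one <- function(v) {
    if (is_file_value(v)) {
      src <- file_value_path(v)
      if (!file.exists(src))
        cwl_abort("staging_error",
                  sprintf("input file '%s' is missing or unreadable", src))
      dest <- file.path(workdir, basename(src))
      if (!file.exists(dest)) {
        ok <- suppressWarnings(file.symlink(src, dest))
        if (!ok) ok <- file.copy(src, dest)
        if (!ok)
          cwl_abort("staging_error", sprintf("cannot stage '%s' into '%s'",
                                             src, workdir))
      }
      return(list(class = "File", path = dest, basename = basename(src)))
    }
    if (is.list(v) && is.null(names(v))) return(lapply(v, stage_one))
    v
  }
  lapply(job_values, stage_one)
}

# --- process execution ------------------------------------------------------

#' Run a bound command
#'
#' Executes `plan$argv` with the working directory, environment and stream
#' redirections of the plan. A missing executable is a spawn error
#' (distinguished from a nonzero exit, which is returned, not thrown).
#'
#' @param plan a `command_plan`
#' @param log_path fallback file for streams not redirected by the plan
#' @return list with `exit_code`, `started_at`, `ended_at`
#' @export
run_process <- function(plan, log_path = NULL) {
  stopifnot(length(plan$argv) > 0L)
  exe <- Sys.which(plan$argv[[1]])
  if (!nzchar(exe) && !file.exists(plan$argv[[1]]))
    cwl_abort("spawn_error",
              sprintf("executable '%s' not found", plan$argv[[1]]))
  if (is.null(log_path)) log_path <- file.path(plan$workdir, ".task.log")
  stdout_to <- plan$stdout_path %||% log_path
  stderr_to <- plan$stderr_path %||% log_path
  env <- if (length(plan$env) > 0L)
    paste0(names(plan$env), "=", shQuote(plan$env)) else character()
  started <- timestamp_now()
  old_wd <- setwd(plan$workdir)
  on.exit(setwd(old_wd), add = TRUE)
  code <- suppressWarnings(system2(
    plan$argv[[1]], shQuote(plan$argv[-1]),
    stdout = stdout_to,
    stderr = if (identical(stdout_to, stderr_to)) stdout_to else stderr_to,
    stdin = plan$stdin_path %||% "",
    env = env))
  list(exit_code = code, started_at = started, ended_at = timestamp_now())
}

# --- output collection ------------------------------------------------------

file_artifact <- function(path, run_uid = NULL, task_id = NULL, output_id = NULL) {
  list(class = "File",
       path = path,
       basename = basename(path),
       size_bytes = as.numeric(file.size(path)),
       checksum = file_checksum(path),
       produced_by = list(run_uid = run_uid, task_id = task_id,
                          output_id = output_id))
}

#' Collect a step's declared outputs from its working directory
#'
#' stdout-captured outputs become the artifact of the redirected stdout
#' file; glob-bound outputs match their pattern (after parameter-reference
#' evaluation) relative to the working directory, sorted lexicographically
#' by basename. A non-optional File output with zero matches is a
#' missing-output error; more than one match on a non-array output is
#' ambiguous. Only File, array-of-File and stdout outputs are in the
#' supported subset.
#'
#' @param tool the `cwl_tool` that ran
#' @param workdir its working directory
#' @param plan the executed `command_plan`
#' @param values the input values used (for references in glob patterns)
#' @param produced_by optional list(run_uid, task_id) stamped on artifacts
#' @return named list output-id -> FileArtifact or list of FileArtifacts
#' @export
collect_outputs <- function(tool, workdir, plan, values = list(),
                            produced_by = list()) {
  context <- list(inputs = values, runtime = list(outdir = workdir, cores = 1L))
  out <- list()
  for (oid in names(tool$outputs)) {
    p <- tool$outputs[[oid]]
    if (!p$type$base %in% c("File", "stdout"))
      cwl_abort("unsupported_feature",
                sprintf("output '%s': only File/stdout outputs are supported", oid),
                feature = "non-file-output")
    if (identical(p$output_binding$capture, "stdout")) {
      if (is.null(plan$stdout_path) || !file.exists(plan$stdout_path))
        cwl_abort("missing_output",
                  sprintf("output '%s': captured stdout file is missing", oid),
                  output = oid)
      out[[oid]] <- file_artifact(plan$stdout_path,
                                  produced_by$run_uid, produced_by$task_id, oid)
      next
    }
    if (is.null(p$output_binding))
      cwl_abort("invalid_document",
                sprintf("output '%s' has no outputBinding", oid))
    pattern <- as.character(eval_param_ref(p$output_binding$glob, context))
    matches <- Sys.glob(file.path(workdir, pattern))
    matches <- matches[file.exists(matches) & !dir.exists(matches)]
    matches <- matches[order(basename(matches))]
    if (p$type$array) {
      out[[oid]] <- lapply(matches, file_artifact,
                           run_uid = produced_by$run_uid,
                           task_id = produced_by$task_id, output_id = oid)
    } else if (length(matches) == 0L) {
      if (p$type$optional) next
      cwl_abort("missing_output",
                sprintf("output '%s': no file matches glob '%s'", oid, pattern),
                output = oid, pattern = pattern)
    } else if (length(matches) > 1L) {
      cwl_abort("ambiguous_output",
                sprintf("output '%s': %d files match glob '%s'",
                        oid, length(matches), pattern),
                output = oid)
    } else {
      out[[oid]] <- file_artifact(matches[[1]],
                                  produced_by$run_uid, produced_by$task_id, oid)
    }
  }
  out
}

# --- one whole step ---------------------------------------------------------

# Stage, bind, run, collect: the unit of work a scheduler worker performs.
# Returns a step_result; never throws for a nonzero exit (that is a state).
execute_step <- function(step, values, workdir, run_uid, log_path,
                         container_mode = "none", cores = 1L) {
  staged <- stage_step(values, workdir)
  plan <- bind_command_line(step$tool, staged, workdir,
                            runtime = list(cores = cores))
  argv_used <- plan$argv
  if (container_mode != "none" && !is.null(step$tool$requirements$DockerRequirement))
    argv_used <- build_container_argv(plan, step$tool$requirements$DockerRequirement,
                                      container_mode)
  exec_plan <- plan
  exec_plan$argv <- argv_used
  res <- run_process(exec_plan, log_path = log_path)
  outputs <- NULL
  error <- NULL
  if (res$exit_code == 0L) {
    outputs <- tryCatch(
      collect_outputs(step$tool, workdir, plan, values = staged,
                      produced_by = list(run_uid = run_uid, task_id = step$id)),
      error = function(e) {
        error <<- conditionMessage(e)
        NULL
      })
    if (!is.null(error)) res$exit_code <- -1L
    missing <- setdiff(step$out_ids,
                       names(outputs %||% list()))
    # outputs keys must equal the step's declared out_ids on success;
    # optional outputs the step does not wire are tolerated
    if (is.null(error) && length(missing) > 0L) {
      error <- sprintf("step '%s' did not produce declared output(s): %s",
                       step$id, paste(missing, collapse = ", "))
      res$exit_code <- -1L
    }
  }
  list(task_id = step$id,
       exit_code = res$exit_code,
       outputs = outputs,
       error = error,
       started_at = res$started_at,
       ended_at = res$ended_at,
       log_path = log_path)
}
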