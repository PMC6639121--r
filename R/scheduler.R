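# The scheduler drives a task graph to completion: dependency-gated
# dispatch, a pool of concurrent fork workers for step processes, retries,
# failure propagation, pause/resume, step restart, crash recovery from the
# persisted store, and final delivery of declared outputs.

TERMINAL_TASK_STATES <- c("success", "failed", "upstream_failed")

#' Worker pool configuration
#'
#' @param worker_count number of concurrently running step tasks
#' @param queue_names priority classes, honored in lexicographic order
#' @param task_queue_assignment named list task_id -> queue name
#' @param retry_limit automatic re-queues after a failure (default 0)
#' @param poll_interval_s scheduler tick while waiting on running tasks
#' @return a `worker_pool_config`
#' @export
worker_pool_config <- function(worker_count = 1L,
                               queue_names = "default",
                               task_queue_assignment = list(),
                               retry_limit = 0L,
                               poll_interval_s = 0.05) {
  stopifnot(worker_count >= 1L, poll_interval_s > 0)
  assigned <- unlist(task_queue_assignment, use.names = FALSE)
  if (length(assigned) > 0L && !all(assigned %in% queue_names))
    cwl_abort("invalid_config", "task assigned to a queue not in queue_names")
  structure(list(worker_count = as.integer(worker_count),
                 queue_names = queue_names,
                 task_queue_assignment = task_queue_assignment,
                 retry_limit = as.integer(retry_limit),
                 poll_interval_s = poll_interval_s),
            class = "worker_pool_config")
}

new_task_state <- function(task_id, kind) {
  list(task_id = task_id, kind = kind, status = "pending", attempt = 0L,
       exit_code = NULL, started_at = NULL, ended_at = NULL,
       outputs = NULL, error = NULL, log_path = NULL)
}

set_task_status <- function(store, run, task_id, status) {
  old <- run$tasks[[task_id]]$status
  run$tasks[[task_id]]$status <- status
  log_event(store, run$run_uid, task_id, sprintf("%s -> %s", old, status))
  run
}

# Attach the built graph and fresh task states to a registered run.
attach_dag <- function(store, run, doc, dag) {
  run$dag <- dag_to_list(dag)
  run$dag_digest <- document_digest(doc)
  run$tasks <- stats::setNames(
    lapply(names(dag$nodes), function(tid)
      new_task_state(tid, dag$nodes[[tid]]$kind)),
    names(dag$nodes))
  store_save_run(store, run)
  run
}

#' Tasks eligible to start
#'
#' Exactly the pending tasks all of whose upstream tasks are in `success`,
#' ordered by (queue priority, task id) for reproducible traces.
#'
#' @param run a `cwl_run_state`
#' @param dag the run's `dag_graph`
#' @param pool a `worker_pool_config`
#' @return character vector of task ids
#' @export
ready_tasks <- function(run, dag, pool = worker_pool_config()) {
  ids <- names(dag$nodes)
  ready <- Filter(function(tid) {
    st <- run$tasks[[tid]]
    if (is.null(st) || st$status != "pending") return(FALSE)
    parents <- dag$nodes[[tid]]$upstream
    all(vapply(parents, function(p)
      identical(run$tasks[[p]]$status, "success"), logical(1)))
  }, ids)
  queue_of <- function(tid) pool$task_queue_assignment[[tid]] %||% "default"
  ready <- unlist(ready, use.names = FALSE) %||% character()
  ready[order(vapply(ready, queue_of, character(1)), ready)]
}

# --- JobDispatcher ----------------------------------------------------------

#' Serialize and provision a run's inputs (the JobDispatcher task)
#'
#' Validates the job against its workflow, resolves every File path to
#' absolute form, and persists the mapping, so all later steps read inputs
#' from the store and never from the job file again. Idempotent: a second
#' dispatch of the same run is a no-op.
#'
#' @param store a `cwl_run_store`
#' @param run the `cwl_run_state`
#' @param doc the workflow `cwl_document`
#' @return the updated run state
#' @export
dispatch_job <- function(store, run, doc) {
  if (!is.null(run$dispatched_inputs)) return(run)
  job <- run$job
  diags <- validate_job(structure(job, class = "job_descriptor"), doc)
  if (has_errors(diags))
    cwl_abort("validation_error",
              paste(diags$message[diags$level == "error"], collapse = "; "),
              diagnostics = diags)
  job_dir <- dirname(job$source_file)
  resolve <- function(v) {
    if (is_file_value(v)) {
      p <- abs_path(file_value_path(v), job_dir)
      return(list(class = "File", path = p, basename = basename(p)))
    }
    if (is.list(v) && is.null(names(v))) return(lapply(v, resolve))
    v
  }
  run$dispatched_inputs <- lapply(run$job$inputs, resolve)
  # workflow-input defaults fill gaps left by the job
  for (iid in names(doc$body$inputs)) {
    p <- doc$body$inputs[[iid]]
    if (is.null(run$dispatched_inputs[[iid]]) && !is.null(p$default_value))
      run$dispatched_inputs[[iid]] <- resolve(p$default_value)
  }
  store_save_run(store, run)
  run
}

# Concrete input values for one step, resolved from the dispatched inputs
# and upstream task outputs.
step_input_values <- function(run, wf, step) {
  values <- list()
  for (iid in names(step$in_bindings)) {
    b <- step$in_bindings[[iid]]
    v <- NULL
    if (!is.null(b$source)) {
      if (grepl("/", b$source)) {
        parts <- strsplit(b$source, "/", fixed = TRUE)[[1]]
        v <- run$tasks[[parts[[1]]]]$outputs[[parts[[2]]]]
      } else {
        v <- run$dispatched_inputs[[b$source]]
      }
    }
    if (is.null(v)) v <- b$default
    if (!is.null(v)) values[[iid]] <- v
  }
  values
}

# --- JobCleanup -------------------------------------------------------------

#' Deliver a run's declared outputs (the JobCleanup task)
#'
#' Moves the workflow-declared outputs (and only those) into the job's
#' output folder atomically (copy to a temporary name inside the target
#' volume, then rename), writes a JSON manifest next to them, and removes
#' the run's temp working directories unless `keep_temp`.
#'
#' @param store a `cwl_run_store`
#' @param run the `cwl_run_state` (all step tasks in success)
#' @param doc the workflow document
#' @param temp_folder the engine temp folder holding the run's workdirs
#' @param keep_temp retain temp directories after delivery
#' @return the delivered-output manifest (list)
#' @export
cleanup_job <- function(store, run, doc, temp_folder, keep_temp = FALSE) {
  wf <- doc$body
  out_folder <- run$job$output_folder
  ok <- dir.create(out_folder, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_folder) || file.access(out_folder, 2L) != 0L)
    cwl_abort("delivery_error",
              sprintf("output folder '%s' is not writable", out_folder))
  manifest <- list()
  for (oid in names(wf$outputs)) {
    src_ref <- wf$outputs[[oid]]$output_source
    parts <- strsplit(src_ref, "/", fixed = TRUE)[[1]]
    value <- if (length(parts) == 2L)
      run$tasks[[parts[[1]]]]$outputs[[parts[[2]]]]
    else run$dispatched_inputs[[src_ref]]
    arts <- if (is_file_value(value)) list(value) else value
    delivered <- list()
    for (art in arts) {
      src <- file_value_path(art)
      if (!file.exists(src))
        cwl_abort("delivery_error", sprintf("artifact '%s' vanished", src))
      src <- normalizePath(src)    # resolve staging symlinks
      dest <- file.path(out_folder, basename(src))
      tmp <- tempfile(tmpdir = out_folder, fileext = ".partial")
      if (!file.copy(src, tmp, overwrite = TRUE))
        cwl_abort("delivery_error", sprintf("cannot write into '%s'", out_folder))
      file.rename(tmp, dest)
      delivered[[length(delivered) + 1L]] <- list(
        output_id = oid, basename = basename(dest),
        size_bytes = as.numeric(file.size(dest)),
        checksum = file_checksum(dest))
    }
    manifest <- c(manifest, delivered)
  }
  manifest_path <- file.path(out_folder, "manifest.json")
  atomic_write_json(list(uid = run$run_uid,
                         delivered_at = timestamp_now(),
                         outputs = manifest), manifest_path)
  run_temp <- file.path(temp_folder, run$run_uid)
  if (!keep_temp && dir.exists(run_temp))
    unlink(run_temp, recursive = TRUE)
  list(outputs = manifest, manifest_path = manifest_path)
}

# --- the execution loop -----------------------------------------------------

run_is_terminal <- function(run) run$status %in% c("success", "failed", "rejected")

finalize_run <- function(store, run) {
  statuses <- vapply(run$tasks, `[[`, character(1), "status")
  if (all(statuses == "success")) {
    run$status <- "success"
  } else if (any(statuses %in% c("failed", "upstream_failed"))) {
    run$status <- "failed"
  }
  run$finished_at <- timestamp_now()
  log_event(store, run$run_uid, "-", sprintf("run -> %s", run$status))
  store_save_run(store, run)
  run
}

# Fork one step task. The child performs stage/bind/run/collect, writes its
# step_result as JSON next to the working directory (atomic rename), and
# exits. Results are handed over through the filesystem, not the fork's
# result pipe, so a killed engine never strands a worker (and a worker's
# result survives for the resuming engine to observe).
launch_step_fork <- function(step, values, workdir, run_uid, log_path,
                             container_mode, result_path) {
  job <- parallel::mcparallel({
    res <- tryCatch(
      execute_step(step, values, workdir, run_uid, log_path,
                   container_mode = container_mode),
      error = function(e) list(task_id = step$id, exit_code = -1L,
                               outputs = NULL, error = conditionMessage(e),
                               started_at = timestamp_now(),
                               ended_at = timestamp_now(),
                               log_path = log_path))
    atomic_write_json(res, result_path)
    # exit without any R shutdown: a forked child shares the engine's session
    # tempdir and connections, so normal quit() would destroy engine state,
    # and the fork's result pipe may have no reader if the engine was killed
    tools::pskill(Sys.getpid(), tools::SIGKILL)
  }, silent = TRUE)
  job
}

# a worker process is alive while its pid exists (procfs; fall back to a
# zero-signal probe elsewhere)
worker_alive <- function(pid) {
  if (dir.exists("/proc")) return(dir.exists(sprintf("/proc/%d", pid)))
  tools::pskill(pid, 0L)
}

#' Execute a run to a terminal (or paused) state
#'
#' The core loop: ready tasks are queued and started — the dispatcher and
#' cleanup endpoints inline, step tasks on a pool of `worker_count` forked
#' workers running concurrently; every state transition is persisted before
#' the next is considered. A task failing with its retry budget exhausted
#' marks all transitive descendants `upstream_failed`. A pause request is
#' honored at the next tick: running tasks finish, pending tasks hold.
#'
#' @param store a `cwl_run_store`
#' @param uid the run to execute
#' @param pool a `worker_pool_config`
#' @param config an `engine_config` (temp folder, container mode, keep_temp)
#' @param doc the workflow document; reloaded from the job when NULL
#' @param on_task_complete optional callback `function(task_id, run)` fired
#'   after each task reaches a terminal state (observability hook; also the
#'   deterministic way to pause after a given task)
#' @return the final `cwl_run_state`
#' @export
execute_run <- function(store, uid, pool = worker_pool_config(),
                        config = NULL, doc = NULL,
                        on_task_complete = NULL) {
  run <- store_load_run(store, uid)
  if (run_is_terminal(run)) return(run)
  if (is.null(config)) config <- engine_config(store_path = store$root)
  if (is.null(doc)) doc <- load_document(run$job$workflow_path)
  if (!is.null(run$dag_digest) && !identical(run$dag_digest, document_digest(doc)))
    cwl_abort("digest_mismatch",
              sprintf("workflow file for run '%s' changed since the graph was built", uid))
  if (is.null(run$dag)) {
    dag <- build_dag(doc, structure(run$job, class = "job_descriptor"))
    run <- attach_dag(store, run, doc, dag)
  } else {
    dag <- dag_from_list(run$dag)
  }
  wf <- doc$body
  run$status <- "running"
  run$paused <- FALSE
  store_save_run(store, run)

  forks <- list()          # task_id -> parallelJob
  temp_root <- config$temp_folder

  fail_task <- function(run, tid, result) {
    run$tasks[[tid]]$exit_code <- result$exit_code
    run$tasks[[tid]]$error <- result$error
    run$tasks[[tid]]$ended_at <- result$ended_at %||% timestamp_now()
    if (run$tasks[[tid]]$attempt <= pool$retry_limit) {
      run <- set_task_status(store, run, tid, "pending")   # re-queue (retry)
    } else {
      run <- set_task_status(store, run, tid, "failed")
      for (d in dag_descendants(dag, tid)) {
        if (!run$tasks[[d]]$status %in% TERMINAL_TASK_STATES)
          run <- set_task_status(store, run, d, "upstream_failed")
      }
    }
    run
  }

  complete_task <- function(run, tid, result) {
    if (result$exit_code == 0L) {
      run$tasks[[tid]]$exit_code <- 0L
      run$tasks[[tid]]$outputs <- result$outputs
      run$tasks[[tid]]$started_at <- result$started_at
      run$tasks[[tid]]$ended_at <- result$ended_at
      run$tasks[[tid]]$log_path <- result$log_path
      run <- set_task_status(store, run, tid, "success")
    } else {
      run$tasks[[tid]]$started_at <- result$started_at
      run$tasks[[tid]]$log_path <- result$log_path
      run <- fail_task(run, tid, result)
    }
    store_save_run(store, run)
    if (!is.null(on_task_complete)) on_task_complete(tid, run)
    store_load_run(store, uid)     # the hook may have paused the run
  }

  run_endpoint_task <- function(run, tid) {
    run$tasks[[tid]]$attempt <- run$tasks[[tid]]$attempt + 1L
    run$tasks[[tid]]$started_at <- timestamp_now()
    run <- set_task_status(store, run, tid, "running")
    store_save_run(store, run)
    result <- tryCatch({
      if (tid == DISPATCHER_ID) {
        run <- dispatch_job(store, run, doc)
      } else {
        delivered <- cleanup_job(store, run, doc, temp_root,
                                 keep_temp = isTRUE(config$keep_temp))
        run$delivery_manifest <- delivered$manifest_path
      }
      list(exit_code = 0L, outputs = NULL, started_at = run$tasks[[tid]]$started_at,
           ended_at = timestamp_now(), log_path = NULL)
    }, cwldag_error = function(e)
      list(exit_code = -1L, outputs = NULL, error = conditionMessage(e),
           started_at = run$tasks[[tid]]$started_at,
           ended_at = timestamp_now(), log_path = NULL))
    complete_task(run, tid, result)
  }

  repeat {
    # re-read pause requests made from outside this process
    disk <- store_load_run(store, uid)
    run$paused <- isTRUE(disk$paused)

    statuses <- vapply(run$tasks, `[[`, character(1), "status")
    if (all(statuses %in% TERMINAL_TASK_STATES) && length(forks) == 0L)
      return(finalize_run(store, run))

    if (run$paused && length(forks) == 0L) {
      run$status <- "paused"
      log_event(store, run$run_uid, "-", "run -> paused")
      store_save_run(store, run)
      return(run)
    }

    launched <- FALSE
    if (!run$paused) {
      for (tid in ready_tasks(run, dag, pool)) {
        kind <- dag$nodes[[tid]]$kind
        if (kind != "step") {
          run <- run_endpoint_task(run, tid)
          launched <- TRUE
          break      # re-evaluate readiness after an endpoint task
        }
        if (length(forks) >= pool$worker_count) break
        run <- set_task_status(store, run, tid, "queued")
        run$tasks[[tid]]$attempt <- run$tasks[[tid]]$attempt + 1L
        run <- set_task_status(store, run, tid, "running")
        run$tasks[[tid]]$started_at <- timestamp_now()
        step <- wf$steps[[tid]]
        values <- step_input_values(run, wf, step)
        workdir <- file.path(temp_root, uid, tid,
                             sprintf("attempt%d", run$tasks[[tid]]$attempt))
        log_path <- task_log_path(store, uid, tid, run$tasks[[tid]]$attempt)
        run$tasks[[tid]]$log_path <- log_path
        store_save_run(store, run)
        result_path <- paste0(workdir, ".result.json")
        forks[[tid]] <- list(
          job = launch_step_fork(step, values, workdir, uid, log_path,
                                 config$container_mode %||% "none",
                                 result_path),
          result_path = result_path)
        launched <- TRUE
      }
    }

    if (length(forks) > 0L) {
      finished <- character()
      for (tid in names(forks)) {
        rp <- forks[[tid]]$result_path
        result <- NULL
        if (file.exists(rp)) {
          result <- read_json_file(rp)
          result$exit_code <- as.integer(result$exit_code)
        } else if (!worker_alive(forks[[tid]]$job$pid)) {
          # the worker renames its result file before exiting, so a dead
          # worker without a result genuinely produced none
          result <- list(task_id = tid, exit_code = -1L, outputs = NULL,
                         error = "worker process died without a result",
                         ended_at = timestamp_now(),
                         log_path = run$tasks[[tid]]$log_path)
        }
        if (!is.null(result)) {
          suppressWarnings(parallel::mccollect(forks[[tid]]$job, wait = FALSE))
          result$started_at <- result$started_at %||% run$tasks[[tid]]$started_at
          run <- complete_task(run, tid, result)
          finished <- c(finished, tid)
        }
      }
      forks[finished] <- NULL
      if (length(finished) == 0L && !launched)
        Sys.sleep(pool$poll_interval_s)
    } else if (!launched) {
      statuses <- vapply(run$tasks, `[[`, character(1), "status")
      if (!any(statuses == "pending") || run$paused) next
      # pending tasks but nothing ready and nothing running: blocked
      Sys.sleep(pool$poll_interval_s)
    }
  }
}

# --- lifecycle --------------------------------------------------------------

#' Pause a run
#'
#' Running tasks are allowed to finish; pending tasks are held. The request
#' is persisted, so it also reaches an engine executing the run in another
#' process at its next scheduler tick.
#'
#' @param store a `cwl_run_store`
#' @param uid run identifier
#' @return the updated `cwl_run_state`
#' @export
pause_run <- function(store, uid) {
  run <- store_load_run(store, uid)
  if (run_is_terminal(run)) return(run)
  run$paused <- TRUE
  log_event(store, uid, "-", "pause requested")
  store_save_run(store, run)
}

#' Resume a paused or interrupted run
#'
#' Releases held tasks and continues execution, reusing every persisted
#' completed task verbatim — nothing already succeeded is redone. Tasks the
#' store recorded as queued/running (an engine killed mid-run) are reset to
#' pending and re-executed. Resume refuses to proceed when the workflow
#' file changed since the graph was built (digest mismatch). Resuming a
#' never-paused terminal run is a no-op.
#'
#' @inheritParams execute_run
#' @return the final `cwl_run_state`
#' @export
resume_run <- function(store, uid, pool = worker_pool_config(),
                       config = NULL, on_task_complete = NULL) {
  run <- store_load_run(store, uid)
  if (run_is_terminal(run)) return(run)
  doc <- load_document(run$job$workflow_path)
  if (!is.null(run$dag_digest) && !identical(run$dag_digest, document_digest(doc)))
    cwl_abort("digest_mismatch",
              sprintf("workflow file for run '%s' changed since it was paused", uid))
  for (tid in names(run$tasks)) {
    if (run$tasks[[tid]]$status %in% c("queued", "running", "paused-hold"))
      run <- set_task_status(store, run, tid, "pending")
  }
  run$paused <- FALSE
  store_save_run(store, run)
  execute_run(store, uid, pool = pool, config = config, doc = doc,
              on_task_complete = on_task_complete)
}

#' Restart a step (optionally with its descendants)
#'
#' Resets the target task to pending — reusing upstream successes and their
#' persisted outputs verbatim — and, with `cascade`, every transitive
#' descendant as well. Descendants that never ran (`upstream_failed`) are
#' released to pending in either mode. The run re-enters `running` and is
#' executed to a terminal state.
#'
#' @inheritParams execute_run
#' @param task_id the task to restart
#' @param cascade also reset all transitive descendants
#' @return the final `cwl_run_state`
#' @export
restart_step <- function(store, uid, task_id, cascade = FALSE,
                         pool = worker_pool_config(), config = NULL,
                         on_task_complete = NULL) {
  run <- store_load_run(store, uid)
  if (!task_id %in% names(run$tasks))
    cwl_abort("unknown_task",
              sprintf("run '%s' has no task '%s'", uid, task_id), task = task_id)
  dag <- dag_from_list(run$dag)
  reset <- function(run, tid) {
    run$tasks[[tid]]$exit_code <- NULL
    run$tasks[[tid]]$outputs <- NULL
    run$tasks[[tid]]$error <- NULL
    run$tasks[[tid]]$ended_at <- NULL
    set_task_status(store, run, tid, "pending")
  }
  run <- reset(run, task_id)
  for (d in dag_descendants(dag, task_id)) {
    if (cascade || run$tasks[[d]]$status == "upstream_failed")
      run <- reset(run, d)
  }
  run$status <- "running"
  run$finished_at <- NULL
  run$paused <- FALSE
  store_save_run(store, run)
  execute_run(store, uid, pool = pool, config = config,
              on_task_complete = on_task_complete)
}
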