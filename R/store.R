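# Run-state store: a directory of per-run JSON documents plus an append-only
# transition log. Every state change is one atomic file replacement
# (write-temp-then-rename), which is what makes killing the engine mid-run
# recoverable: the store is always a consistent snapshot of the last
# completed transition.

#' Open (creating if needed) a run-state store
#'
#' @param path store directory; created if absent
#' @return a `cwl_run_store` handle
#' @export
run_store <- function(path) {
  for (d in c("", "runs", "rejected", "logs"))
    dir.create(file.path(path, d), recursive = TRUE, showWarnings = FALSE)
  structure(list(root = normalizePath(path)), class = "cwl_run_store")
}

#' @export
print.cwl_run_store <- function(x, ...) {
  cat(sprintf("<cwl_run_store> %s (%d runs, %d rejections)\n", x$root,
              length(store_list_run_uids(x)), nrow(store_rejections(x))))
  invisible(x)
}

run_file <- function(store, uid) file.path(store$root, "runs", paste0(uid, ".json"))

#' @rdname run_store
#' @param uid run identifier
#' @export
store_has_run <- function(store, uid) file.exists(run_file(store, uid))

store_list_run_uids <- function(store) {
  sub("\\.json$", "", list.files(file.path(store$root, "runs"), "\\.json$"))
}

# Register a freshly discovered job: creates the RunState document in status
# "registered". Duplicate uid registration is rejected.
store_register_run <- function(store, job) {
  if (store_has_run(store, job$uid))
    cwl_abort("duplicate_uid",
              sprintf("uid '%s' is already registered", job$uid), uid = job$uid)
  run <- structure(list(
    run_uid = job$uid,
    status = "registered",
    created_at = timestamp_now(),
    finished_at = NULL,
    job = unclass(job),
    dag_digest = NULL,
    dag = NULL,
    dispatched_inputs = NULL,
    paused = FALSE,
    tasks = stats::setNames(list(), character())
  ), class = "cwl_run_state")
  store_save_run(store, run)
  run
}

store_save_run <- function(store, run) {
  doc <- unclass(run)
  doc$job <- unclass(doc$job)
  atomic_write_json(doc, run_file(store, run$run_uid))
  invisible(run)
}

store_load_run <- function(store, uid) {
  if (!store_has_run(store, uid))
    cwl_abort("unknown_run", sprintf("no run with uid '%s'", uid), uid = uid)
  run <- read_json_file(run_file(store, uid))
  run$job <- structure(run$job, class = "job_descriptor")
  structure(run, class = "cwl_run_state")
}

# --- rejected runs ----------------------------------------------------------

rejection_file <- function(store, hash) {
  file.path(store$root, "rejected", paste0(hash, ".json"))
}

store_has_rejection <- function(store, hash) file.exists(rejection_file(store, hash))

store_record_rejection <- function(store, hash, source_file, reason) {
  atomic_write_json(list(content_hash = hash,
                         source_file = source_file,
                         reason = reason,
                         recorded_at = timestamp_now()),
                    rejection_file(store, hash))
  log_event(store, "-", "-", sprintf("rejected: %s (%s)", source_file, reason))
  invisible(NULL)
}

#' Rejected job files recorded in a store
#' @param store a `cwl_run_store`
#' @return data frame with columns source_file, reason, recorded_at
#' @export
store_rejections <- function(store) {
  files <- list.files(file.path(store$root, "rejected"), "\\.json$",
                      full.names = TRUE)
  recs <- lapply(files, read_json_file)
  data.frame(
    source_file = vapply(recs, `[[`, character(1), "source_file"),
    reason = vapply(recs, `[[`, character(1), "reason"),
    recorded_at = vapply(recs, `[[`, numeric(1), "recorded_at"),
    stringsAsFactors = FALSE)
}

# --- transition log ---------------------------------------------------------

# One line per state transition: timestamp, run uid, task id, message.
log_event <- function(store, uid, task_id, message) {
  line <- sprintf("%.3f\t%s\t%s\t%s", timestamp_now(), uid, task_id, message)
  cat(line, "\n", sep = "", file = file.path(store$root, "transitions.log"),
      append = TRUE)
  invisible(NULL)
}

# --- per-task log files -----------------------------------------------------

task_log_path <- function(store, uid, task_id, attempt) {
  dir <- file.path(store$root, "logs", uid)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file.path(dir, sprintf("%s.attempt%d.log", task_id, attempt))
}

# --- history ----------------------------------------------------------------

#' Run execution history
#'
#' Read-only summary of every run in the store: uid, workflow, status,
#' created/finished timestamps and per-task durations, newest first.
#'
#' @param store a `cwl_run_store`
#' @return list of run summaries ordered by created_at descending
#' @export
run_history <- function(store) {
  uids <- store_list_run_uids(store)
  runs <- lapply(uids, function(u) store_load_run(store, u))
  created <- vapply(runs, function(r) r$created_at, numeric(1))
  runs <- runs[order(created, decreasing = TRUE)]
  lapply(runs, function(r) {
    tasks <- lapply(r$tasks, function(t) {
      dur <- if (!is.null(t$started_at) && !is.null(t$ended_at))
        t$ended_at - t$started_at else NA_real_
      list(task_id = t$task_id, status = t$status, attempt = t$attempt,
           duration_s = dur, started_at = t$started_at, ended_at = t$ended_at)
    })
    list(uid = r$run_uid,
         workflow = r$job$workflow_path,
         status = r$status,
         created_at = r$created_at,
         finished_at = r$finished_at,
         tasks = tasks)
  })
}
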