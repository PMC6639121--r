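# Engine configuration and the high-level one-shot / watch entry points.

#' Engine configuration
#'
#' Folder layout and execution knobs shared by the whole engine. All folders
#' are created on startup if absent. Values come from (lowest to highest
#' precedence) defaults, a YAML config file, and explicit arguments.
#'
#' @param jobs_folder watched folder for job files
#' @param temp_folder working directories for step execution
#' @param output_default default output folder root (jobs name their own)
#' @param store_path run-state store directory
#' @param worker_count concurrent step tasks per run
#' @param poll_interval_s jobs-folder polling interval (seconds)
#' @param container_mode "none" (construct container argv but execute the
#'   plain command), "docker" or "singularity"
#' @param keep_temp retain per-run temp directories after delivery
#' @param retry_limit automatic retries per task
#' @param log_level "debug", "info" or "warn"
#' @param config_file optional YAML file with any of the above keys
#' @return an `engine_config`
#' @export
engine_config <- function(jobs_folder = file.path(tempdir(), "cwldag", "jobs"),
                          temp_folder = file.path(tempdir(), "cwldag", "temp"),
                          output_default = file.path(tempdir(), "cwldag", "output"),
                          store_path = file.path(tempdir(), "cwldag", "store"),
                          worker_count = 1L,
                          poll_interval_s = 3,
                          container_mode = c("none", "docker", "singularity"),
                          keep_temp = FALSE,
                          retry_limit = 0L,
                          log_level = "info",
                          config_file = NULL) {
  explicit <- as.list(match.call())[-1]
  cfg <- list(jobs_folder = jobs_folder, temp_folder = temp_folder,
              output_default = output_default, store_path = store_path,
              worker_count = worker_count, poll_interval_s = poll_interval_s,
              container_mode = match.arg(container_mode),
              keep_temp = keep_temp, retry_limit = retry_limit,
              log_level = log_level)
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    for (k in intersect(names(file_cfg), names(cfg))) {
      if (!k %in% names(explicit)) cfg[[k]] <- file_cfg[[k]]
    }
  }
  stopifnot(cfg$worker_count >= 1L, cfg$poll_interval_s > 0)
  for (d in c(cfg$jobs_folder, cfg$temp_folder, cfg$output_default))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dirname(cfg$store_path)))
    cwl_abort("invalid_config",
              sprintf("parent of store_path '%s' does not exist", cfg$store_path))
  structure(cfg, class = "engine_config")
}

config_pool <- function(config) {
  worker_pool_config(worker_count = config$worker_count,
                     retry_limit = config$retry_limit)
}

#' Run one workflow + job end to end
#'
#' Parse, validate, register, build the task graph, execute it, and deliver
#' outputs. The one-shot equivalent of dropping a job file into the watched
#' jobs folder.
#'
#' @param workflow_path path to the CWL Workflow descriptor; when NULL the
#'   job file's mandatory `workflow` field is used
#' @param job_path path to the job file
#' @param config an `engine_config`
#' @param on_task_complete optional per-task callback (see [execute_run()])
#' @return the final `cwl_run_state`
#' @export
run_job <- function(job_path, workflow_path = NULL,
                    config = engine_config(),
                    on_task_complete = NULL) {
  store <- run_store(config$store_path)
  job <- parse_job_file(job_path)
  if (!is.null(workflow_path)) job$workflow_path <- abs_path(workflow_path)
  doc <- load_document(job$workflow_path)
  diags <- bind_diagnostics(validate_connectivity(doc), validate_job(job, doc))
  if (has_errors(diags))
    cwl_abort("validation_error",
              paste(diags$message[diags$level == "error"], collapse = "; "),
              diagnostics = diags)
  run <- store_register_run(store, job)
  dag <- build_dag(doc, job)
  run <- attach_dag(store, run, doc, dag)
  execute_run(store, job$uid, pool = config_pool(config), config = config,
              doc = doc, on_task_complete = on_task_complete)
}

#' Watch a jobs folder and execute arriving jobs
#'
#' Scans the configured jobs folder every `poll_interval_s` seconds,
#' registers new job files and executes each registered run to a terminal
#' state. Malformed files become rejected-run records (reported once per
#' content) and do not stop the service. Runs sequentially in this process;
#' each run's steps still use the configured worker pool.
#'
#' @param config an `engine_config`
#' @param max_cycles stop after this many scan cycles (NULL = run forever);
#'   an interrupt also stops the service, leaving the store resumable
#' @return uids of runs executed, invisibly
#' @export
watch_jobs <- function(config = engine_config(), max_cycles = NULL) {
  store <- run_store(config$store_path)
  executed <- character()
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    jobs <- scan_jobs_folder(config$jobs_folder, store)
    for (job in jobs) {
      res <- tryCatch({
        doc <- load_document(job$workflow_path)
        diags <- bind_diagnostics(validate_connectivity(doc),
                                  validate_job(job, doc))
        if (has_errors(diags))
          cwl_abort("validation_error",
                    paste(diags$message[diags$level == "error"], collapse = "; "))
        run <- store_load_run(store, job$uid)
        dag <- build_dag(doc, job)
        attach_dag(store, run, doc, dag)
        execute_run(store, job$uid, pool = config_pool(config),
                    config = config, doc = doc)
      }, cwldag_error = function(e) {
        run <- store_load_run(store, job$uid)
        run$status <- "rejected"
        run$error <- conditionMessage(e)
        store_save_run(store, run)
        log_event(store, job$uid, "-", sprintf("rejected: %s", conditionMessage(e)))
        run
      })
      executed <- c(executed, job$uid)
    }
    if (!is.null(max_cycles) && cycle >= max_cycles) break
    if (is.null(max_cycles) || cycle < max_cycles) Sys.sleep(config$poll_interval_s)
  }
  invisible(executed)
}
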