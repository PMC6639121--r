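# State machine, dependency gating, worker pool, failure propagation,
# lifecycle (pause/resume/restart), crash recovery, delivery, history.

test_that("ready_tasks returns exactly the pending tasks with all parents succeeded", {
  d <- fresh_dir()
  write_diamond(d)
  job <- write_job(d, file.path(d, "wf.cwl"), "ready-1", file.path(d, "out"))
  doc <- load_document(file.path(d, "wf.cwl"))
  jd <- parse_job_file(job)
  dag <- build_dag(doc, jd)
  run <- list(tasks = stats::setNames(lapply(names(dag$nodes), function(t)
    list(task_id = t, status = "pending")), names(dag$nodes)))

  # brute-force recompute over all reachable state combinations of {A..D}
  expect_identical(ready_tasks(run, dag), "JobDispatcher")
  run$tasks$JobDispatcher$status <- "success"
  expect_identical(ready_tasks(run, dag), "A")
  run$tasks$A$status <- "success"
  expect_identical(ready_tasks(run, dag), c("B", "C"))
  run$tasks$B$status <- "success"
  expect_identical(ready_tasks(run, dag), "C")
  run$tasks$C$status <- "success"
  expect_identical(ready_tasks(run, dag), "D")
  run$tasks$D$status <- "success"
  expect_identical(ready_tasks(run, dag), "JobCleanup")
  run$tasks$JobCleanup$status <- "success"
  expect_length(ready_tasks(run, dag), 0L)
})

test_that("dispatch is idempotent and resolves file paths to absolute form", {
  d <- fresh_dir()
  write_diamond(d)
  job_path <- write_job(d, file.path(d, "wf.cwl"), "disp-1", file.path(d, "out"))
  cfg <- test_config(d)
  store <- run_store(cfg$store_path)
  job <- parse_job_file(job_path)
  doc <- load_document(job$workflow_path)
  run <- cwldag:::store_register_run(store, job)
  run <- dispatch_job(store, run, doc)
  expect_true(startsWith(run$dispatched_inputs$f$path, "/"))
  again <- dispatch_job(store, run, doc)
  expect_identical(run$dispatched_inputs, again$dispatched_inputs)
})

test_that("a run executes in dependency order and delivers exactly the declared outputs", {
  d <- fresh_dir()
  write_diamond(d)
  job <- write_job(d, file.path(d, "wf.cwl"), "dia-1", file.path(d, "out"))
  cfg <- test_config(d)
  run <- run_job(job, config = cfg)
  expect_identical(run$status, "success")
  statuses <- vapply(run$tasks, `[[`, character(1), "status")
  expect_true(all(statuses == "success"))           # steps + 2 all succeed
  expect_length(statuses, 6L)
  # executed order is a linear extension of the DAG
  dag <- cwldag:::dag_from_list(run$dag)
  order_seen <- run_task_order(run)
  exts <- oracle_linear_extensions(names(dag$nodes), dag$edges)
  expect_true(any(vapply(exts, identical, logical(1), order_seen)))
  # delivery: declared outputs + manifest only; temp removed
  expect_identical(sort(list.files(file.path(d, "out"))),
                   c("manifest.json", "out.txt"))
  expect_false(dir.exists(file.path(cfg$temp_folder, "dia-1")))
  # safety: no task started before its parents ended
  for (tid in names(dag$nodes)) {
    for (p in dag$nodes[[tid]]$upstream)
      expect_lte(run$tasks[[p]]$ended_at, run$tasks[[tid]]$started_at)
  }
})

test_that("worker counts 1 and 3 produce byte-identical delivered outputs", {
  d <- fresh_dir()
  write_diamond(d)
  sums <- lapply(c(1L, 3L), function(w) {
    sub <- file.path(d, paste0("w", w))
    dir.create(sub)
    job <- write_job(d, file.path(d, "wf.cwl"), paste0("dia-w", w),
                     file.path(sub, "out"),
                     file = file.path(sub, "job.yml"))
    cfg <- test_config(sub, worker_count = w)
    run <- run_job(job, config = cfg)
    expect_identical(run$status, "success")
    delivered_checksums(file.path(sub, "out"))
  })
  expect_identical(sums[[1]], sums[[2]])
})

test_that("a failing step fails the run, descendants become upstream_failed, nothing is delivered", {
  d <- fresh_dir()
  write_diamond(d, b_body = "exit 1")
  job <- write_job(d, file.path(d, "wf.cwl"), "fail-1", file.path(d, "out"))
  cfg <- test_config(d)
  run <- run_job(job, config = cfg)
  expect_identical(run$status, "failed")
  st <- vapply(run$tasks, `[[`, character(1), "status")
  expect_identical(st[["B"]], "failed")
  expect_identical(st[["D"]], "upstream_failed")
  expect_identical(st[["JobCleanup"]], "upstream_failed")
  expect_identical(st[["A"]], "success")
  expect_identical(st[["C"]], "success")
  expect_length(list.files(file.path(d, "out")), 0L)
  # temp retained for forensics on failure
  expect_true(dir.exists(file.path(cfg$temp_folder, "fail-1")))
})

test_that("retries re-queue a failing task until the limit", {
  d <- fresh_dir()
  # fails on first attempt, succeeds when the marker exists
  marker <- file.path(d, "marker")
  write_diamond(d, b_body = sprintf(
    'if [ -f %s ]; then cat "$1" > out.txt; else touch %s; exit 1; fi',
    marker, marker))
  job <- write_job(d, file.path(d, "wf.cwl"), "retry-1", file.path(d, "out"))
  cfg <- test_config(d, retry_limit = 1L)
  run <- run_job(job, config = cfg)
  expect_identical(run$status, "success")
  expect_identical(run$tasks$B$attempt, 2L)
  expect_identical(run$tasks$A$attempt, 1L)
})

test_that("pause lets running work finish and resume redoes nothing", {
  d <- fresh_dir()
  write_diamond(d)
  job <- write_job(d, file.path(d, "wf.cwl"), "pause-1", file.path(d, "out"))
  cfg <- test_config(d)
  store <- run_store(cfg$store_path)
  paused <- run_job(job, config = cfg, on_task_complete = function(tid, run) {
    if (tid == "A") pause_run(store, run$run_uid)
  })
  expect_identical(paused$status, "paused")
  expect_identical(paused$tasks$A$status, "success")
  expect_identical(paused$tasks$D$status, "pending")
  done <- resume_run(store, "pause-1", config = cfg)
  expect_identical(done$status, "success")
  expect_true(all(vapply(done$tasks, `[[`, integer(1), "attempt") == 1L))
  # resuming a terminal run is a no-op
  again <- resume_run(store, "pause-1", config = cfg)
  expect_identical(again$status, "success")
  expect_true(all(vapply(again$tasks, `[[`, integer(1), "attempt") == 1L))
})

test_that("resume refuses a run whose workflow file changed", {
  d <- fresh_dir()
  write_diamond(d)
  job <- write_job(d, file.path(d, "wf.cwl"), "digest-1", file.path(d, "out"))
  cfg <- test_config(d)
  store <- run_store(cfg$store_path)
  paused <- run_job(job, config = cfg, on_task_complete = function(tid, run) {
    if (tid == "A") pause_run(store, run$run_uid)
  })
  expect_identical(paused$status, "paused")
  wf <- yaml::read_yaml(file.path(d, "wf.cwl"))
  wf$steps$B$`in`$f <- "f"      # rewire: different graph
  yaml::write_yaml(wf, file.path(d, "wf.cwl"))
  expect_error(resume_run(store, "digest-1", config = cfg),
               class = "cwldag_digest_mismatch")
})

test_that("restart of a failed step re-runs exactly its descendant set", {
  d <- fresh_dir()
  write_diamond(d, b_body = "exit 1")
  job <- write_job(d, file.path(d, "wf.cwl"), "restart-1", file.path(d, "out"))
  cfg <- test_config(d)
  store <- run_store(cfg$store_path)
  run <- run_job(job, config = cfg)
  expect_identical(run$status, "failed")
  before <- vapply(run$tasks, `[[`, integer(1), "attempt")

  # repair the step's script (the workflow document is unchanged)
  writeLines(c("#!/bin/sh", 'cat "$1" > out.txt'), file.path(d, "bstep.sh"))
  fixed <- restart_step(store, "restart-1", "B", cascade = TRUE, config = cfg)
  expect_identical(fixed$status, "success")
  after <- vapply(fixed$tasks, `[[`, integer(1), "attempt")

  dag <- cwldag:::dag_from_list(fixed$dag)
  descendants <- oracle_descendants(dag$edges, "B")
  # B itself plus exactly its descendant set executed after the restart
  executed <- names(fixed$tasks)[vapply(names(fixed$tasks), function(t)
    fixed$tasks[[t]]$started_at > run$finished_at, logical(1))]
  expect_identical(sort(executed), sort(c("B", descendants)))
  expect_identical(after[["A"]], before[["A"]])
  expect_identical(after[["C"]], before[["C"]])
  expect_identical(sort(list.files(file.path(d, "out"))),
                   c("manifest.json", "out.txt"))
})

test_that("restart of an unknown task errors", {
  d <- fresh_dir()
  write_diamond(d)
  job <- write_job(d, file.path(d, "wf.cwl"), "unk-1", file.path(d, "out"))
  cfg <- test_config(d)
  store <- run_store(cfg$store_path)
  run_job(job, config = cfg)
  expect_error(restart_step(store, "unk-1", "nope", config = cfg),
               class = "cwldag_unknown_task")
})

test_that("killing the engine mid-run and resuming reproduces an uninterrupted run", {
  d <- fresh_dir()
  script <- file.path(d, "slow.sh")
  writeLines(c("#!/bin/sh", "sleep 0.4", 'cat "$1" > out.txt'), script)
  tool <- list(cwlVersion = "v1.0", class = "CommandLineTool",
               baseCommand = list("sh", script),
               inputs = list(f = list(type = "File",
                                      inputBinding = list(position = 1L))),
               outputs = list(out = list(type = "File",
                                         outputBinding = list(glob = "out.txt"))))
  yaml::write_yaml(tool, file.path(d, "slow.cwl"))
  wf <- list(cwlVersion = "v1.0", class = "Workflow",
             inputs = list(f = list(type = "File")),
             outputs = list(result = list(type = "File", outputSource = "C/out")),
             steps = list(A = list(run = "slow.cwl", `in` = list(f = "f"),
                                   out = list("out")),
                          B = list(run = "slow.cwl", `in` = list(f = "A/out"),
                                   out = list("out")),
                          C = list(run = "slow.cwl", `in` = list(f = "B/out"),
                                   out = list("out"))))
  yaml::write_yaml(wf, file.path(d, "wf.cwl"))
  writeLines("crash recovery data", file.path(d, "in.txt"))
  crash_job <- write_job(d, file.path(d, "wf.cwl"), "crash-1", file.path(d, "out1"))
  ref_job <- write_job(d, file.path(d, "wf.cwl"), "ref-1", file.path(d, "out2"))
  cfg <- test_config(d)
  store <- run_store(cfg$store_path)

  child <- parallel::mcparallel(run_job(crash_job, config = cfg))
  deadline <- Sys.time() + 20
  repeat {
    Sys.sleep(0.05)
    started <- tryCatch({
      r <- cwldag:::store_load_run(store, "crash-1")
      identical(r$tasks$A$status, "success")
    }, error = function(e) FALSE)
    if (started || Sys.time() > deadline) break
  }
  tools::pskill(child$pid, tools::SIGKILL)
  Sys.sleep(0.3)
  suppressWarnings(parallel::mccollect(child, wait = FALSE))
  interrupted <- cwldag:::store_load_run(store, "crash-1")
  expect_false(interrupted$status %in% c("success", "failed"))

  resumed <- resume_run(store, "crash-1", config = cfg)
  expect_identical(resumed$status, "success")
  reference <- run_job(ref_job, config = cfg)
  expect_identical(reference$status, "success")
  expect_identical(delivered_checksums(file.path(d, "out1")),
                   delivered_checksums(file.path(d, "out2")))
})

test_that("keep_temp retains working directories with identical delivery", {
  d <- fresh_dir()
  write_diamond(d)
  job <- write_job(d, file.path(d, "wf.cwl"), "keep-1", file.path(d, "out"))
  cfg <- test_config(d, keep_temp = TRUE)
  run <- run_job(job, config = cfg)
  expect_identical(run$status, "success")
  expect_true(dir.exists(file.path(cfg$temp_folder, "keep-1")))
  expect_identical(sort(list.files(file.path(d, "out"))),
                   c("manifest.json", "out.txt"))
})

test_that("history lists runs newest first with per-task durations", {
  d <- fresh_dir()
  write_diamond(d)
  cfg <- test_config(d)
  store <- run_store(cfg$store_path)
  expect_length(run_history(store), 0L)
  for (uid in c("hist-1", "hist-2")) {
    job <- write_job(d, file.path(d, "wf.cwl"), uid,
                     file.path(d, paste0("out-", uid)))
    run_job(job, config = cfg)
  }
  hist <- run_history(store)
  expect_length(hist, 2L)
  expect_identical(hist[[1]]$uid, "hist-2")     # newest first
  expect_identical(hist[[2]]$uid, "hist-1")
  for (t in hist[[1]]$tasks) {
    expect_identical(t$duration_s, t$ended_at - t$started_at)
    expect_gte(t$duration_s, 0)
  }
})
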