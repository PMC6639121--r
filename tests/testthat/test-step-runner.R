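# Parameter references, command binding, staging, process execution,
# container argv construction, and output collection.

test_that("parameter references resolve with native types and interpolate in text", {
  ctx <- list(inputs = list(threads = 4L, sample = "s1",
                            reads = list(class = "File", path = "/d/in/a.fq")),
              runtime = list(outdir = "/tmp/wd", cores = 2L))
  expect_identical(eval_param_ref("$(inputs.threads)", ctx), 4L)
  expect_identical(eval_param_ref("out_$(inputs.sample).bam", ctx), "out_s1.bam")
  expect_identical(eval_param_ref("$(inputs.reads.basename)", ctx), "a.fq")
  expect_identical(eval_param_ref("$(inputs.reads.path)", ctx), "/d/in/a.fq")
  expect_identical(eval_param_ref("$(runtime.outdir)/x", ctx), "/tmp/wd/x")
  expect_identical(eval_param_ref("plain text", ctx), "plain text")
  expect_error(eval_param_ref("$(inputs.nope)", ctx),
               class = "cwldag_unknown_reference")
  expect_error(eval_param_ref("${ return 1 }", ctx),
               class = "cwldag_unsupported_expression")
})

test_that("bound argv matches the committed conformance expectations", {
  d <- fresh_dir()
  cases <- make_binding_suite(d)
  expect_length(cases, 12L)
  wd <- file.path(d, "wd")
  dir.create(wd)
  for (cs in cases) {
    expect_false(is.null(cs$expected_argv), label = paste("expectation for", cs$name))
    tool <- load_document(cs$tool)$body
    values <- yaml::read_yaml(cs$values)
    plan <- bind_command_line(tool, values, wd)
    file_paths <- vapply(Filter(function(v) is.list(v) &&
                                  identical(v$class, "File"), values),
                         `[[`, character(1), "path")
    got <- cwldag:::normalize_argv(plan$argv, file_paths)
    expect_identical(as.character(got), cs$expected_argv,
                     label = paste("argv of", cs$name))
  }
})

test_that("binding errors distinguish missing required inputs from type mismatches", {
  d <- fresh_dir()
  cases <- make_binding_suite(d)
  names(cases) <- vapply(cases, `[[`, character(1), "name")
  tool <- load_document(cases[["prefix-separate"]]$tool)$body
  wd <- file.path(d, "wd2"); dir.create(wd)
  expect_error(bind_command_line(tool, list(), wd),
               class = "cwldag_missing_required_input")
  expect_error(bind_command_line(tool, list(threads = "not-an-int"), wd),
               class = "cwldag_type_mismatch")
})

test_that("stdin and stdout redirections land in the plan", {
  d <- fresh_dir()
  cases <- make_binding_suite(d)
  names(cases) <- vapply(cases, `[[`, character(1), "name")
  cs <- cases[["stdio-redirect"]]
  tool <- load_document(cs$tool)$body
  values <- yaml::read_yaml(cs$values)
  wd <- file.path(d, "wd3"); dir.create(wd)
  plan <- bind_command_line(tool, values, wd)
  expect_identical(plan$stdin_path, values$src$path)
  expect_identical(plan$stdout_path, file.path(wd, "counted.txt"))
  res <- run_process(plan)
  expect_identical(res$exit_code, 0L)
  expect_true(file.exists(plan$stdout_path))
  outs <- collect_outputs(tool, wd, plan)
  expect_identical(names(outs), "counted")
  expect_identical(outs$counted$basename, "counted.txt")
})

test_that("staging links preserve content and missing sources fail", {
  d <- fresh_dir()
  src <- file.path(d, "data.txt")
  writeLines(c("alpha", "beta"), src)
  wd <- file.path(d, "wd")
  staged <- stage_step(list(f = list(class = "File", path = src),
                            n = 7L), wd)
  expect_identical(staged$n, 7L)
  expect_true(startsWith(staged$f$path, wd))
  expect_identical(file_checksum(staged$f$path), file_checksum(src))
  expect_error(stage_step(list(f = list(class = "File",
                                        path = file.path(d, "gone.txt"))),
                          file.path(d, "wd2")),
               class = "cwldag_staging_error")
})

test_that("process execution reports exit codes and distinguishes spawn failure", {
  d <- fresh_dir()
  plan <- function(argv) structure(list(argv = argv, workdir = d, env = character()),
                                   class = "command_plan")
  expect_identical(run_process(plan("true"))$exit_code, 0L)
  expect_identical(run_process(plan("false"))$exit_code, 1L)
  expect_error(run_process(plan("definitely-not-a-real-binary-xyz")),
               class = "cwldag_spawn_error")
})

test_that("container argv construction wraps without executing", {
  plan <- structure(list(argv = c("echo", "hi"), workdir = "/tmp/wd",
                         env = character()), class = "command_plan")
  dk <- build_container_argv(plan, list(image = "alpine:3"), "docker")
  expect_identical(dk[1:2], c("docker", "run"))
  expect_true(any(grepl("/tmp/wd:/tmp/wd", dk, fixed = TRUE)))
  expect_lt(which(dk == "alpine:3"), which(dk == "echo"))
  expect_identical(utils::tail(dk, 2L), c("echo", "hi"))
  sg <- build_container_argv(plan, list(image = "alpine:3"), "singularity")
  expect_identical(sg[[1]], "singularity")
  expect_true("exec" %in% sg)
  expect_true(any(grepl("alpine:3", sg, fixed = TRUE)))
})

test_that("glob collection sorts matches and enforces arity", {
  d <- fresh_dir()
  wd <- file.path(d, "wd"); dir.create(wd)
  writeLines("b", file.path(wd, "b.txt"))
  writeLines("a", file.path(wd, "a.txt"))
  mktool <- function(type) {
    p <- file.path(d, "t.cwl")
    yaml::write_yaml(list(cwlVersion = "v1.0", class = "CommandLineTool",
                          baseCommand = "true", inputs = list(),
                          outputs = list(res = list(type = type,
                                                    outputBinding = list(glob = "*.txt")))),
                     p)
    load_document(p)$body
  }
  plan <- structure(list(argv = "true", workdir = wd, env = character()),
                    class = "command_plan")
  arr <- collect_outputs(mktool("File[]"), wd, plan)
  expect_identical(vapply(arr$res, `[[`, character(1), "basename"),
                   c("a.txt", "b.txt"))
  expect_error(collect_outputs(mktool("File"), wd, plan),
               class = "cwldag_ambiguous_output")
  unlink(file.path(wd, c("a.txt", "b.txt")))
  expect_error(collect_outputs(mktool("File"), wd, plan),
               class = "cwldag_missing_output")
  expect_length(collect_outputs(mktool("File?"), wd, plan), 0L)
})

test_that("pass-through steps conserve checksums end to end", {
  d <- fresh_dir()
  write_script_tool(d, "copy", 'cat "$1" > out.txt')
  wf <- list(cwlVersion = "v1.0", class = "Workflow",
             inputs = list(f = list(type = "File")),
             outputs = list(result = list(type = "File", outputSource = "A/out")),
             steps = list(A = list(run = "copy.cwl", `in` = list(f = "f"),
                                   out = list("out"))))
  yaml::write_yaml(wf, file.path(d, "wf.cwl"))
  writeLines("conserved content", file.path(d, "in.txt"))
  job <- write_job(d, file.path(d, "wf.cwl"), "conserve-1", file.path(d, "out"))
  cfg <- test_config(d)
  run <- run_job(job, config = cfg)
  expect_identical(run$status, "success")
  expect_identical(file_checksum(file.path(d, "out", "out.txt")),
                   file_checksum(file.path(d, "in.txt")))
})
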