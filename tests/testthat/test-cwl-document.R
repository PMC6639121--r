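# Loading, validation and canonical serialization of CWL documents.

test_that("a minimal CommandLineTool loads with empty IO", {
  d <- fresh_dir()
  p <- file.path(d, "min.cwl")
  writeLines('{"cwlVersion": "v1.0", "class": "CommandLineTool",
              "baseCommand": ["echo"], "inputs": [], "outputs": []}', p)
  doc <- load_document(p)
  expect_s3_class(doc, "cwl_document")
  expect_identical(doc$class_kind, "CommandLineTool")
  expect_identical(doc$body$base_command, "echo")
  expect_length(doc$body$inputs, 0L)
  expect_length(doc$body$outputs, 0L)
})

test_that("the chipseq-shaped fixture loads with the manifest's steps resolved", {
  d <- fresh_dir()
  m <- make_chipseq_like(d, seed = 3)
  doc <- load_document(m$workflow)
  expect_identical(doc$class_kind, "Workflow")
  expect_identical(names(doc$body$steps), m$step_ids)
  for (step in doc$body$steps) {
    expect_s3_class(step$tool, "cwl_tool")   # every run_ref resolved
    expect_true(file.exists(step$run_ref))
  }
})

test_that("cwlVersion other than v1.0 is rejected", {
  d <- fresh_dir()
  p <- file.path(d, "v11.cwl")
  writeLines('{"cwlVersion": "v1.1", "class": "CommandLineTool",
              "baseCommand": ["echo"], "inputs": [], "outputs": []}', p)
  expect_error(load_document(p), class = "cwldag_version_error")
  writeLines('{"class": "CommandLineTool", "baseCommand": ["echo"],
              "inputs": [], "outputs": []}', p)
  expect_error(load_document(p), class = "cwldag_version_error")
})

test_that("features outside the subset are rejected naming the feature", {
  d <- fresh_dir()
  base <- list(cwlVersion = "v1.0", class = "CommandLineTool",
               baseCommand = "echo", inputs = list(), outputs = list())
  # unknown top-level key: nothing is silently dropped
  bad <- c(base, list(successCodes = list(0L, 1L)))
  p <- file.path(d, "bad.cwl")
  yaml::write_yaml(bad, p)
  expect_error(load_document(p), "successCodes",
               class = "cwldag_unsupported_feature")
  # scatter
  write_script_tool(d, "copy", 'cat "$1" > out.txt')
  wf <- list(cwlVersion = "v1.0", class = "Workflow",
             inputs = list(f = list(type = "File")),
             outputs = list(result = list(type = "File", outputSource = "A/out")),
             steps = list(A = list(run = "copy.cwl", scatter = "f",
                                   `in` = list(f = "f"), out = list("out"))))
  yaml::write_yaml(wf, file.path(d, "scatter.cwl"))
  expect_error(load_document(file.path(d, "scatter.cwl")), "scatter",
               class = "cwldag_unsupported_feature")
  # unknown requirement kind fails closed, naming the kind
  req <- c(base, list(requirements = list(list(class = "InlineJavascriptRequirement"))))
  yaml::write_yaml(req, file.path(d, "req.cwl"))
  expect_error(load_document(file.path(d, "req.cwl")),
               "InlineJavascriptRequirement",
               class = "cwldag_unsupported_feature")
  # only the ["null", T] union is accepted
  uni <- base
  uni$inputs <- list(x = list(type = list("string", "int")))
  yaml::write_yaml(uni, file.path(d, "union.cwl"))
  expect_error(load_document(file.path(d, "union.cwl")),
               class = "cwldag_unsupported_feature")
})

test_that("a dangling run reference is an unresolved-reference error", {
  d <- fresh_dir()
  wf <- list(cwlVersion = "v1.0", class = "Workflow",
             inputs = list(f = list(type = "File")),
             outputs = list(result = list(type = "File", outputSource = "A/out")),
             steps = list(A = list(run = "no-such-tool.cwl",
                                   `in` = list(f = "f"), out = list("out"))))
  yaml::write_yaml(wf, file.path(d, "wf.cwl"))
  expect_error(load_document(file.path(d, "wf.cwl")), "no-such-tool",
               class = "cwldag_unresolved_reference")
})

test_that("loading is deterministic and independent of key order", {
  d <- fresh_dir()
  writeLines('{"cwlVersion": "v1.0", "class": "CommandLineTool",
    "baseCommand": ["echo"],
    "inputs": {"msg": {"type": "string", "inputBinding": {"position": 1}}},
    "outputs": []}', file.path(d, "a.cwl"))
  writeLines('{"inputs": {"msg": {"inputBinding": {"position": 1}, "type": "string"}},
    "outputs": [], "class": "CommandLineTool",
    "baseCommand": ["echo"], "cwlVersion": "v1.0"}', file.path(d, "b.cwl"))
  expect_identical(document_signature(load_document(file.path(d, "a.cwl"))),
                   document_signature(load_document(file.path(d, "b.cwl"))))
})

test_that("canonical JSON round-trips to an equal representation", {
  d <- fresh_dir()
  m <- make_chipseq_like(d, seed = 5)
  doc <- load_document(m$workflow)
  out <- file.path(d, "canon.json")
  write_document(doc, out)
  doc2 <- load_document(out)
  expect_identical(document_signature(doc), document_signature(doc2))
  # and serializing the reloaded document is byte-stable
  out2 <- file.path(d, "canon2.json")
  write_document(doc2, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("connectivity validation flags dangling sources and type mismatches", {
  d <- fresh_dir()
  suite <- make_topology_suite(d)
  names(suite) <- vapply(suite, `[[`, character(1), "name")

  diamond <- load_document(suite[["diamond-4"]]$workflow)
  expect_identical(nrow(validate_connectivity(diamond)), 0L)

  dangling <- load_document(suite[["dangling-source-invalid"]]$workflow)
  diags <- validate_connectivity(dangling)
  expect_true(any(grepl("stepX/missing", diags$message)))
  expect_true(has_errors <- any(diags$level == "error"))

  # File output wired to an int input
  intake <- list(cwlVersion = "v1.0", class = "CommandLineTool",
                 baseCommand = "echo",
                 inputs = list(n = list(type = "int",
                                        inputBinding = list(position = 1L))),
                 outputs = list())
  yaml::write_yaml(intake, file.path(d, "intake.cwl"))
  write_script_tool(d, "copy", 'cat "$1" > out.txt')
  wf <- list(cwlVersion = "v1.0", class = "Workflow",
             inputs = list(f = list(type = "File")),
             outputs = list(result = list(type = "File", outputSource = "A/out")),
             steps = list(A = list(run = "copy.cwl", `in` = list(f = "f"),
                                   out = list("out")),
                          B = list(run = "intake.cwl",
                                   `in` = list(n = "A/out"), out = list())))
  yaml::write_yaml(wf, file.path(d, "mismatch.cwl"))
  diags <- validate_connectivity(load_document(file.path(d, "mismatch.cwl")))
  expect_identical(sum(diags$code == "type-mismatch"), 1L)
})
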