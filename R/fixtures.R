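# Generators for synthetic test material: a five-step pipeline shaped like a
# ChIP-Seq analysis (align, sort, index, peak calling, coverage) built from
# stub text-transform commands, a suite of topology-stress workflows, and a
# twelve-case command-line-binding conformance suite. Everything is
# generated from code — no downloads, no bioinformatics tools — and fully
# determined by (outdir, seed): the same call produces byte-identical trees.

write_lines <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, path)
  path
}

write_cwl_yaml <- function(obj, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(obj, path)
  path
}

write_stub <- function(path, body) {
  write_lines(c("#!/bin/sh", "set -eu", body), path)
  Sys.chmod(path, "0755")
  path
}

fixture_manifest <- function(name, step_ids, intended_edges,
                             expected_output_ids, seed, dir,
                             workflow = NULL, job = NULL, valid = TRUE) {
  structure(list(name = name, step_ids = step_ids,
                 intended_edges = intended_edges,
                 expected_output_ids = expected_output_ids,
                 seed = seed, dir = dir, workflow = workflow, job = job,
                 valid = valid),
            class = "fixture_manifest")
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf("<fixture_manifest> %s: %d steps, %d intended edges (%s)\n",
              x$name, length(x$step_ids), length(x$intended_edges),
              if (x$valid) "valid" else "invalid by construction"))
  invisible(x)
}

# seeded pseudo-reads: `count` uniform 4-letter strings of length `len`,
# one "id sequence" record per line
make_pseudo_reads <- function(path, seed, count = 1000L, len = 36L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  reads <- vapply(seq_len(count), function(i)
    paste(sample(bases, len, replace = TRUE), collapse = ""), character(1))
  write_lines(sprintf("read_%04d %s", seq_len(count), reads), path)
}

stub_tool <- function(script, input_ids, input_positions, output_id,
                      output_glob) {
  inputs <- stats::setNames(lapply(seq_along(input_ids), function(i)
    list(type = "File", inputBinding = list(position = input_positions[[i]]))),
    input_ids)
  list(cwlVersion = "v1.0",
       class = "CommandLineTool",
       baseCommand = list("sh", script),
       inputs = inputs,
       outputs = stats::setNames(
         list(list(type = "File", outputBinding = list(glob = output_glob))),
         output_id))
}

#' Generate the five-step ChIP-Seq-shaped demonstration pipeline
#'
#' Emits a CWL workflow whose topology mirrors a basic ChIP-Seq analysis —
#' alignment producing unsorted records, coordinate sort, index, peak
#' calling, and fragment-coverage reporting — with every tool replaced by a
#' deterministic stub text transform (awk/sort one-liners), a seeded
#' pseudo-reads input, and a matching job file carrying the three mandatory
#' fields. Wiring: align to sort; sort to index, peak calling and coverage;
#' peak calling to coverage.
#'
#' @param outdir directory to generate into (created)
#' @param seed integer seed fully determining the generated bytes
#' @return a `fixture_manifest` (step ids, intended edges, file paths)
#' @export
make_chipseq_like <- function(outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outdir <- normalizePath(outdir)
  bin <- file.path(outdir, "bin")
  tools_dir <- file.path(outdir, "tools")

  # stub transforms standing in for aligner / sorter / indexer / peak
  # caller / coverage: line-oriented, deterministic, sub-second
  write_stub(file.path(bin, "align.sh"), c(
    'awk \'{ s=0; for (i=1; i<=length($2); i++) s=(s*31+index("ACGT", substr($2,i,1))) % 10007;',
    '       print $1, s, $2 }\' "$1" > aligned.sam.txt'))
  write_stub(file.path(bin, "sortrec.sh"),
    'LC_ALL=C sort -k2,2n -k1,1 "$1" > sorted.bam.txt')
  write_stub(file.path(bin, "indexrec.sh"), c(
    'awk \'{ bin=int($2/1000); c[bin]++ } END { for (b in c) print b*1000, c[b] }\' "$1" \\',
    '  | LC_ALL=C sort -n > index.bai.txt'))
  write_stub(file.path(bin, "callpeak.sh"), c(
    'awk \'{ bin=int($2/500); c[bin]++ } END { for (b in c) if (c[b] >= 50) print b*500, (b+1)*500, c[b] }\' "$1" \\',
    '  | LC_ALL=C sort -n > peaks.txt'))
  write_stub(file.path(bin, "coverage.sh"), c(
    'awk \'NR==FNR { start[++n]=$1; end[n]=$2; next }',
    '     { for (i=1; i<=n; i++) if ($2 >= start[i] && $2 < end[i]) c[i]++ }',
    '     END { for (i=1; i<=n; i++) print start[i], end[i], c[i]+0 }\' "$2" "$1" > coverage.bw.txt'))

  write_cwl_yaml(stub_tool(file.path(bin, "align.sh"), "reads", 1L,
                           "sam", "aligned.sam.txt"),
                 file.path(tools_dir, "align.cwl"))
  write_cwl_yaml(stub_tool(file.path(bin, "sortrec.sh"), "sam", 1L,
                           "bam", "sorted.bam.txt"),
                 file.path(tools_dir, "sortrec.cwl"))
  write_cwl_yaml(stub_tool(file.path(bin, "indexrec.sh"), "bam", 1L,
                           "bai", "index.bai.txt"),
                 file.path(tools_dir, "indexrec.cwl"))
  write_cwl_yaml(stub_tool(file.path(bin, "callpeak.sh"), "bam", 1L,
                           "peaks", "peaks.txt"),
                 file.path(tools_dir, "callpeak.cwl"))
  write_cwl_yaml(stub_tool(file.path(bin, "coverage.sh"),
                           c("bam", "peaks"), c(1L, 2L),
                           "bigwig", "coverage.bw.txt"),
                 file.path(tools_dir, "coverage.cwl"))

  wf <- list(
    cwlVersion = "v1.0",
    class = "Workflow",
    inputs = list(reads = list(type = "File")),
    outputs = list(
      bam = list(type = "File", outputSource = "sortrec/bam"),
      bai = list(type = "File", outputSource = "indexrec/bai"),
      peaks = list(type = "File", outputSource = "callpeak/peaks"),
      bigwig = list(type = "File", outputSource = "coverage/bigwig")),
    steps = list(
      align = list(run = "tools/align.cwl",
                   `in` = list(reads = "reads"), out = list("sam")),
      sortrec = list(run = "tools/sortrec.cwl",
                     `in` = list(sam = "align/sam"), out = list("bam")),
      indexrec = list(run = "tools/indexrec.cwl",
                      `in` = list(bam = "sortrec/bam"), out = list("bai")),
      callpeak = list(run = "tools/callpeak.cwl",
                      `in` = list(bam = "sortrec/bam"), out = list("peaks")),
      coverage = list(run = "tools/coverage.cwl",
                      `in` = list(bam = "sortrec/bam",
                                  peaks = "callpeak/peaks"),
                      out = list("bigwig"))))
  wf_path <- write_cwl_yaml(wf, file.path(outdir, "workflow.cwl"))

  make_pseudo_reads(file.path(outdir, "data", "reads.txt"), seed)
  job <- list(workflow = wf_path,
              output_folder = file.path(outdir, "output"),
              uid = sprintf("chipseq-seed%d", seed),
              reads = list(class = "File",
                           path = file.path(outdir, "data", "reads.txt")))
  job_path <- file.path(outdir, "job.yml")
  yaml::write_yaml(job, job_path)

  fixture_manifest(
    name = "chipseq-like",
    step_ids = c("align", "sortrec", "indexrec", "callpeak", "coverage"),
    intended_edges = list(c("align", "sortrec"),
                          c("sortrec", "indexrec"),
                          c("sortrec", "callpeak"),
                          c("sortrec", "coverage"),
                          c("callpeak", "coverage")),
    expected_output_ids = c("bam", "bai", "peaks", "bigwig"),
    seed = seed, dir = outdir, workflow = wf_path, job = job_path)
}

# shared stub tools for the topology suite: copy one file / merge 2 or 3
topology_tools <- function(outdir) {
  bin <- file.path(outdir, "bin")
  write_stub(file.path(bin, "copy.sh"), 'cat "$1" > out.txt')
  write_stub(file.path(bin, "merge2.sh"), 'cat "$1" "$2" > out.txt')
  write_stub(file.path(bin, "merge3.sh"), 'cat "$1" "$2" "$3" > out.txt')
  tools_dir <- file.path(outdir, "tools")
  write_cwl_yaml(stub_tool(file.path(bin, "copy.sh"), "f", 1L, "out", "out.txt"),
                 file.path(tools_dir, "copy.cwl"))
  write_cwl_yaml(stub_tool(file.path(bin, "merge2.sh"), c("f1", "f2"),
                           c(1L, 2L), "out", "out.txt"),
                 file.path(tools_dir, "merge2.cwl"))
  write_cwl_yaml(stub_tool(file.path(bin, "merge3.sh"), c("f1", "f2", "f3"),
                           c(1L, 2L, 3L), "out", "out.txt"),
                 file.path(tools_dir, "merge3.cwl"))
  tools_dir
}

#' Generate the topology-stress workflow suite
#'
#' Seven fixtures exercising graph construction: single-step, linear-3,
#' diamond-4, fan-out/fan-in, isolated-step, cyclic-invalid and
#' dangling-source-invalid. Valid fixtures come with a job file; the two
#' invalid ones exist to be rejected (cycle detection, dangling source).
#'
#' @param outdir directory to generate into
#' @return list of `fixture_manifest`, one per fixture
#' @export
make_topology_suite <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outdir <- normalizePath(outdir)
  tools_dir <- topology_tools(outdir)
  seed_file <- write_lines("topology seed data", file.path(outdir, "data", "seed.txt"))
  rel_tools <- function(wf_dir) {
    # workflows live in subdirectories; run refs are relative to them
    file.path("..", "tools")
  }

  emit <- function(name, steps, outputs, intended_edges, valid = TRUE,
                   extra_inputs = NULL) {
    dir <- file.path(outdir, name)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    wf <- list(cwlVersion = "v1.0", class = "Workflow",
               inputs = c(list(f = list(type = "File")), extra_inputs),
               outputs = outputs, steps = steps)
    wf_path <- write_cwl_yaml(wf, file.path(dir, "workflow.cwl"))
    job_path <- NULL
    if (valid) {
      job <- list(workflow = wf_path,
                  output_folder = file.path(dir, "output"),
                  uid = paste0(name, "-run"),
                  f = list(class = "File", path = seed_file))
      job_path <- file.path(dir, "job.yml")
      yaml::write_yaml(job, job_path)
    }
    fixture_manifest(name = name,
                     step_ids = names(steps),
                     intended_edges = intended_edges,
                     expected_output_ids = names(outputs),
                     seed = 0L, dir = dir, workflow = wf_path,
                     job = job_path, valid = valid)
  }
  copy_step <- function(src) list(run = "../tools/copy.cwl",
                                  `in` = list(f = src), out = list("out"))

  fixtures <- list(
    emit("single-step",
         steps = list(A = copy_step("f")),
         outputs = list(result = list(type = "File", outputSource = "A/out")),
         intended_edges = list()),
    emit("linear-3",
         steps = list(A = copy_step("f"),
                      B = copy_step("A/out"),
                      C = copy_step("B/out")),
         outputs = list(result = list(type = "File", outputSource = "C/out")),
         intended_edges = list(c("A", "B"), c("B", "C"))),
    emit("diamond-4",
         steps = list(A = copy_step("f"),
                      B = copy_step("A/out"),
                      C = copy_step("A/out"),
                      D = list(run = "../tools/merge2.cwl",
                               `in` = list(f1 = "B/out", f2 = "C/out"),
                               out = list("out"))),
         outputs = list(result = list(type = "File", outputSource = "D/out")),
         intended_edges = list(c("A", "B"), c("A", "C"),
                               c("B", "D"), c("C", "D"))),
    emit("fanout-fanin",
         steps = list(A = copy_step("f"),
                      B = copy_step("A/out"),
                      C = copy_step("A/out"),
                      D = copy_step("A/out"),
                      E = list(run = "../tools/merge3.cwl",
                               `in` = list(f1 = "B/out", f2 = "C/out",
                                           f3 = "D/out"),
                               out = list("out"))),
         outputs = list(result = list(type = "File", outputSource = "E/out")),
         intended_edges = list(c("A", "B"), c("A", "C"), c("A", "D"),
                               c("B", "E"), c("C", "E"), c("D", "E"))),
    emit("isolated-step",
         steps = list(A = copy_step("f"),
                      Z = copy_step("f")),      # side branch: feeds nothing
         outputs = list(result = list(type = "File", outputSource = "A/out")),
         intended_edges = list()),
    emit("cyclic-invalid",
         steps = list(A = list(run = "../tools/copy.cwl",
                               `in` = list(f = "B/out"), out = list("out")),
                      B = list(run = "../tools/copy.cwl",
                               `in` = list(f = "A/out"), out = list("out"))),
         outputs = list(result = list(type = "File", outputSource = "A/out")),
         intended_edges = list(), valid = FALSE),
    emit("dangling-source-invalid",
         steps = list(A = list(run = "../tools/copy.cwl",
                               `in` = list(f = "stepX/missing"),
                               out = list("out"))),
         outputs = list(result = list(type = "File", outputSource = "A/out")),
         intended_edges = list(), valid = FALSE))
  fixtures
}

# --- binding conformance suite ---------------------------------------------

binding_case_defs <- function() {
  list(
    list(name = "positions",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "echo",
                     arguments = list("-q"),
                     inputs = list(
                       a = list(type = "string", inputBinding = list(position = 3L)),
                       b = list(type = "string", inputBinding = list(position = 1L)),
                       c = list(type = "string", inputBinding = list(position = 2L))),
                     outputs = list()),
         values = list(a = "A", b = "B", c = "C")),
    list(name = "position-ties",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "echo",
                     inputs = list(
                       zeta = list(type = "string", inputBinding = list(position = 1L)),
                       alpha = list(type = "string", inputBinding = list(position = 1L)),
                       mid = list(type = "string", inputBinding = list(position = 1L))),
                     outputs = list()),
         values = list(zeta = "Z", alpha = "A", mid = "M")),
    list(name = "prefix-separate",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "echo",
                     inputs = list(
                       threads = list(type = "int",
                                      inputBinding = list(position = 1L,
                                                          prefix = "-t"))),
                     outputs = list()),
         values = list(threads = 4L)),
    list(name = "prefix-joined",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "echo",
                     inputs = list(
                       level = list(type = "string",
                                    inputBinding = list(position = 1L,
                                                        prefix = "--level=",
                                                        separate = FALSE))),
                     outputs = list()),
         values = list(level = "high")),
    list(name = "array-plain",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "echo",
                     inputs = list(
                       items = list(type = "string[]",
                                    inputBinding = list(position = 1L,
                                                        prefix = "-i"))),
                     outputs = list()),
         values = list(items = list("a", "b", "c"))),
    list(name = "array-itemsep",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "echo",
                     inputs = list(
                       ids = list(type = "string[]",
                                  inputBinding = list(position = 1L,
                                                      prefix = "-i",
                                                      itemSeparator = ","))),
                     outputs = list()),
         values = list(ids = list("a", "b", "c"))),
    list(name = "bool-true",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "echo",
                     inputs = list(
                       verbose = list(type = "boolean",
                                      inputBinding = list(position = 1L,
                                                          prefix = "--verbose"))),
                     outputs = list()),
         values = list(verbose = TRUE)),
    list(name = "bool-false",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "echo",
                     inputs = list(
                       verbose = list(type = "boolean",
                                      inputBinding = list(position = 1L,
                                                          prefix = "--verbose")),
                       anchor = list(type = "string",
                                     inputBinding = list(position = 2L))),
                     outputs = list()),
         values = list(verbose = FALSE, anchor = "x")),
    list(name = "optional-omitted",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "echo",
                     inputs = list(
                       opt = list(type = "string?",
                                  inputBinding = list(position = 1L,
                                                      prefix = "-o")),
                       anchor = list(type = "string",
                                     inputBinding = list(position = 2L))),
                     outputs = list()),
         values = list(anchor = "x")),
    list(name = "stdio-redirect",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = list("wc", "-c"),
                     stdin = "$(inputs.src.path)",
                     stdout = "counted.txt",
                     inputs = list(src = list(type = "File")),
                     outputs = list(counted = list(type = "stdout"))),
         values = list(src = "__DATA__")),
    list(name = "valuefrom-interp",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "echo",
                     inputs = list(
                       sample = list(type = "string",
                                     inputBinding = list(
                                       position = 1L,
                                       valueFrom = "out_$(inputs.sample).txt"))),
                     outputs = list()),
         values = list(sample = "s1")),
    list(name = "file-path",
         tool = list(cwlVersion = "v1.0", class = "CommandLineTool",
                     baseCommand = "cat",
                     inputs = list(
                       infile = list(type = "File",
                                     inputBinding = list(position = 1L))),
                     outputs = list()),
         values = list(infile = "__DATA__")))
}

#' Generate the command-line-binding conformance suite
#'
#' Twelve CommandLineTool cases covering positions, position ties, prefixes
#' with separate true/false, arrays with and without itemSeparator,
#' booleans, optional-null omission, stdin/stdout redirection, valueFrom
#' interpolation, and File path substitution. Each case directory holds the
#' tool, its input values, and the expected argv committed with the package
#' (`expected_argv.json`; File-path tokens appear as
#' `"__FILE__:<basename>"` placeholders, compared by basename). The engine
#' never depends on an external executor at run time.
#'
#' @param outdir directory to generate into
#' @return list of case descriptors (name, tool path, values path, expected
#'   argv or NULL when no expectation is committed for a case)
#' @export
make_binding_suite <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outdir <- normalizePath(outdir)
  expected_root <- system.file("extdata", "binding_expected", package = "cwldag")
  lapply(binding_case_defs(), function(def) {
    dir <- file.path(outdir, def$name)
    dir.create(dir, showWarnings = FALSE)
    data_path <- write_lines("binding fixture data",
                             file.path(dir, "reads.dat"))
    values <- lapply(def$values, function(v)
      if (identical(v, "__DATA__")) list(class = "File", path = data_path) else v)
    tool_path <- write_cwl_yaml(def$tool, file.path(dir, "tool.cwl"))
    values_path <- file.path(dir, "values.yml")
    yaml::write_yaml(values, values_path)
    expected <- NULL
    exp_src <- file.path(expected_root, paste0(def$name, ".json"))
    if (nzchar(expected_root) && file.exists(exp_src)) {
      file.copy(exp_src, file.path(dir, "expected_argv.json"), overwrite = TRUE)
      expected <- as.character(unlist(read_json_file(exp_src)$argv))
    }
    list(name = def$name, dir = dir, tool = tool_path, values = values_path,
         data_file = data_path, expected_argv = expected)
  })
}

# normalize an argv for comparison against committed expectations: any token
# that is the path of one of the case's File inputs becomes
# "__FILE__:<basename>"
normalize_argv <- function(argv, file_paths) {
  vapply(argv, function(tok) {
    hit <- vapply(file_paths, function(p)
      identical(tok, p) || identical(basename(tok), basename(p)) &&
        grepl("/", tok, fixed = TRUE) && file.exists(tok), logical(1))
    if (length(hit) > 0L && any(hit))
      paste0("__FILE__:", basename(tok)) else tok
  }, character(1), USE.NAMES = FALSE)
}
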