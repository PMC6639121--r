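# Brute-force oracles, independent of the engine's graph code, plus small
# builders for ad-hoc workflows used across the tests.

# quadratic dependency scan straight off the parsed workflow: an edge (A, B)
# exists iff some input of B sources an output of A
oracle_step_edges <- function(doc) {
  wf <- doc$body
  ids <- names(wf$steps)
  edges <- list()
  for (a in ids) for (b in ids) {
    if (a == b) next
    hits <- vapply(wf$steps[[b]]$in_bindings, function(x)
      !is.null(x$source) && grepl("/", x$source) &&
        strsplit(x$source, "/", fixed = TRUE)[[1]][[1]] == a, logical(1))
    if (any(hits)) edges[[length(edges) + 1L]] <- c(a, b)
  }
  edges
}

edge_set_key <- function(edges) {
  sort(vapply(edges, function(e) paste(e[[1]], e[[2]], sep = "->"), character(1)))
}

# transitive reachability by repeated expansion over an edge list
oracle_descendants <- function(edges, node) {
  children <- function(x) unique(vapply(
    Filter(function(e) e[[1]] == x, edges), `[[`, character(1), 2L))
  seen <- character()
  frontier <- children(node)
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, children))), seen)
  }
  sort(seen)
}

# enumerate every linear extension of a small DAG (recursive; fine to ~8 nodes)
oracle_linear_extensions <- function(nodes, edges) {
  parents_of <- function(x) unique(vapply(
    Filter(function(e) e[[2]] == x, edges), `[[`, character(1), 1L))
  recurse <- function(placed, remaining) {
    if (length(remaining) == 0L) return(list(placed))
    ready <- Filter(function(x) all(parents_of(x) %in% placed), remaining)
    out <- list()
    for (x in ready)
      out <- c(out, recurse(c(placed, x), setdiff(remaining, x)))
    out
  }
  recurse(character(), nodes)
}

# brute-force layer oracle: longest path from a source, per node
oracle_layers <- function(nodes, edges) {
  parents_of <- function(x) unique(vapply(
    Filter(function(e) e[[2]] == x, edges), `[[`, character(1), 1L))
  depth <- function(x) {
    ps <- parents_of(x)
    if (length(ps) == 0L) return(0L)
    max(vapply(ps, depth, integer(1))) + 1L
  }
  d <- vapply(nodes, depth, integer(1))
  lapply(sort(unique(d)), function(l) sort(nodes[d == l]))
}

# --- builders ---------------------------------------------------------------

fresh_dir <- function() {
  d <- tempfile("cwldag-test-")
  dir.create(d, recursive = TRUE)
  d
}

test_config <- function(d, ...) {
  engine_config(store_path = file.path(d, "store"),
                temp_folder = file.path(d, "temp"),
                jobs_folder = file.path(d, "jobs"),
                output_default = file.path(d, "outdef"),
                ...)
}

# write a one-File-in/one-File-out stub tool whose script body is given
write_script_tool <- function(dir, name, body) {
  script <- file.path(dir, paste0(name, ".sh"))
  writeLines(c("#!/bin/sh", body), script)
  Sys.chmod(script, "0755")
  tool <- list(cwlVersion = "v1.0", class = "CommandLineTool",
               baseCommand = list("sh", script),
               inputs = list(f = list(type = "File",
                                      inputBinding = list(position = 1L))),
               outputs = list(out = list(type = "File",
                                         outputBinding = list(glob = "out.txt"))))
  yaml::write_yaml(tool, file.path(dir, paste0(name, ".cwl")))
  file.path(dir, paste0(name, ".cwl"))
}

# diamond A -> {B, C} -> D where B's behavior is controlled by its script
write_diamond <- function(d, b_body = 'cat "$1" > out.txt') {
  write_script_tool(d, "copy", 'cat "$1" > out.txt')
  write_script_tool(d, "bstep", b_body)
  merge <- file.path(d, "merge.sh")
  writeLines(c("#!/bin/sh", 'cat "$1" "$2" > out.txt'), merge)
  tool <- list(cwlVersion = "v1.0", class = "CommandLineTool",
               baseCommand = list("sh", merge),
               inputs = list(f1 = list(type = "File",
                                       inputBinding = list(position = 1L)),
                             f2 = list(type = "File",
                                       inputBinding = list(position = 2L))),
               outputs = list(out = list(type = "File",
                                         outputBinding = list(glob = "out.txt"))))
  yaml::write_yaml(tool, file.path(d, "merge.cwl"))
  wf <- list(cwlVersion = "v1.0", class = "Workflow",
             inputs = list(f = list(type = "File")),
             outputs = list(result = list(type = "File",
                                          outputSource = "D/out")),
             steps = list(
               A = list(run = "copy.cwl", `in` = list(f = "f"),
                        out = list("out")),
               B = list(run = "bstep.cwl", `in` = list(f = "A/out"),
                        out = list("out")),
               C = list(run = "copy.cwl", `in` = list(f = "A/out"),
                        out = list("out")),
               D = list(run = "merge.cwl",
                        `in` = list(f1 = "B/out", f2 = "C/out"),
                        out = list("out"))))
  yaml::write_yaml(wf, file.path(d, "wf.cwl"))
  writeLines("diamond input data", file.path(d, "in.txt"))
  file.path(d, "wf.cwl")
}

write_job <- function(d, wf_path, uid, out_folder,
                      inputs = list(f = list(class = "File",
                                             path = file.path(d, "in.txt"))),
                      file = file.path(d, paste0(uid, ".yml"))) {
  yaml::write_yaml(c(list(workflow = wf_path, output_folder = out_folder,
                          uid = uid), inputs), file)
  file
}

run_task_order <- function(run) {
  starts <- vapply(run$tasks, function(t) t$started_at %||% Inf, numeric(1))
  names(sort(starts))
}

delivered_checksums <- function(folder) {
  files <- setdiff(list.files(folder), "manifest.json")
  stats::setNames(vapply(file.path(folder, sort(files)), cwldag::file_checksum,
                         character(1)), sort(files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
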