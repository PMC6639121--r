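# Translation of a validated workflow + job into the executable task graph:
# one node per workflow step plus the two synthetic endpoints, JobDispatcher
# (serializes and provisions the job's inputs) and JobCleanup (delivers the
# declared outputs to the run's output folder). Edges between step nodes are
# exactly the dataflow dependencies: an edge (A, B) exists iff some input of
# B sources an output of A.

DISPATCHER_ID <- "JobDispatcher"
CLEANUP_ID <- "JobCleanup"

#' Build the executable task graph for one run
#'
#' @param doc a `cwl_document` of class_kind Workflow that passed
#'   [validate_connectivity()]
#' @param job the `job_descriptor` for this run
#' @return a `dag_graph`: run_uid, nodes (named list of task nodes with
#'   kind/upstream/downstream), edges (list of c(from, to) pairs)
#' @export
build_dag <- function(doc, job) {
  stopifnot(inherits(doc, "cwl_document"), doc$class_kind == "Workflow")
  wf <- doc$body
  step_ids <- names(wf$steps)
  clash <- intersect(step_ids, c(DISPATCHER_ID, CLEANUP_ID))
  if (length(clash) > 0L)
    cwl_abort("invalid_document",
              sprintf("step id '%s' collides with a reserved task id", clash[[1]]))

  # dataflow edges between steps
  edges <- list()
  for (b_id in step_ids) {
    step <- wf$steps[[b_id]]
    sources <- vapply(step$in_bindings, function(x) x$source %||% "", character(1))
    parents <- unique(vapply(
      sources[grepl("/", sources)],
      function(s) strsplit(s, "/", fixed = TRUE)[[1]][[1]], character(1)))
    for (a_id in sort(intersect(parents, step_ids)))
      edges[[length(edges) + 1L]] <- c(a_id, b_id)      # parallel data edges collapse
  }
  step_parents <- function(sid)
    unique(vapply(Filter(function(e) e[[2]] == sid, edges), `[[`, character(1), 1L))
  step_children <- function(sid)
    unique(vapply(Filter(function(e) e[[1]] == sid, edges), `[[`, character(1), 1L))

  # dispatcher feeds every step with no step parents (consumes only workflow
  # inputs/constants); cleanup collects every sink and every step feeding a
  # workflow output, so no work is orphaned
  producers <- unique(vapply(wf$outputs, function(op) {
    if (grepl("/", op$output_source))
      strsplit(op$output_source, "/", fixed = TRUE)[[1]][[1]] else ""
  }, character(1)))
  producers <- setdiff(producers, "")
  for (sid in step_ids) {
    if (length(step_parents(sid)) == 0L)
      edges[[length(edges) + 1L]] <- c(DISPATCHER_ID, sid)
    if (length(step_children(sid)) == 0L || sid %in% producers)
      edges[[length(edges) + 1L]] <- c(sid, CLEANUP_ID)
  }
  edges <- unique(edges)

  all_ids <- c(DISPATCHER_ID, step_ids, CLEANUP_ID)
  nodes <- stats::setNames(lapply(all_ids, function(tid) {
    kind <- if (tid == DISPATCHER_ID) "dispatcher"
    else if (tid == CLEANUP_ID) "cleanup" else "step"
    up <- sort(unique(vapply(Filter(function(e) e[[2]] == tid, edges),
                             `[[`, character(1), 1L)))
    down <- sort(unique(vapply(Filter(function(e) e[[1]] == tid, edges),
                               `[[`, character(1), 2L)))
    list(task_id = tid, kind = kind, upstream = up, downstream = down)
  }), all_ids)

  dag <- structure(list(run_uid = job$uid, nodes = nodes, edges = edges),
                   class = "dag_graph")
  topological_layers(dag)    # raises CycleDetected on a cyclic workflow
  dag
}

#' @export
print.dag_graph <- function(x, ...) {
  cat(sprintf("<dag_graph> run '%s': %d tasks, %d edges\n",
              x$run_uid, length(x$nodes), length(x$edges)))
  for (layer in topological_layers(x))
    cat("  ", paste(layer, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# step-to-step edges only (the dataflow core of the graph)
step_edges <- function(dag) {
  Filter(function(e) dag$nodes[[e[[1]]]]$kind == "step" &&
           dag$nodes[[e[[2]]]]$kind == "step", dag$edges)
}

#' Kahn layers of a task graph
#'
#' Layer 0 holds the dispatcher; every other node sits one layer above the
#' deepest of its parents. Raises a cycle error (listing the task ids stuck
#' on the cycle) when the graph is not acyclic.
#'
#' @param dag a `dag_graph`
#' @return list of character vectors, one per layer, each sorted
#' @export
topological_layers <- function(dag) {
  ids <- names(dag$nodes)
  indeg <- stats::setNames(vapply(dag$nodes, function(n) length(n$upstream),
                                  integer(1)), ids)
  topo_order <- character()
  frontier <- sort(ids[indeg == 0L])
  remaining <- indeg
  while (length(frontier) > 0L) {
    topo_order <- c(topo_order, frontier)
    next_frontier <- character()
    for (tid in frontier) {
      for (child in dag$nodes[[tid]]$downstream) {
        remaining[[child]] <- remaining[[child]] - 1L
        if (remaining[[child]] == 0L)
          next_frontier <- c(next_frontier, child)
      }
    }
    frontier <- sort(unique(next_frontier))
  }
  if (length(topo_order) < length(ids)) {
    stuck <- sort(setdiff(ids, topo_order))
    cwl_abort("cycle_detected",
              sprintf("cycle detected among task(s): %s",
                      paste(stuck, collapse = ", ")),
              tasks = stuck)
  }
  # a node sits one layer above the deepest of its parents (longest path
  # from a source), computed along the topological order
  layer_of <- stats::setNames(rep(0L, length(ids)), ids)
  for (tid in topo_order) {
    parents <- dag$nodes[[tid]]$upstream
    if (length(parents) > 0L)
      layer_of[[tid]] <- max(layer_of[parents]) + 1L
  }
  lapply(sort(unique(layer_of)), function(l) sort(names(layer_of)[layer_of == l]))
}

#' Export a task graph as Graphviz DOT
#'
#' Deterministic: node and edge statements are emitted in lexicographic
#' order, so the same graph always serializes to byte-identical text.
#'
#' @param dag a `dag_graph`
#' @return DOT source as a single character scalar
#' @export
export_dot <- function(dag) {
  shape <- c(dispatcher = "invhouse", step = "box", cleanup = "house")
  node_lines <- sort(vapply(dag$nodes, function(n)
    sprintf("  \"%s\" [shape=%s];", n$task_id, shape[[n$kind]]), character(1)))
  edge_lines <- sort(vapply(dag$edges, function(e)
    sprintf("  \"%s\" -> \"%s\";", e[[1]], e[[2]]), character(1)))
  paste(c(sprintf("digraph \"%s\" {", dag$run_uid), node_lines, edge_lines, "}"),
        collapse = "\n")
}

# serializable form for persistence / `status --graph`
dag_to_list <- function(dag) {
  list(run_uid = dag$run_uid,
       nodes = lapply(unname(dag$nodes), function(n)
         list(task_id = n$task_id, kind = n$kind,
              upstream = as.list(n$upstream), downstream = as.list(n$downstream))),
       edges = lapply(dag$edges, as.list))
}

dag_from_list <- function(x) {
  nodes <- stats::setNames(lapply(x$nodes, function(n)
    list(task_id = n$task_id, kind = n$kind,
         upstream = as.character(unlist(n$upstream)),
         downstream = as.character(unlist(n$downstream)))),
    vapply(x$nodes, `[[`, character(1), "task_id"))
  edges <- lapply(x$edges, function(e) c(e[[1]], e[[2]]))
  structure(list(run_uid = x$run_uid, nodes = nodes, edges = edges),
            class = "dag_graph")
}

# transitive descendants of a task (used by failure propagation and
# cascading restart)
dag_descendants <- function(dag, task_id) {
  seen <- character()
  frontier <- dag$nodes[[task_id]]$downstream
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(frontier, function(t) dag$nodes[[t]]$downstream))),
      seen)
  }
  sort(seen)
}
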