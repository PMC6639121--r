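---
title: "cwldag: dataflow-to-DAG execution of CWL v1.0 pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cwldag: dataflow-to-DAG execution of CWL v1.0 pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwldag)
```

## The model

cwldag executes pipelines written in a subset of the Common Workflow
Language v1.0. The central translation is from *dataflow* to *precedence*:
a CWL workflow declares which step inputs source which step outputs, and the
engine derives from that a directed acyclic task graph. An edge (A, B)
exists exactly when some input of B references `A/<output>`; multiple
parallel data links between the same step pair collapse into a single
scheduling edge, because scheduling cares about precedence, not
multiplicity.

Two synthetic endpoint tasks frame every run. `JobDispatcher` (always layer
0) validates the job against the workflow, resolves every File path to
absolute form, and persists the mapping, so that all later tasks read their
inputs from the run-state store and never from the job file again.
`JobCleanup` (always the final layer) moves the workflow-declared outputs —
and only those — into the run's output folder and writes a manifest. The
dispatcher feeds every step with no step parents; cleanup collects every
sink step and every step feeding a workflow output, so no work is orphaned
even in workflows with side branches. An isolated step (no connections to
any other step) is wired dispatcher → step → cleanup rather than rejected:
CWL permits side-effect-only diagnostic steps, and refusing them would be
gratuitous.

Graph identifiers are the step ids verbatim, with `JobDispatcher` and
`JobCleanup` reserved (a user step with either name is a load-time error).
This keeps log lines, CLI references, and restart targets human-readable
and stable across runs.

## The supported CWL subset, fail-closed

The parser consumes exactly the subset it implements and rejects everything
else by name: JavaScript expressions (`${...}`), `scatter`, nested
workflows as step run targets, schema-salad record/enum types, unions other
than `["null", T]`, and unknown requirement kinds all raise
unsupported-feature errors, and *any* unconsumed key in a document does the
same. The alternative — silently dropping keys — is how executors come to
disagree about what a workflow means. Within the subset, restricted
parameter references (`$(inputs.x)`, `$(inputs.x.path)`,
`$(inputs.x.basename)`, `$(runtime.outdir)`, `$(runtime.cores)`, `$(self)`)
are evaluated with native types for lone references and string
interpolation inside longer text.

JSON is attempted before YAML when reading both workflow and job files; the
file extension is advisory only, since files in the wild mix them. Loaded
documents serialize to a canonical, self-contained JSON form (step `run`
targets inlined, keys ordered) that reloads to a structurally equal
representation — the round-trip property the test suite checks.

Command-line binding follows the v1.0 rules: tokens sort by binding
position; boolean true contributes its prefix alone; arrays join into one
token under `itemSeparator` and otherwise emit the prefix once followed by
the elements; `separate: false` concatenates prefix and value. Position
ties are broken by parameter id, lexicographically; where arguments and
inputs share a position, arguments (ordered by declaration index) come
first. CWL leaves the cross-class tie implementation-defined, so the engine
fixes a deterministic order and documents it. Glob matches sort
lexicographically by basename for the same reason: the standard leaves the
order open, and determinism is what makes output identity testable. A
declared stdout capture without a `stdout` name gets the generated name
`step.stdout`.

Container requirements are honored *constructively* by default: the full
`docker run`/`singularity exec` invocation (bind-mounted working directory,
working-directory flag, image, then the bound argv) is built and recorded,
but the plain command is executed unless `container_mode` is set. Container
execution is an integration property of the host, not an algorithm; keeping
it construct-only lets the whole suite run where no container engine
exists, while the wrapping logic itself stays tested.

## Scheduling and state

Each task moves through pending → queued → running → success/failed, with
failed → queued on retry and pending → upstream_failed when an ancestor
exhausts its retry budget (default 0 retries). The attempt counter
increments exactly on queued → running. A task is ready when every parent
is in success; among simultaneously ready tasks the order is (queue
priority, task id), so traces are reproducible. The test suite checks
executed orders against the enumerated set of linear extensions of the
graph on the small fixtures.

The worker pool is N forked processes on one machine, fed from the
persisted queue — the single-machine reduction of a distributed
queue-worker cluster. Workers hand their results back through the
filesystem, not the fork's result pipe: each worker writes its step result
as JSON next to its working directory (write-temp-then-rename) and then
exits without running any interpreter shutdown, since a forked child shares
the engine's session state and a normal exit would tear it down. This
choice also makes the handoff crash-safe: if the engine is killed while a
worker runs, the worker's result is on disk for the resuming engine, and no
process is left waiting on a pipe nobody reads.

The run-state store is a directory of per-run JSON documents plus an
append-only transition log. Every transition is one atomic rename, so the
store is always a consistent snapshot of the last completed transition —
that is the whole crash-recovery story. Resume reloads the workflow,
refuses to proceed if its content digest changed since the graph was built,
resets tasks recorded as queued/running (an engine died mid-flight) to
pending, and re-enters the loop; completed work is never redone. Pause is
honored at scheduler ticks: running tasks finish, pending tasks hold. In a
single-process engine a pause request lands either from another process
(the persisted flag is re-read every tick) or deterministically through the
`on_task_complete` hook, which is also the observability surface the tests
use to pause after a named task.

Restarting a step resets it to pending, reusing upstream successes and
their persisted outputs verbatim; `cascade = TRUE` also resets all
transitive descendants, and descendants that never ran (upstream_failed)
are released in either mode. One practical limit follows from the delivery
design: after a successful delivery the run's temp directories are removed,
so restarting a mid-pipeline step of an already-delivered run requires
`keep_temp = TRUE` at execution time — otherwise the step's staged inputs
no longer exist. Restarting steps of a *failed* run (the common case) needs
nothing special, because temp is retained whenever delivery did not happen.

Delivery itself is atomic per file (copy to a temporary name inside the
target volume, then rename), writes a manifest with output id, basename,
size, and SHA-1 checksum, and removes the run's temp tree unless
`keep_temp`. On any step failure the output folder receives nothing.

## Job intake

The jobs folder is polled (default every 3 s) rather than watched through
OS file notification, trading latency for portability. A job file is never
mutated or consumed; registration is keyed by `uid`. A second file carrying
an already-registered uid is recorded as a rejected run — first writer
wins, and the collision is visible in the store. Malformed files are
rejected once per content hash: editing the file makes it eligible again.
Unknown job keys warn rather than fail, so job files survive workflow edits
in either direction. Relative `workflow`/`output_folder` paths are resolved
against the job file's directory; mandatory-field absence is an error
naming the field.

## What the generators emulate, and what they do not

`make_chipseq_like()` emits a five-step workflow whose *topology* mirrors a
basic ChIP-Seq analysis — alignment producing unsorted records, coordinate
sort, index, peak calling, fragment coverage — wired align → sort; sort →
index, peak calling, coverage; peak calling → coverage. The tools are stub
text transforms (awk/sort one-liners over line-oriented records), the input
is 1000 seeded pseudo-reads of length 36 over ACGT, and a matching job file
carries the three mandatory fields. The numbers (1000 reads, 36 bp, a
count-threshold peak stub) are chosen so every step does visible,
deterministic work in well under a second. Same `(outdir, seed)` reproduces
the tree byte for byte.

What passing on these fixtures shows is confined to the *engine*: graph
construction, binding, scheduling, delivery, and lifecycle semantics are
exercised on realistic topologies. It says nothing about biological
correctness, real aligner/peak-caller behavior, large-file staging
performance, or container execution — the stubs have none of those
properties, by design.

`make_topology_suite()` adds the graph stress cases (single step, linear
chain, diamond, fan-out/fan-in, isolated step, a cycle, a dangling source),
each self-checking against its manifest. `make_binding_suite()` emits
twelve CommandLineTool cases covering the binding rules; their expected
argv were computed once with an independent binding oracle implemented
directly from the v1.0 rules (in Python, sharing no code with the engine),
hand-checked, and committed as JSON. File-path tokens are stored as
`__FILE__:<basename>` placeholders and compared by basename, because
absolute staged paths differ across machines.

## Numerical and operational choices

* Timestamps are numeric epoch seconds; durations are end minus start per
  task. Checksums are SHA-1 in CWL's `sha1$<hex>` form.
* The scheduler's poll interval defaults to 0.05 s while tasks run; the
  jobs-folder watcher defaults to 3 s.
* Problem sizes in the tests and the acceptance script (fixtures of two to
  five steps, 1000-record inputs, worker counts 1–3, one
  kill-and-resume cycle per scenario) keep a full run of everything in the
  tens of seconds on a single CPU while still covering every contract; they
  are the package's chosen desk-scale study conditions, not limits of the
  engine.
* Degenerate inputs: empty workflows are rejected (a workflow must have
  steps); empty arrays bind to nothing; optional outputs with zero matches
  are simply absent; a step producing fewer outputs than its `out` list
  declares fails that task.

## Known limitations

Cross-machine distribution, web dashboards, and REST endpoints are out of
scope; observability is the CLI and the JSON store. Subworkflows are
rejected rather than flattened — the safe reading of an underspecified
case. `successCodes`, `secondaryFiles`, `InitialWorkDirRequirement`, and
JavaScript expressions are outside the subset. Scalar-typed step outputs
(content inference from files) are not supported; outputs are File,
array-of-File, or captured stdout.
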