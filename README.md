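# cwldag

A lightweight, self-contained execution engine for pipelines written in a
defined subset of the Common Workflow Language (CWL) v1.0, implemented as an
R package. It is aimed at bioinformatics groups who describe their analyses
as CWL `CommandLineTool` and `Workflow` documents and want a small,
inspectable runner with the operational comforts of a full pipeline manager:
batch intake from a watched jobs folder, pause/resume, restart of individual
steps, run history, and crash recovery — without a database server, message
broker, or web stack.

## How it works

A *job file* (YAML or JSON) requests one run. It carries three mandatory
fields — `workflow` (path to the CWL descriptor), `output_folder` (where
results are delivered), and `uid` (the unique run identifier) — plus the
workflow's concrete input values (`{class: File, path: ...}` for files).

The engine translates the workflow's dataflow into a directed acyclic task
graph: one node per step, plus two synthetic endpoints. `JobDispatcher`
validates and serializes the job's inputs so every later step reads from the
persisted store rather than the job file; `JobCleanup` moves the
workflow-declared outputs (and only those) atomically into the output folder
with a JSON manifest. An edge (A, B) exists exactly when some input of step
B sources an output of step A. A scheduler drives the graph with a pool of N
forked workers: a task starts only when all of its parents succeeded, every
state transition is one atomic write to the run-state store, and each step
runs in its own working directory under the temp folder with inputs staged
by symlink.

Command lines are bound per the CWL v1.0 rules (positions, prefixes,
`separate`, `itemSeparator`, booleans, optional omission, `valueFrom` with
restricted `$(...)` parameter references), outputs are collected by glob or
stdout capture, and a `DockerRequirement` is honored by constructing the
wrapped `docker run`/`singularity exec` invocation. JavaScript expressions,
`scatter`, and nested workflows are outside the supported subset and are
rejected at load time with an error naming the feature.

## Worked example

```r
library(cwldag)

dir <- tempfile(); dir.create(dir)
fx <- make_chipseq_like(dir, seed = 7)       # workflow + tools + reads + job file
cfg <- engine_config(store_path = file.path(dir, "store"),
                     temp_folder = file.path(dir, "temp"),
                     worker_count = 2)
run <- run_job(fx$job, config = cfg)
run$status
#> [1] "success"
sort(list.files(file.path(dir, "output")))
#> [1] "coverage.bw.txt" "index.bai.txt"   "manifest.json"   "peaks.txt"
#> [5] "sorted.bam.txt"
```

The four delivered files are the workflow's declared outputs — the sorted
record list, the index summary, the called peak intervals, and the per-peak
coverage table produced by the stub transforms — and `manifest.json` records
each one's output id, basename, size, and SHA-1 checksum. Re-running with
`worker_count = 1` or `3` delivers byte-identical files.

The same engine is scriptable from a shell via the installed
`exec/cwldag` launcher (`run`, `watch`, `validate`, `status`, `history`,
`logs`, `pause`, `resume`, `restart`, `fixtures` subcommands), with the exit
code contract 0 = run success, 1 = run failure, 2 = validation error.

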