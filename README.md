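# specflow

Speculative execution of *uncertain* tasks in a sequential task flow (STF)
runtime, with the performance theory of speculation chains and a Metropolis
/ replica exchange Monte Carlo particle simulator that exercises the
mechanism end to end.

## The problem

In the STF model, tasks are inserted by one thread declaring per-datum
access modes (`READ`/`WRITE`); the runtime derives the dependency DAG and
guarantees the parallel result equals the sequential one. Metropolis Monte
Carlo breaks this: every proposed move *may* write a particle domain and
the energy matrix, so every move task must declare `WRITE` and the whole
simulation serializes — even though many moves are rejected and write
nothing.

`specflow` adds the `MAYBE_WRITE` access mode. A task using it is
*uncertain*: its body reports a did-write flag on completion. Around each
uncertain task the runtime automatically builds

* **copy** tasks duplicating the maybe-written data,
* a **speculative twin** of the successor running early on the duplicates,
* **select** tasks that, when enabled, overwrite the original datum with
  the duplicate (`x = x'`).

If the uncertain task did not write, the twin's result is merged in via the
selects and the original successor is disabled; if it wrote, the twin is
cancelled (best-effort) and the original path runs. Linked *speculative
task groups* propagate outcomes along chains: one write anywhere disables
every downstream speculative path (predictive speculation — no restart).
Final payloads are bitwise those of the sequential execution, always.

For a chain of `N` consecutive uncertain tasks of cost `t` followed by a
certain one (write probabilities `P_i`, `P_{N+1} = 1`), the expected saved
duration and speedup are

    D_N = sum_{i=1..N} t * i * P_{i+1} * prod_{j<=i} (1 - P_j)
    S   = (N+1) t / ((N+1) t - D_N)

with the eager variant `F(N) = t * sum_i (1 - P_i)` provided as theory.

## Worked example

```r
library(specflow)

rt <- stf_runtime("simulated", workers = 2)
demo <- demo_uncertain_chain(rt, b_writes = FALSE)  # A, B?, C, D on one datum
wait_all(rt)
makespan(rt)
#> [1] 1
data_value(demo$x)
#> [1] 3
run_trace(rt)$records[, c("id","name","role","activation","worker","start","end")]
#>   id      name   role activation worker start end
#> 1  1         A   task    ENABLED      1     0   0
#> 2  2   copy(x)   copy    ENABLED      1     0   0
#> 3  3         B   task    ENABLED      1     0   1
#> 4  4         C   task   DISABLED      1     1   1
#> 5  5        C'   task    ENABLED      2     0   1
#> 6  6 select(x) select    ENABLED      1     1   1
#> 7  7         D   task    ENABLED      1     1   1
```

The four user tasks became seven: `B` (uncertain) and the twin `C'` ran
concurrently; since `B` did not write, `C` was disabled and the select
merged `C'`'s output, so the final value 3 (= `1 * 2 + 1`) equals the
sequential result with `B` a no-op — in one time unit instead of two.

The expected-speedup table (unit cost, uniform write probability per row):

```r
theory_table(n_max = 4)
#>   quantity    p    N1     N2     N3     N4
#> 1        D 0.25 0.750 1.3125 1.7344 2.0508
#> 2        S 0.25 1.600 1.7778 1.7655 1.6954
#> 3        D 0.50 0.500 0.7500 0.8750 0.9375
#> 4        S 0.50 1.333 1.3333 1.2800 1.2308
#> 5        D 0.75 0.250 0.3125 0.3281 0.3320
#> 6        S 0.75 1.143 1.1163 1.0894 1.0711
```

`D` is the expected saved duration (in task costs), `S` the speedup; e.g.
a 3-chain at `p = 1/2` saves 0.875 of a task and runs 1.28x faster.

The Monte Carlo task flow is bitwise identical to its sequential
reference, for any executor and worker count:

```r
cfg <- mc_config(num_domains = 2, particles_per_domain = 12,
                 temperature = 2, num_loops = 3, spec_depth = 2, seed = 7)
ref <- run_mc(cfg)                                        # Algorithm-style loop
tf  <- run_mc_taskflow(cfg, executor = "parallel", workers = 4)
identical(tf$domains, ref$domains)
#> [1] TRUE
ref$accept_ratio
#> [1] 0.3333333
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/specflow.R theory --n-max 7
Rscript inst/cli/specflow.R mc --domains 3 --particles 20 --loops 3 --verify
```

## Package layout

* `R/runtime.R`, `R/speculation.R`, `R/executor.R` — the STF runtime:
  access modes, dependency inference, copy/twin/select construction,
  group outcome propagation, three executors, DOT/JSON export.
* `R/theory.R` — predictive and eager speedup models plus the Monte Carlo
  gain estimator.
* `R/energy.R`, `R/mc.R`, `R/remc.R` — Lennard-Jones energies, the MC
  reference and task-flow builds, replica exchange.
* `R/io.R`, `R/cli.R`, `R/demo_graphs.R` — XYZ/config/CSV I/O, the CLI,
  canned demonstration graphs.
* `vignettes/speculative-task-flows.Rmd` — the model, its assumptions,
  parameter choices and limitations.
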