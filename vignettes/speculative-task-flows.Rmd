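---
title: "Speculative execution of uncertain tasks in sequential task flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speculative execution of uncertain tasks in sequential task flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specflow)
```

## The problem

In the sequential task flow (STF) model a single thread inserts tasks,
declaring for each task how it accesses each datum (`READ`, `WRITE`), and
the runtime derives the dependency DAG that guarantees the parallel result
equals the sequential one. Metropolis Monte Carlo (MC) simulations break
this model's parallelism: each proposed move *may* modify a domain of
particles and the energy matrix, so every move task must declare `WRITE`
and the whole simulation serializes -- even though a large fraction of
moves is rejected and writes nothing.

`specflow` adds a third access mode, `MAYBE_WRITE`. A task with such an
access is *uncertain*: only when it completes does its body report a
did-write flag. Declaring uncertainty lets the runtime speculate: it copies
the maybe-written data before the uncertain task, runs a *speculative twin*
of the next task early on the copies, and inserts a *select* task per datum
that, when enabled, overwrites the original with the duplicate (`x = x'`).
If the uncertain task reports no write, the twin's result is the real
result: the original successor is disabled and the selects merge the
duplicates back. If it wrote, the twin's output is discarded (cancelled if
it has not started; otherwise it runs to completion harmlessly), the
selects stay disabled, and the original path runs. Either way the final
payloads are exactly the sequential ones -- speculation only changes *when*
things run.

## Speculative task groups and chains

Construction happens entirely at insertion time, with a registry of live
duplicates. Each speculation level is a *group* holding its copy tasks, the
original task, its twin and its selects; groups are linked parent-to-child
rather than merged, and outcomes flow along the links:

* a level whose ancestors all reported "did not write" is *valid*: its
  original is disabled, its selects enabled, and (for an uncertain level)
  its twin's did-write flag decides the next level;
* one write anywhere invalidates every downstream group -- twins are
  cancelled best-effort, selects disabled, originals re-enabled. This is
  *predictive* speculation: after a failure the remaining tasks run
  normally, with no re-speculation.

For a chain of consecutive uncertain tasks on the same data, each insertion
makes two copies per maybe-written datum from the current registry head:
a write target for the twin, and a clean copy registered as the head for
the *next* level. The clean heads are what let all twins of a chain start
together -- the degree of parallelism grows with the chain length. A
certain `WRITE` consumes the duplicates of the data it writes (its selects
remove them from the registry), which is the barrier that restarts
speculation; the MC task flow inserts one certain task after every
`spec_depth` uncertain ones for exactly this purpose.

Whether to speculate at all is decided at run time, once per group, when
the group's first copy task becomes ready; the policy hook sees the number
of ready tasks and the worker count. The default (`policy_always_on()`)
always speculates; `policy_threshold()` speculates only while the scheduler
is starved. A disabled group degrades to the plain task-based run.

## Executors and the timing model

Three engines execute the same graph and end with identical payloads:

* `run_sequential()`: enabled tasks in insertion order -- the reference;
* `run_parallel()`: a deterministic logical worker pool (FIFO ready queue
  keyed by insertion index, earliest-free worker, durations ignored).
  Workers are a scheduling contract, not OS threads, which keeps every
  interleaving reproducible and testable;
* `run_simulated()`: the same greedy list-scheduling engine driven by task
  durations (abstract units), returning a hardware-independent makespan.

Numerical/tie-break choices: at a given clock value, completions are
processed (in insertion order) before each new start, so a cancellation
that becomes known at a twin's would-be start instant still cancels it,
while a twin that started earlier contributes its full duration. A task
disabled before starting costs zero time. Copy and select tasks default to
zero duration, matching the unit-cost performance model below, and are
configurable (`copy_duration`, `select_duration`).

On the four-task demonstration graph (one uncertain task `B`, durations
`copy`, `B`, `C`, `C'`, `select`), the simulated makespan with two workers
is `copy + max(B + C, C')` when `B` writes and
`copy + max(B, C') + select` when it does not -- the tests assert both
closed forms for arbitrary integer durations.

```{r}
rt <- stf_runtime("simulated", workers = 2, copy_duration = 1,
                  select_duration = 1)
demo <- demo_uncertain_chain(rt, b_writes = FALSE,
                             durations = c(a = 0, b = 2, c = 3, twin = 4,
                                           d = 0))
wait_all(rt)
makespan(rt)   # 1 + max(2, 4) + 1
data_value(demo$x)
```

## Expected speedup of a speculation chain

For `N` consecutive uncertain tasks followed by one certain task, all of
cost `t`, with negligible copies/selects and at least `N` workers, the
predictive strategy saves `i t` when the first writing task is number
`i + 1`, and `N t` when none writes. With `P_i` the probability that task
`i` writes (and `P_{N+1} = 1` for the closing certain task):

$$D_N = \sum_{i=1}^{N} t\, i\, P_{i+1} \prod_{j \le i} (1 - P_j), \qquad
  S = \frac{(N+1)\,t}{(N+1)\,t - D_N}.$$

The eager strategy (theory only: the runtime would need
`(N^2 + N)/2 - N` extra speculative tasks, see `eager_task_count()`)
re-speculates after every failure, so every non-writing task saves a full
`t`: `F(N) = t \sum_i (1 - P_i)`. At uniform `p = 1/2` its speedup is
`2 (N+1) / (N+2)`, which approaches 2 for long chains (the limit quoted
for the eager scheme; it is attained only as `N` grows).

```{r}
theory_table(n_max = 7)[, 1:6]
predictive_gain(rep(0.5, 3))      # 0.875
eager_speedup(rep(0.5, 1e6))      # ~2
```

`mc_gain_estimate()` is the stochastic oracle for `D_N`: it simulates
write/no-write chains and averages the realized saving; the tests require
agreement with the closed form within four standard errors over the whole
probability grid, and the simulated-clock executor reproduces the
per-outcome saving exactly on forced-outcome chains (theory and scheduler
agree outcome by outcome, not just in expectation).

The printed reference table is reproduced at its printed precision; its
exact midpoint cells (0.3125, 0.9375) resolve half to even, so the
comparison uses banker's rounding (`round()`), while `round_half_up()` is
kept for contexts that prescribe half-up.

## The Monte Carlo application

The simulator works on `D` domains of `P` particles in a box (reduced
units, `epsilon = sigma = 1`, Boltzmann constant 1). The energy is the
Lennard-Jones pair sum `4 (r^-12 - r^-6)` over all particle pairs, with no
cutoff and no periodic images -- the box only bounds move proposals. The
energy lives in a symmetric `D x D` domain-pair matrix (diagonal:
intra-domain), so a single-domain move touches one row/column
(`update_energy()` is `O(P^2 (D-1)/D)` instead of `O(P^2)`) and, more
importantly, realizes the maybe-write access pattern: each move task
declares `MAYBE_WRITE` on the energy matrix, its domain and the RNG key,
and `READ` on every other domain. A move redistributes all particles of
one domain uniformly in the box and is accepted with the Metropolis
probability `min(1, exp(-dE/T))`.

Randomness follows an *RNG-as-data* contract: every draw comes from an
explicit RNG-state datum in the task's access list. The state is a
counter-based key -- the draws for iteration `iter`, domain `d` come from
sub-streams derived from `(key, iter, d, purpose)` (`stream_seed()`), with
move draws first and the acceptance draw last. Because the key itself is
never advanced, a speculative twin holding a copy draws the identical
stream as the original task, which is what makes the task-flow execution
*bitwise* equal to the sequential Algorithm-style reference (`run_mc()`),
for any executor, worker count and speculation depth. This is the headline
correctness property and is asserted on toy systems in the tests.

Replica exchange (`run_remc()` / `build_remc_taskflow()`) runs one MC
chain per temperature; after every `exchange_period` sweeps, neighbouring
replicas attempt to swap configurations via a Metropolis test on their
energy difference, evaluated at the lower-indexed replica's temperature,
alternating odd-even pairs on odd phases and even-odd pairs otherwise.
Exchange tasks are certain writers of both replicas' domains and energies,
so they double as speculation barriers.

```{r}
cfg <- mc_config(num_domains = 2, particles_per_domain = 12,
                 temperature = 2, num_loops = 3, spec_depth = 2, seed = 7)
ref <- run_mc(cfg)
tf <- run_mc_taskflow(cfg, executor = "parallel", workers = 4)
identical(tf$domains, ref$domains)
ref$accept_ratio
```

### What the generator emulates -- and what it does not

The default configuration mirrors the reference study conditions: 5
domains of 2,000 particles, 5 replicas, an exchange every 3 sweeps,
speculation always enabled. Defaults chosen where no value was stated: a
cubic box at reduced number density 0.01 (uniform random placement then
stays in a moderate-energy regime where both acceptances and rejections
occur), temperature 1 in reduced units, uniform redistribution moves. The
tests and examples run far smaller systems (2-5 domains, 4-20 particles,
a handful of sweeps; random graphs of 6-18 tasks) so the whole suite
completes in well under a minute; sizes are stated in each test. Passing
them demonstrates the runtime's construction, scheduling and
bitwise-equivalence guarantees -- it does not demonstrate physical realism
(no cutoffs, no periodic images, whole-domain redistribution is a crude
proposal) nor wall-clock speedups on real cores, which depend on hardware
and on the accept ratio regime. The all-reject mode (`force_reject`) gives
the idealized regime in which every speculation succeeds: with at least
`D` workers the simulated critical path carries a single move task per
sweep, the qualitative upper-bound shape.

## Degenerate inputs and numerical notes

Coincident particles (`r = 0`) raise an error naming both particles.
Energies are compared to full recomputation within `1e-9` relative in the
tests; the incremental update recomputes whole rows with the same kernel,
so agreement is at machine precision. Payloads must be value-semantic
(copyable, comparable); environments, connections and pointers are
rejected at registration. A duplicate-edge between two tasks is recorded
once; readers between two writes are mutually unordered. Uncertain bodies
must return a scalar did-write flag; violations are runtime errors, not
silent misbehaviour.

## Known limitations

* Eager speculation is implemented as theory only (gain/speedup/task
  count); the runtime never re-speculates after a failure.
* Group failure is tracked at group granularity: one write fails every
  downstream level, even levels on data the writer never touched.
* The worker pool is logical; the package measures schedules in abstract
  time and does not use OS threads.
* Greedy list scheduling is not optimal and, in adversarial graphs, adding
  workers can in principle lengthen a schedule; the non-increasing-makespan
  property is asserted on the random-graph family used throughout, not
  proved in general.
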