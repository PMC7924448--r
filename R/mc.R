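# Metropolis Monte Carlo on a multi-domain particle system, as a sequential
# reference implementation and as a speculative task flow.
#
# Randomness contract (RNG-as-data): every random draw a task consumes comes
# from an explicit RNG-state datum in its access list.  The state is a
# counter-based key: the draws of the move and of the acceptance test for
# iteration `iter`, domain `d` are produced from sub-streams derived from
# (key, iter, d), not from a shared sequential stream.  A speculative twin
# holding a copy of the key therefore draws the identical stream as the
# original task, which is what makes sequential and speculative executions
# bitwise identical.

#' Derive a reproducible sub-stream seed
#'
#' Mixes a base key with integer indices (iteration, domain, purpose, ...)
#' into a seed below 2^31, so that independent draw groups can be replayed
#' in any order.
#'
#' @param key integer base key.
#' @param ... integer indices identifying the draw group.
#' @return an integer seed.
#' @export
stream_seed <- function(key, ...) {
  idx <- c(...)
  m <- .Machine$integer.max
  s <- as.numeric(key) %% m
  mult <- c(1000003, 7919, 104729, 613651)
  for (i in seq_along(idx)) {
    k <- mult[((i - 1L) %% length(mult)) + 1L]
    s <- (s * 31 + as.numeric(idx[i]) * k + 17) %% m
  }
  as.integer(s)
}

#' Evaluate an expression under a temporary RNG stream
#'
#' Seeds R's generator with `seed`, evaluates `expr`, and restores the
#' previous global RNG state, so task bodies never perturb (nor depend on)
#' the session stream.
#'
#' @param seed integer seed (see [stream_seed()]).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_stream <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a random particle system
#'
#' Particles are placed uniformly in the box, the standard initial state of
#' the simulator (moves later redistribute a whole domain the same way).
#'
#' @param num_domains number of domains.
#' @param particles_per_domain particles in each domain.
#' @param box edge lengths (length 3); by default a cube at reduced number
#'   density 0.01, which keeps a random uniform configuration in a
#'   moderate-energy regime.
#' @param seed integer seed.
#' @return list of `P x 3` position matrices.
#' @export
make_particle_system <- function(num_domains, particles_per_domain,
                                 box = NULL, seed = 1L) {
  box <- box %||% default_box(num_domains * particles_per_domain)
  with_stream(stream_seed(seed, 424243L), {
    lapply(seq_len(num_domains), function(d) {
      random_positions(particles_per_domain, box)
    })
  })
}

default_box <- function(n_particles, density = 0.01) {
  rep((n_particles / density)^(1 / 3), 3)
}

random_positions <- function(n, box) {
  sweep(matrix(runif(n * 3), n, 3), 2L, box, "*")
}

#' Propose a domain move
#'
#' Redistributes every particle of the domain uniformly in the box (the
#' move used by the simulator), drawing from the sub-stream `seed`. The
#' original domain is not modified; the same seed always yields the same
#' proposal.
#'
#' @param domain `P x 3` position matrix.
#' @param box edge lengths.
#' @param seed sub-stream seed (see [stream_seed()]).
#' @return a new `P x 3` position matrix inside the box.
#' @export
move_domain <- function(domain, box, seed) {
  with_stream(seed, random_positions(nrow(domain), box))
}

#' Metropolis acceptance probability
#'
#' `min(1, exp(-(new - old) / temperature))` in reduced units (Boltzmann
#' constant 1). Downhill moves are always accepted.
#'
#' @param new_energy,old_energy total energies.
#' @param temperature temperature (> 0), reduced units.
#' @return a probability in `[0, 1]`.
#' @export
metropolis_probability <- function(new_energy, old_energy, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("'temperature' must be > 0", call. = FALSE)
  }
  min(1, exp(-(new_energy - old_energy) / temperature))
}

## ---- configuration ----------------------------------------------------------

#' Monte Carlo simulation configuration
#'
#' @param num_domains number of particle domains.
#' @param particles_per_domain particles per domain.
#' @param temperature reduced temperature (> 0).
#' @param num_loops number of MC sweeps (each sweep proposes one move per
#'   domain).
#' @param spec_depth S, the number of consecutive uncertain tasks inserted
#'   before a certain task forces the speculation to restart (>= 1). With
#'   `spec_depth = num_domains` the speculation restarts once per sweep.
#' @param seed integer RNG key.
#' @param box box edge lengths; default density 0.01 cube.
#' @param force_reject logical; when `TRUE` every proposal is rejected
#'   (the all-reject reference regime in which every speculation succeeds).
#' @return a list of class `mc_config`.
#' @export
mc_config <- function(num_domains = 5L, particles_per_domain = 2000L,
                      temperature = 1, num_loops = 10L,
                      spec_depth = num_domains, seed = 1L, box = NULL,
                      force_reject = FALSE) {
  stopifnot(num_domains >= 1, particles_per_domain >= 1, temperature > 0,
            num_loops >= 1, spec_depth >= 1)
  structure(list(
    num_domains = as.integer(num_domains),
    particles_per_domain = as.integer(particles_per_domain),
    temperature = temperature,
    num_loops = as.integer(num_loops),
    spec_depth = as.integer(spec_depth),
    seed = as.integer(seed),
    box = box %||% default_box(num_domains * particles_per_domain),
    force_reject = isTRUE(force_reject)), class = "mc_config")
}

# One (iteration, domain) step: propose, update energy incrementally, accept
# or reject.  Shared verbatim by the sequential reference and the task
# bodies so both follow the identical floating-point path.
mc_step <- function(domains, energy, d, iter, key, temperature, box,
                    force_reject) {
  new_d <- move_domain(domains[[d]], box, stream_seed(key, iter, d, 1L))
  new_energy <- update_energy(energy, new_d, d, domains, box)
  u <- with_stream(stream_seed(key, iter, d, 2L), runif(1))
  p <- metropolis_probability(total_energy(new_energy), total_energy(energy),
                              temperature)
  accepted <- !force_reject && u <= p
  list(new_d = new_d, new_energy = new_energy, accepted = accepted)
}

#' Sequential Metropolis Monte Carlo reference
#'
#' Per sweep and per domain: propose a uniform redistribution, update the
#' energy matrix incrementally, and accept with the Metropolis probability.
#' Fully reproducible from the seed; this is the ground-truth the task-flow
#' execution must reproduce bitwise.
#'
#' @param config an [mc_config()].
#' @param domains optional initial system (defaults to
#'   [make_particle_system()] from the config seed).
#' @return list with final `domains`, `energy` matrix, `accept_ratio`,
#'   per-sweep `stats` (data.frame: loop, accept_ratio, total_energy) and
#'   the `config`.
#' @export
run_mc <- function(config, domains = NULL) {
  stopifnot(inherits(config, "mc_config"))
  domains <- domains %||% make_particle_system(
    config$num_domains, config$particles_per_domain, config$box, config$seed)
  energy <- compute_energy(domains, config$box)
  key <- config$seed
  acc <- 0L
  stats <- vector("list", config$num_loops)
  for (iter in seq_len(config$num_loops)) {
    acc_loop <- 0L
    for (d in seq_len(config$num_domains)) {
      st <- mc_step(domains, energy, d, iter, key, config$temperature,
                    config$box, config$force_reject)
      if (st$accepted) {
        domains[[d]] <- st$new_d
        energy <- st$new_energy
        acc_loop <- acc_loop + 1L
      }
    }
    acc <- acc + acc_loop
    stats[[iter]] <- data.frame(loop = iter,
                                accept_ratio = acc_loop / config$num_domains,
                                total_energy = total_energy(energy))
  }
  list(domains = domains, energy = energy,
       accept_ratio = acc / (config$num_loops * config$num_domains),
       stats = do.call(rbind, stats), config = config)
}

## ---- task-flow build --------------------------------------------------------

mc_task_body <- function(d, iter, n_domains, temperature, box, force_reject) {
  # evaluate every argument now: the factory is called inside loops and the
  # bodies run much later
  force(d); force(iter); force(n_domains); force(temperature)
  force(box); force(force_reject)
  # access order: energy, domain d, rng key, all other domains (ascending)
  others <- setdiff(seq_len(n_domains), d)
  function(vals) {
    energy <- vals[[1L]]
    dom <- vals[[2L]]
    key <- vals[[3L]]$key
    domains <- vector("list", n_domains)
    domains[[d]] <- dom
    for (k in seq_along(others)) domains[[others[k]]] <- vals[[3L + k]]
    st <- mc_step(domains, energy, d, iter, key, temperature, box,
                  force_reject)
    out <- vals
    if (st$accepted) {
      out[[1L]] <- st$new_energy
      out[[2L]] <- st$new_d
    }
    list(values = out, did_write = st$accepted, result = st$accepted)
  }
}

#' Build the Monte Carlo speculative task flow
#'
#' One task per (sweep, domain) move: it accesses the energy matrix, its
#' domain and the RNG key in maybe-write mode and every other domain in
#' read mode, and reports on completion whether the move was accepted.
#' After every `spec_depth` consecutive uncertain tasks one task is
#' inserted as a certain writer instead, which restarts the speculation
#' process. An initial certain task computes the starting energy matrix.
#'
#' @param rt a fresh `stf_runtime`.
#' @param config an [mc_config()].
#' @param domains optional initial system.
#' @param task_duration,init_duration abstract durations of the move tasks
#'   and the initial energy task (for the simulated executor).
#' @return list with the runtime, the data handles (`energy`, `domains`,
#'   `rng`) and the move-task references, invisibly.
#' @export
build_mc_taskflow <- function(rt, config, domains = NULL, task_duration = 1,
                              init_duration = 1) {
  stopifnot(inherits(rt, "stf_runtime"), inherits(config, "mc_config"))
  domains <- domains %||% make_particle_system(
    config$num_domains, config$particles_per_domain, config$box, config$seed)
  nd <- config$num_domains
  h_energy <- register_data(rt, NULL, name = "energy")
  h_dom <- lapply(seq_len(nd), function(d) {
    register_data(rt, domains[[d]], name = paste0("dom", d))
  })
  h_rng <- register_data(rt, list(key = config$seed), name = "rng")
  box <- config$box
  insert_task(rt,
              c(list(sp_write(h_energy)), lapply(h_dom, sp_read)),
              function(vals) {
                vals[[1L]] <- compute_energy(vals[-1L], box)
                list(values = vals)
              },
              duration = init_duration, name = "init_energy")
  refs <- list()
  consec <- 0L
  for (iter in seq_len(config$num_loops)) {
    for (d in seq_len(nd)) {
      certain <- consec >= config$spec_depth
      consec <- if (certain) 0L else consec + 1L
      mode <- if (certain) sp_write else sp_maybe_write
      others <- setdiff(seq_len(nd), d)
      accs <- c(list(mode(h_energy), mode(h_dom[[d]]), mode(h_rng)),
                lapply(h_dom[others], sp_read))
      refs[[length(refs) + 1L]] <- insert_task(
        rt, accs,
        mc_task_body(d, iter, nd, config$temperature, box,
                     config$force_reject),
        duration = task_duration, uncertain = !certain,
        name = sprintf("move(%d,%d)%s", iter, d, if (certain) "!" else ""))
    }
  }
  invisible(list(runtime = rt, energy = h_energy, domains = h_dom,
                 rng = h_rng, tasks = refs))
}

#' Run the Monte Carlo task flow and collect the final state
#'
#' Builds the task flow, executes it with the chosen engine and returns the
#' final state in the same shape as [run_mc()] (plus the trace), so the two
#' can be compared payload-by-payload.
#'
#' @inheritParams build_mc_taskflow
#' @param executor `"sequential"`, `"parallel"` or `"simulated"`.
#' @param workers worker count.
#' @param ... passed to [stf_runtime()] (e.g. `speculation_policy`).
#' @return list with `domains`, `energy`, `trace`, `makespan`, `runtime`.
#' @export
run_mc_taskflow <- function(config, domains = NULL,
                            executor = c("parallel", "sequential", "simulated"),
                            workers = config$num_domains, ...) {
  executor <- match.arg(executor)
  rt <- stf_runtime(executor, workers = workers, ...)
  fl <- build_mc_taskflow(rt, config, domains = domains)
  wait_all(rt)
  tr <- run_trace(rt)
  list(domains = lapply(fl$domains, data_value),
       energy = data_value(fl$energy),
       trace = tr, makespan = tr$makespan, runtime = rt)
}
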