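# Replica exchange Monte Carlo (parallel tempering): several MC chains at
# different temperatures; periodically, neighbouring replicas attempt to
# exchange configurations via a Metropolis test on their energy difference,
# alternating odd-even and even-odd pairs.

#' Replica exchange configuration
#'
#' @param temperatures ascending vector of reduced temperatures (>= 2
#'   replicas, all > 0).
#' @param num_domains,particles_per_domain per-replica system size.
#' @param num_loops number of outer loops; each runs `exchange_period` MC
#'   sweeps per replica and then one exchange phase.
#' @param exchange_period MC sweeps between exchange phases.
#' @param spec_depth speculation depth for the task-flow build (per
#'   replica).
#' @param seed integer RNG key.
#' @param box box edge lengths.
#' @param force_reject reject every MC move (exchanges still attempted).
#' @return a list of class `remc_config`.
#' @export
remc_config <- function(temperatures = c(0.5, 1, 2, 4, 8),
                        num_domains = 5L, particles_per_domain = 2000L,
                        num_loops = 10L, exchange_period = 3L,
                        spec_depth = num_domains, seed = 1L, box = NULL,
                        force_reject = FALSE) {
  stopifnot(length(temperatures) >= 2, all(temperatures > 0),
            num_loops >= 1, exchange_period >= 1)
  structure(list(
    temperatures = temperatures,
    num_replicas = length(temperatures),
    num_domains = as.integer(num_domains),
    particles_per_domain = as.integer(particles_per_domain),
    num_loops = as.integer(num_loops),
    exchange_period = as.integer(exchange_period),
    spec_depth = as.integer(spec_depth),
    seed = as.integer(seed),
    box = box %||% default_box(num_domains * particles_per_domain),
    force_reject = isTRUE(force_reject)), class = "remc_config")
}

replica_key <- function(seed, r) stream_seed(seed, 500009L, r)

#' Exchange partners for one exchange phase
#'
#' Odd-even pairs (1,2), (3,4), ... when the phase index is odd, even-odd
#' pairs (2,3), (4,5), ... otherwise.
#'
#' @param iter exchange phase index (1-based).
#' @param n number of replicas.
#' @return integer vector of lower indices `s`; each pair is `(s, s + 1)`.
#' @export
exchange_pairs <- function(iter, n) {
  n <- as.integer(n)
  if (iter %% 2 == 1) seq.int(1L, n - 1L, by = 2L)
  else if (n >= 3L) seq.int(2L, n - 1L, by = 2L)
  else integer(0)
}

remc_exchange_decision <- function(e_s, e_s1, temp_s, seed, loop, s) {
  u <- with_stream(stream_seed(seed, 700001L, loop, s), runif(1))
  # criterion on the energy difference, at the lower-indexed temperature
  u <= metropolis_probability(e_s, e_s1, temp_s)
}

#' Sequential replica exchange Monte Carlo reference
#'
#' Per outer loop: `exchange_period` MC sweeps on every replica (each at
#' its own temperature and RNG key), then one exchange phase over
#' [exchange_pairs()], swapping domains and energies when the Metropolis
#' test on the energy difference accepts.
#'
#' @param config an [remc_config()].
#' @param replicas optional list of initial systems (one per replica).
#' @return list with final `replicas` (lists of domains), `energies`
#'   (matrices), per-pair `exchange_stats`, per-replica `accept_ratio`, and
#'   the `config`.
#' @export
run_remc <- function(config, replicas = NULL) {
  stopifnot(inherits(config, "remc_config"))
  nr <- config$num_replicas
  replicas <- replicas %||% lapply(seq_len(nr), function(r) {
    make_particle_system(config$num_domains, config$particles_per_domain,
                         config$box, replica_key(config$seed, r))
  })
  energies <- lapply(replicas, compute_energy, box = config$box)
  accept <- integer(nr)
  proposals <- integer(nr)
  ex_rows <- list()
  for (loop in seq_len(config$num_loops)) {
    for (r in seq_len(nr)) {
      key <- replica_key(config$seed, r)
      for (sweep in seq_len(config$exchange_period)) {
        iter <- (loop - 1L) * config$exchange_period + sweep
        for (d in seq_len(config$num_domains)) {
          st <- mc_step(replicas[[r]], energies[[r]], d, iter, key,
                        config$temperatures[r], config$box,
                        config$force_reject)
          proposals[r] <- proposals[r] + 1L
          if (st$accepted) {
            replicas[[r]][[d]] <- st$new_d
            energies[[r]] <- st$new_energy
            accept[r] <- accept[r] + 1L
          }
        }
      }
    }
    for (s in exchange_pairs(loop, nr)) {
      swap <- remc_exchange_decision(total_energy(energies[[s]]),
                                     total_energy(energies[[s + 1L]]),
                                     config$temperatures[s],
                                     config$seed, loop, s)
      if (swap) {
        tmp <- replicas[[s]]; replicas[[s]] <- replicas[[s + 1L]]
        replicas[[s + 1L]] <- tmp
        tmp <- energies[[s]]; energies[[s]] <- energies[[s + 1L]]
        energies[[s + 1L]] <- tmp
      }
      ex_rows[[length(ex_rows) + 1L]] <- data.frame(loop = loop, pair_low = s,
                                                    accepted = swap)
    }
  }
  list(replicas = replicas, energies = energies,
       exchange_stats = if (length(ex_rows)) do.call(rbind, ex_rows) else
         data.frame(loop = integer(0), pair_low = integer(0),
                    accepted = logical(0)),
       accept_ratio = ifelse(proposals > 0, accept / proposals, NA_real_),
       config = config)
}

## ---- task-flow build --------------------------------------------------------

remc_exchange_body <- function(nd, temp_s, seed, loop, s) {
  force(nd); force(temp_s); force(seed); force(loop); force(s)
  # access order: E_s, E_s1, doms of s, doms of s+1
  function(vals) {
    e_s <- vals[[1L]]
    e_s1 <- vals[[2L]]
    swap <- remc_exchange_decision(total_energy(e_s), total_energy(e_s1),
                                   temp_s, seed, loop, s)
    out <- vals
    if (swap) {
      out[[1L]] <- e_s1
      out[[2L]] <- e_s
      for (d in seq_len(nd)) {
        out[[2L + d]] <- vals[[2L + nd + d]]
        out[[2L + nd + d]] <- vals[[2L + d]]
      }
    }
    list(values = out, result = swap)
  }
}

#' Build the replica exchange speculative task flow
#'
#' Each replica gets its own energy matrix, domain handles and RNG key, so
#' its MC move tasks (uncertain, as in [build_mc_taskflow()]) run
#' concurrently across replicas. Exchange phases are certain tasks writing
#' both replicas' energies and domains; they act as speculation barriers
#' for the data they swap.
#'
#' @param rt a fresh `stf_runtime`.
#' @param config an [remc_config()].
#' @param replicas optional initial systems.
#' @param task_duration,init_duration,exchange_duration abstract durations.
#' @return list with the runtime and per-replica handles, invisibly.
#' @export
build_remc_taskflow <- function(rt, config, replicas = NULL,
                                task_duration = 1, init_duration = 1,
                                exchange_duration = 0) {
  stopifnot(inherits(rt, "stf_runtime"), inherits(config, "remc_config"))
  nr <- config$num_replicas
  nd <- config$num_domains
  replicas <- replicas %||% lapply(seq_len(nr), function(r) {
    make_particle_system(config$num_domains, config$particles_per_domain,
                         config$box, replica_key(config$seed, r))
  })
  box <- config$box
  h_energy <- vector("list", nr)
  h_dom <- vector("list", nr)
  h_rng <- vector("list", nr)
  for (r in seq_len(nr)) {
    h_energy[[r]] <- register_data(rt, NULL, name = paste0("E", r))
    h_dom[[r]] <- lapply(seq_len(nd), function(d) {
      register_data(rt, replicas[[r]][[d]], name = paste0("dom", r, ".", d))
    })
    h_rng[[r]] <- register_data(rt, list(key = replica_key(config$seed, r)),
                                name = paste0("rng", r))
    insert_task(rt, c(list(sp_write(h_energy[[r]])),
                      lapply(h_dom[[r]], sp_read)),
                function(vals) {
                  vals[[1L]] <- compute_energy(vals[-1L], box)
                  list(values = vals)
                },
                duration = init_duration, name = paste0("init_E", r))
  }
  consec <- integer(nr)
  for (loop in seq_len(config$num_loops)) {
    for (r in seq_len(nr)) {
      for (sweep in seq_len(config$exchange_period)) {
        iter <- (loop - 1L) * config$exchange_period + sweep
        for (d in seq_len(nd)) {
          certain <- consec[r] >= config$spec_depth
          consec[r] <- if (certain) 0L else consec[r] + 1L
          mode <- if (certain) sp_write else sp_maybe_write
          others <- setdiff(seq_len(nd), d)
          accs <- c(list(mode(h_energy[[r]]), mode(h_dom[[r]][[d]]),
                         mode(h_rng[[r]])),
                    lapply(h_dom[[r]][others], sp_read))
          insert_task(rt, accs,
                      mc_task_body(d, iter, nd, config$temperatures[r], box,
                                   config$force_reject),
                      duration = task_duration, uncertain = !certain,
                      name = sprintf("mv%d(%d,%d)%s", r, iter, d,
                                     if (certain) "!" else ""))
        }
      }
    }
    for (s in exchange_pairs(loop, nr)) {
      accs <- c(list(sp_write(h_energy[[s]]), sp_write(h_energy[[s + 1L]])),
                lapply(h_dom[[s]], sp_write),
                lapply(h_dom[[s + 1L]], sp_write))
      insert_task(rt, accs,
                  remc_exchange_body(nd, config$temperatures[s], config$seed,
                                     loop, s),
                  duration = exchange_duration,
                  name = sprintf("exch(%d,%d-%d)", loop, s, s + 1L))
      consec[s] <- 0L
      consec[s + 1L] <- 0L
    }
  }
  invisible(list(runtime = rt, energy = h_energy, domains = h_dom,
                 rng = h_rng, replicas0 = replicas))
}

#' Run the replica exchange task flow and collect the final state
#'
#' @inheritParams build_remc_taskflow
#' @param executor,workers,... see [run_mc_taskflow()].
#' @return list with `replicas`, `energies`, `trace`, `makespan`,
#'   `runtime`.
#' @export
run_remc_taskflow <- function(config, replicas = NULL,
                              executor = c("parallel", "sequential",
                                           "simulated"),
                              workers = config$num_replicas, ...) {
  executor <- match.arg(executor)
  rt <- stf_runtime(executor, workers = workers, ...)
  fl <- build_remc_taskflow(rt, config, replicas = replicas)
  wait_all(rt)
  tr <- run_trace(rt)
  list(replicas = lapply(fl$domains, function(hs) lapply(hs, data_value)),
       energies = lapply(fl$energy, data_value),
       trace = tr, makespan = tr$makespan, runtime = rt)
}
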