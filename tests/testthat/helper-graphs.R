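# Fixture builders: random task graphs with uncertain tasks, plus an
# independent oracle that applies the logical tasks in insertion order
# (no runtime machinery), used for sequential-equivalence checks.

random_graph_case <- function(seed) {
  set.seed(seed)
  nh <- sample(2:4, 1)
  n_tasks <- sample(6:18, 1)
  payloads <- as.list(as.numeric(sample(1:9, nh, replace = TRUE)))
  specs <- vector("list", n_tasks)
  for (k in seq_len(n_tasks)) {
    nacc <- sample(seq_len(min(3L, nh)), 1)
    hs <- sample.int(nh, nacc)
    uncertain <- runif(1) < 0.45
    if (uncertain) {
      modes <- c("MAYBE_WRITE",
                 sample(c("READ", "WRITE", "MAYBE_WRITE"), nacc - 1,
                        replace = TRUE, prob = c(.6, .2, .2)))
    } else {
      modes <- sample(c("READ", "WRITE"), nacc, replace = TRUE)
    }
    specs[[k]] <- list(hs = hs, modes = modes,
                       coefs = sample(1:5, nacc, replace = TRUE),
                       wmod = sample(2:4, 1), k = k, uncertain = uncertain)
  }
  list(payloads = payloads, specs = specs)
}

# Deterministic body: the write decision and the written values are pure
# functions of the access payloads, so a speculative twin on duplicated
# payloads computes identical results (the contract bodies must satisfy).
case_body <- function(sp) {
  force(sp)
  function(vals) {
    s <- sum(sp$coefs * unlist(vals))
    dw <- (floor(abs(s)) %% sp$wmod) != 0
    out <- vals
    for (i in seq_along(sp$modes)) {
      m <- sp$modes[i]
      if (m == "WRITE" || (m == "MAYBE_WRITE" && dw)) {
        out[[i]] <- (vals[[i]] * 31 + sp$coefs[i] + sp$k + floor(s) %% 97) %% 1009
      }
    }
    if (sp$uncertain) list(values = out, did_write = dw)
    else list(values = out)
  }
}

build_case <- function(case, rt) {
  hs <- lapply(seq_along(case$payloads), function(i) {
    register_data(rt, case$payloads[[i]], name = paste0("h", i))
  })
  for (sp in case$specs) {
    accs <- lapply(seq_along(sp$hs), function(i) {
      switch(sp$modes[i],
             READ = sp_read(hs[[sp$hs[i]]]),
             WRITE = sp_write(hs[[sp$hs[i]]]),
             MAYBE_WRITE = sp_maybe_write(hs[[sp$hs[i]]]))
    })
    insert_task(rt, accs, case_body(sp), duration = 1 + sp$k %% 3)
  }
  hs
}

oracle_case <- function(case) {
  vals <- case$payloads
  for (sp in case$specs) {
    res <- case_body(sp)(vals[sp$hs])
    for (i in seq_along(sp$hs)) vals[[sp$hs[i]]] <- res$values[[i]]
  }
  vals
}

# A chain of uncertain tasks with forced did-write outcomes, closed by a
# certain writer and a reader; payload arithmetic gives a distinct final
# value for every outcome mask.
build_forced_chain <- function(rt, writes, init_dur = 0, task_dur = 1) {
  x <- register_data(rt, 1, name = "x")
  insert_task(rt, list(sp_write(x)), function(v) list(values = list(10)),
              duration = init_dur, name = "A")
  for (i in seq_along(writes)) {
    local({
      ii <- i
      insert_task(rt, list(sp_maybe_write(x)), function(v) {
        if (writes[ii]) list(values = list(v[[1]] * 3 + ii), did_write = TRUE)
        else list(values = v, did_write = FALSE)
      }, duration = task_dur, name = paste0("U", ii))
    })
  }
  insert_task(rt, list(sp_write(x)), function(v) list(values = list(v[[1]] + 1)),
              duration = task_dur, name = "N")
  x
}

forced_chain_oracle <- function(writes) {
  x <- 10
  for (i in seq_along(writes)) if (writes[i]) x <- x * 3 + i
  x + 1
}

toy_mc_config <- function(...) {
  mc_config(num_domains = 2L, particles_per_domain = 20L, temperature = 2,
            num_loops = 3L, spec_depth = 2L, seed = 101L, ...)
}

toy_remc_config <- function(...) {
  remc_config(temperatures = c(0.5, 1, 2), num_domains = 2L,
              particles_per_domain = 12L, num_loops = 3L,
              exchange_period = 2L, spec_depth = 2L, seed = 202L, ...)
}

# Reference gain/speedup table rows as printed (one decimal precision per
# cell varies); used for agreement checks at printed precision.
printed_speedup_table <- function() {
  list(
    list(p = 0.25, q = "D",
         cells = c("0.75", "1.31", "1.73", "2.05", "2.29", "2.47", "2.6")),
    list(p = 0.25, q = "S",
         cells = c("1.6", "1.78", "1.77", "1.7", "1.62", "1.54", "1.48")),
    list(p = 0.5, q = "D",
         cells = c("0.5", "0.75", "0.875", "0.938", "0.969", "0.984", "0.992")),
    list(p = 0.5, q = "S",
         cells = c("1.33", "1.33", "1.28", "1.23", "1.19", "1.16", "1.14")),
    list(p = 0.75, q = "D",
         cells = c("0.25", "0.312", "0.328", "0.332", "0.333", "0.333", "0.333")),
    list(p = 0.75, q = "S",
         cells = c("1.14", "1.12", "1.09", "1.07", "1.06", "1.05", "1.04")))
}

printed_decimals <- function(s) {
  dot <- as.integer(regexpr(".", s, fixed = TRUE))
  if (dot < 0L) 0L else nchar(s) - dot
}
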