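test_that("chains and empty graphs have the obvious makespans", {
  rt <- stf_runtime("simulated", workers = 4)
  wait_all(rt)
  expect_identical(makespan(rt), 0)
  for (w in c(1, 3)) {
    rt <- stf_runtime("simulated", workers = w)
    x <- register_data(rt, 0)
    for (i in 1:5) insert_task(rt, list(sp_write(x)),
                               function(v) list(values = list(i)),
                               duration = 1)
    wait_all(rt)
    expect_identical(makespan(rt), 5)  # a chain has no parallelism
  }
})

test_that("the simulated clock reproduces both speculative timing closed forms", {
  set.seed(99)
  for (rep in 1:8) {
    dur <- sample(1:9, 5, replace = TRUE)  # copy, B, C, C', select
    for (bw in c(TRUE, FALSE)) {
      rt <- stf_runtime("simulated", workers = 3,
                        copy_duration = dur[1], select_duration = dur[5])
      demo_uncertain_chain(rt, b_writes = bw,
                           durations = c(a = 0, b = dur[2], c = dur[3],
                                         twin = dur[4], d = 0))
      wait_all(rt)
      expected <- if (bw) {
        dur[1] + max(dur[2] + dur[3], dur[4])          # copy + max(B + C, C')
      } else {
        dur[1] + max(dur[2], dur[4]) + dur[5]          # copy + max(B, C') + select
      }
      expect_equal(makespan(rt), as.numeric(expected),
                       label = paste("durations", paste(dur, collapse = ","),
                                     "bw", bw))
    }
  }
})

test_that("a cancelled twin costs nothing; a started one runs to completion", {
  # B instantaneous: its failure is known before the twin starts, so the
  # twin is cancelled and contributes zero
  rt <- stf_runtime("simulated", workers = 3, copy_duration = 2)
  demo_uncertain_chain(rt, b_writes = TRUE,
                       durations = c(a = 0, b = 0, c = 3, twin = 50, d = 0))
  wait_all(rt)
  expect_identical(makespan(rt), 2 + 3)
  tr <- run_trace(rt)$records
  twin <- tr[tr$speculative, ]
  expect_identical(twin$activation, "DISABLED")
  expect_identical(twin$end - twin$start, 0)

  # B takes time: the twin has started and its duration is paid in full
  rt <- stf_runtime("simulated", workers = 3, copy_duration = 2)
  demo_uncertain_chain(rt, b_writes = TRUE,
                       durations = c(a = 0, b = 1, c = 3, twin = 50, d = 0))
  wait_all(rt)
  expect_identical(makespan(rt), 2 + max(1 + 3, 50))
})

test_that("payloads agree across executors and worker counts on random graphs", {
  for (s in 1:25) {
    case <- random_graph_case(s)
    exp <- oracle_case(case)
    rt <- stf_runtime("sequential")
    hs <- build_case(case, rt)
    wait_all(rt)
    expect_identical(lapply(hs, data_value), exp, label = paste("seq seed", s))
    for (ex in c("parallel", "simulated")) {
      w <- c(2, 8)[s %% 2 + 1]
      rt <- stf_runtime(ex, workers = w)
      hs <- build_case(case, rt)
      wait_all(rt)
      expect_identical(lapply(hs, data_value), exp,
                       label = paste(ex, "workers", w, "seed", s))
    }
  }
})

test_that("simulated makespan does not increase with more workers", {
  for (s in 1:20) {
    case <- random_graph_case(s + 300)
    m <- vapply(c(1, 2, 4, 8), function(w) {
      rt <- stf_runtime("simulated", workers = w)
      build_case(case, rt)
      wait_all(rt)
      makespan(rt)
    }, numeric(1))
    expect_true(all(diff(m) <= 1e-9), label = paste("seed", s + 300))
  }
})

test_that("disabling speculation reproduces the plain task-based makespan", {
  mask <- c(FALSE, TRUE, FALSE)
  rt_off <- stf_runtime("simulated", workers = 4,
                        speculation_policy = policy_always_off())
  x_off <- build_forced_chain(rt_off, mask)
  wait_all(rt_off)
  # the plain chain: A (0) + three unit uncertain tasks + the closing writer
  expect_identical(makespan(rt_off), 4)
  expect_identical(data_value(x_off), forced_chain_oracle(mask))
})

test_that("worker assignments never overlap in time", {
  rt <- stf_runtime("simulated", workers = 3)
  build_case(random_graph_case(42), rt)
  wait_all(rt)
  tr <- run_trace(rt)$records
  for (w in unique(tr$worker)) {
    rw <- tr[tr$worker == w & tr$end > tr$start, ]
    if (nrow(rw) > 1) {
      rw <- rw[order(rw$start), ]
      expect_true(all(rw$start[-1] >= rw$end[-nrow(rw)]))
    }
  }
})

test_that("the event log reconstructs the enable/disable narrative", {
  rt <- stf_runtime("parallel", workers = 4)
  build_forced_chain(rt, c(FALSE, TRUE))
  wait_all(rt)
  lg <- event_log(rt)
  expect_true(all(c("insert", "start", "end", "disable",
                    "group_valid", "group_invalid") %in% lg$event))
  # inserts precede starts which precede the matching ends, per task
  for (id in unique(lg$task[lg$event == "start"])) {
    expect_lt(min(lg$seq[lg$event == "insert" & lg$task == id]),
              min(lg$seq[lg$event == "start" & lg$task == id]))
    expect_lt(min(lg$seq[lg$event == "start" & lg$task == id]),
              min(lg$seq[lg$event == "end" & lg$task == id]))
  }
})
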