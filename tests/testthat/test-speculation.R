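test_that("select tasks act as a switch over the duplicate", {
  # speculation holds: the select overwrites x with the twin's output
  rt <- stf_runtime("parallel", workers = 4)
  d <- demo_uncertain_chain(rt, b_writes = FALSE)
  wait_all(rt)
  expect_identical(data_value(d$x), 3L)   # x = (1) * 2 + 1 via the twin
  n <- graph_nodes(rt)
  expect_identical(n$activation[n$role == "select"], "ENABLED")
  expect_identical(n$activation[n$name == "C"], "DISABLED")

  # speculation fails: the select is disabled, the original path runs
  rt <- stf_runtime("parallel", workers = 4)
  d <- demo_uncertain_chain(rt, b_writes = TRUE)
  wait_all(rt)
  expect_identical(data_value(d$x), 23L)  # x = (1 + 10) * 2 + 1 via C
  n <- graph_nodes(rt)
  expect_identical(n$activation[n$role == "select"], "DISABLED")
  expect_identical(n$activation[n$name == "C"], "ENABLED")
})

test_that("a task reading another producer's datum shares it; writing forces a copy", {
  # writing the shared datum: one extra copy and one extra select
  rt_w <- stf_runtime("parallel", workers = 4)
  demo_shared_datum(rt_w, c_writes_y = TRUE)
  n_w <- graph_nodes(rt_w)
  # reading it: original and twin use the same datum concurrently
  rt_r <- stf_runtime("parallel", workers = 4)
  demo_shared_datum(rt_r, c_writes_y = FALSE)
  n_r <- graph_nodes(rt_r)
  expect_identical(sum(n_w$role == "copy") - sum(n_r$role == "copy"), 1L)
  expect_identical(sum(n_w$role == "select") - sum(n_r$role == "select"), 1L)
  for (bw in c(TRUE, FALSE)) for (wy in c(TRUE, FALSE)) {
    rt <- stf_runtime("parallel", workers = 4)
    d <- demo_shared_datum(rt, c_writes_y = wy, b_writes = bw)
    wait_all(rt)
    x <- 2L; if (bw) x <- x + 100L
    expect_identical(data_value(d$x), (x + 5L) * 3L)
    expect_identical(data_value(d$y), if (wy) 6L else 5L)
  }
})

test_that("two independent uncertain tasks open two unlinked root groups", {
  rt <- stf_runtime()
  x <- register_data(rt, 1)
  y <- register_data(rt, 2)
  insert_task(rt, list(sp_maybe_write(x)),
              function(v) list(values = v, did_write = FALSE))
  insert_task(rt, list(sp_maybe_write(y)),
              function(v) list(values = v, did_write = FALSE))
  g <- group_table(rt)
  expect_identical(nrow(g), 2L)
  expect_true(all(g$root))
  expect_identical(nrow(graph_edges(rt)), 2L)  # only copy -> uncertain, per datum
})

test_that("an uncertain task after a dead group starts a fresh chain without a twin", {
  rt <- stf_runtime("sequential", speculation_policy = policy_always_off())
  x <- register_data(rt, 1)
  insert_task(rt, list(sp_write(x)), function(v) list(values = list(2)))
  insert_task(rt, list(sp_maybe_write(x)),
              function(v) list(values = v, did_write = FALSE))
  wait_all(rt)  # the policy disables the first group
  expect_identical(group_table(rt)$policy, "DISABLED")
  insert_task(rt, list(sp_maybe_write(x)),
              function(v) list(values = v, did_write = FALSE))
  g <- group_table(rt)
  expect_identical(nrow(g), 2L)
  expect_true(g$root[2])                       # fresh parentless chain
  n <- graph_nodes(rt)
  expect_identical(sum(n$speculative), 0L)     # no speculative twin created
  wait_all(rt)
  expect_identical(data_value(x), 2)
})

test_that("one write fails every downstream group; upstream successes stand", {
  # chain U1 (no write), U2 (writes), U3 (writes), then a certain task:
  # level 2 is valid (its select runs, its original is disabled), while the
  # groups after the writing task fall back to their originals.
  rt <- stf_runtime("parallel", workers = 8)
  x <- build_forced_chain(rt, c(FALSE, TRUE, TRUE))
  wait_all(rt)
  expect_identical(data_value(x), forced_chain_oracle(c(FALSE, TRUE, TRUE)))
  g <- group_table(rt)
  expect_identical(g$validity[2], "VALID")     # U2's level: speculation held
  expect_false(g$failed[2])
  expect_true(all(g$validity[3:4] == "INVALID"))
  expect_true(all(g$failed[3:4]))
  n <- graph_nodes(rt)
  sel <- n[n$role == "select", ]
  expect_identical(sel$activation[1], "ENABLED")
  expect_true(all(sel$activation[-1] == "DISABLED"))
  orig <- n[n$name %in% c("U2", "U3", "N"), ]
  expect_identical(orig$activation, c("DISABLED", "ENABLED", "ENABLED"))
})

test_that("longer mixed-outcome chains settle selects and originals consistently", {
  # first task writes nothing, the next three write: the first guarded level
  # is merged in via its select, every later select is disabled and the
  # originals run (no restart after a failure)
  for (mask in list(c(FALSE, TRUE, TRUE, TRUE), c(TRUE, FALSE, FALSE),
                    c(FALSE, FALSE, TRUE, FALSE))) {
    rt <- stf_runtime("parallel", workers = 8)
    x <- build_forced_chain(rt, mask)
    wait_all(rt)
    expect_identical(data_value(x), forced_chain_oracle(mask))
    g <- group_table(rt)
    first_writer <- which(mask)[1]
    if (!is.na(first_writer)) {
      lvl <- g[!g$root, ]
      if (first_writer > 1) {
        expect_true(all(lvl$validity[seq_len(first_writer - 1)] == "VALID"))
      }
      expect_true(all(lvl$validity[seq(first_writer,
                                       nrow(lvl))] == "INVALID"))
    } else {
      expect_true(all(g$validity == "VALID"))
    }
  }
})

test_that("non-consecutive uncertain tasks stay linked through their groups", {
  for (bw in c(FALSE, TRUE)) for (fw in c(FALSE, TRUE)) {
    rt <- stf_runtime("parallel", workers = 6)
    d <- demo_nonconsecutive_uncertain(rt, b_writes = bw, f_writes = fw)
    wait_all(rt)
    x <- 3L; if (bw) x <- x + 7L; x <- x * 2L
    if (fw) x <- x - 5L; x <- x + 11L
    expect_identical(data_value(d$x), x)
    expect_identical(task_result(d$refs$h), x)
  }
})

test_that("consecutive uncertain tasks speculate concurrently (increasing parallelism)", {
  # with S = 3 uncertain tasks and enough workers, the first task and the
  # speculative twins of the later levels all run in the same time slot
  rt <- stf_runtime("simulated", workers = 8)
  build_forced_chain(rt, c(FALSE, FALSE, FALSE))
  wait_all(rt)
  tr <- run_trace(rt)$records
  twins <- tr[tr$speculative, ]
  root <- tr[tr$name == "U1", ]
  expect_identical(nrow(twins), 3L)           # U2', U3', N'
  expect_true(all(twins$start == root$start))
  expect_identical(makespan(rt), root$end)    # everything else is free
})

test_that("registry hygiene: at most one live duplicate per datum", {
  for (s in c(3, 7, 11)) {
    rt <- stf_runtime()
    build_case(random_graph_case(s), rt)
    reg <- rt$registry
    keys <- ls(reg)
    origs <- vapply(keys, function(k) get(k, envir = reg)$orig$id, integer(1))
    expect_false(anyDuplicated(origs) > 0)
  }
})

test_that("speculation policies steer group activation", {
  # threshold policy: with a saturated ready queue the group is disabled
  rt <- stf_runtime("parallel", workers = 1,
                    speculation_policy = policy_threshold())
  # several independent ready tasks saturate the single worker
  hs <- lapply(1:4, function(i) register_data(rt, i))
  for (h in hs) insert_task(rt, list(sp_write(h)),
                            function(v) list(values = list(0)))
  x <- register_data(rt, 1)
  insert_task(rt, list(sp_write(x)), function(v) list(values = list(2)))
  insert_task(rt, list(sp_maybe_write(x)),
              function(v) list(values = v, did_write = FALSE))
  insert_task(rt, list(sp_write(x)), function(v) list(values = list(9)))
  wait_all(rt)
  expect_identical(group_table(rt)$policy[1], "DISABLED")
  expect_identical(data_value(x), 9)

  # always-on: every group enabled
  rt2 <- stf_runtime("parallel", workers = 2)
  build_forced_chain(rt2, c(FALSE, FALSE))
  wait_all(rt2)
  expect_true(all(group_table(rt2)$policy %in% c("ENABLED", "UNDEFINED")))
})
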