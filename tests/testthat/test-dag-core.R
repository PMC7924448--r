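test_that("data registration gives fresh handles with value semantics", {
  rt <- stf_runtime()
  h <- register_data(rt, 0)
  expect_s3_class(h, "stf_handle")
  expect_identical(data_value(h), 0)
  h2 <- register_data(rt, 0)
  expect_false(identical(h$id, h2$id))  # identity is not equality
  expect_error(register_data(rt, new.env()), "copyable")
  expect_error(register_data(rt, list(a = 1, f = sum)), "copyable")
  # a payload round-trips unchanged through a read/maybe-write task
  m <- matrix(runif(12), 4, 3)
  hm <- register_data(rt, m)
  insert_task(rt, list(sp_maybe_write(hm)),
              function(v) list(values = v, did_write = FALSE))
  wait_all(rt)
  expect_identical(data_value(hm), m)
})

test_that("dependencies follow read-after-write, write-after-read, write-after-write", {
  rt <- stf_runtime()
  x <- register_data(rt, 0)
  insert_task(rt, list(sp_write(x)), function(v) list(values = list(1)))
  insert_task(rt, list(sp_read(x)), function(v) list())
  e <- graph_edges(rt)
  expect_identical(e, data.frame(from = 1L, to = 2L))
  insert_task(rt, list(sp_write(x)), function(v) list(values = list(2)))
  e <- graph_edges(rt)
  expect_setequal(paste(e$from, e$to), c("1 2", "1 3", "2 3"))
  # two readers after one writer are unordered between themselves
  rt2 <- stf_runtime()
  y <- register_data(rt2, 0)
  insert_task(rt2, list(sp_write(y)), function(v) list(values = list(1)))
  insert_task(rt2, list(sp_read(y)), function(v) list())
  insert_task(rt2, list(sp_read(y)), function(v) list())
  e2 <- graph_edges(rt2)
  expect_setequal(paste(e2$from, e2$to), c("1 2", "1 3"))
})

test_that("all two-task access-mode pairs order exactly the conflicting pairs", {
  for (m1 in c("READ", "WRITE")) {
    for (m2 in c("READ", "WRITE")) {
      rt <- stf_runtime()
      x <- register_data(rt, 0)
      acc <- function(m, h) if (m == "READ") sp_read(h) else sp_write(h)
      insert_task(rt, list(acc(m1, x)), function(v) {
        if (m1 == "READ") list() else list(values = list(1))
      })
      insert_task(rt, list(acc(m2, x)), function(v) {
        if (m2 == "READ") list() else list(values = list(2))
      })
      conflict <- !(m1 == "READ" && m2 == "READ")
      expect_identical(nrow(graph_edges(rt)) == 1L, conflict,
                       label = paste(m1, m2))
    }
  }
})

test_that("insert_task validates access modes and flags", {
  rt <- stf_runtime()
  x <- register_data(rt, 0)
  expect_error(insert_task(rt, list(sp_maybe_write(x)),
                           function(v) list(values = v, did_write = FALSE),
                           uncertain = FALSE),
               "uncertain by definition")
  expect_error(insert_task(rt, list(sp_write(x)),
                           function(v) list(values = v), uncertain = TRUE),
               "MAYBE_WRITE")
  expect_error(insert_task(rt, list(sp_write(x)), function(v) list(),
                           duration = -1), "nonnegative")
  expect_error(insert_task(rt, list(x), function(v) list()), "sp_read")
  # an uncertain body that does not report did_write fails at run time
  insert_task(rt, list(sp_maybe_write(x)), function(v) list(values = v))
  expect_error(wait_all(rt), "did_write")
})

test_that("a single uncertain task expands to the seven-node graph", {
  rt <- stf_runtime()
  demo_uncertain_chain(rt)
  n <- graph_nodes(rt)
  expect_identical(nrow(n), 7L)
  expect_identical(sum(n$role == "copy"), 1L)
  expect_identical(sum(n$role == "select"), 1L)
  expect_identical(sum(n$speculative), 1L)
  # chain A -> copy -> B and the speculative path copy -> C' -> select
  e <- graph_edges(rt)
  expect_true(all(e$from < e$to))  # insertion order is topological
})

test_that("insertion order is a topological order for random graphs", {
  for (s in 1:10) {
    rt <- stf_runtime()
    build_case(random_graph_case(s), rt)
    e <- graph_edges(rt)
    expect_true(all(e$from < e$to))
    # no duplicate edges
    expect_false(anyDuplicated(paste(e$from, e$to)) > 0)
  }
})

test_that("waits complete the requested amount of work", {
  rt <- stf_runtime()
  expect_silent(wait_all(rt))  # empty graph returns immediately
  expect_identical(makespan(rt), 0)

  rt <- stf_runtime()
  x <- register_data(rt, 0)
  refs <- lapply(1:5, function(i) {
    insert_task(rt, list(sp_write(x)), function(v) list(values = list(i)))
  })
  expect_error(wait_remain(rt, -1), "nonnegative")
  wait_remain(rt, 2)
  done <- sum(vapply(refs, function(r) task_state(r) == "DONE", logical(1)))
  expect_gte(done, 3L)
  wait_all(rt)
  expect_true(all(vapply(refs, function(r) task_state(r) == "DONE",
                         logical(1))))

  # single-task wait returning the body's flag, as a boolean-returning task
  rt2 <- stf_runtime()
  y <- register_data(rt2, 5)
  r <- insert_task(rt2, list(sp_maybe_write(y)),
                   function(v) list(values = list(v[[1]] + 1), did_write = TRUE))
  expect_true(task_wait(r))
  expect_identical(data_value(y), 6)
})

test_that("DOT export is deterministic and mirrors the graph", {
  rt <- stf_runtime()
  dot <- export_dot(rt)
  expect_match(dot, "digraph", fixed = TRUE)
  expect_false(grepl("->", dot, fixed = TRUE))  # no edges in an empty graph

  rt <- stf_runtime()
  demo_uncertain_chain(rt)
  dot <- export_dot(rt)
  expect_identical(dot, export_dot(rt))
  lines <- strsplit(dot, "\n")[[1]]
  n_nodes <- sum(grepl("^  t[0-9]+ \\[", lines))
  n_edges <- sum(grepl("->", lines, fixed = TRUE))
  expect_identical(n_nodes, nrow(graph_nodes(rt)))
  expect_identical(n_edges, nrow(graph_edges(rt)))
})
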