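# Canned task-graph topologies exercising the speculation construction.
# These are first-class fixtures: tests and the documentation build them
# through the public API.

#' Single-uncertain-task demonstration graph
#'
#' Four user tasks on one integer datum `x`: `A` writes, `B` maybe-writes
#' (it adds 10 when `b_writes`), `C` writes (doubles), `D` writes (adds 1).
#' The runtime expands this to 7 tasks: `A`, `copy`, `B`, `C`, `C'`,
#' `select`, `D`. Durations are configurable so the two closed-form
#' makespans of the speculative timing model can be checked on it:
#' with at least two workers, `copy + max(B + C, C')` when `B` writes and
#' `copy + max(B, C') + select` when it does not (`A` and `D` default to
#' zero cost).
#'
#' @param rt a fresh `stf_runtime`.
#' @param b_writes does the uncertain task write?
#' @param durations named vector with entries `a`, `b`, `c`, `twin`,
#'   `select_`, `d` plus `copy` applied via the runtime's `copy_duration`.
#' @return list with the handle `x` and the task refs, invisibly.
#' @export
demo_uncertain_chain <- function(rt, b_writes = TRUE,
                                 durations = c(a = 0, b = 1, c = 1, twin = 1,
                                               d = 0)) {
  x <- register_data(rt, 0L, name = "x")
  a <- insert_task(rt, list(sp_write(x)),
                   function(v) list(values = list(1L)),
                   duration = durations[["a"]], name = "A")
  b <- insert_task(rt, list(sp_maybe_write(x)), function(v) {
    if (b_writes) list(values = list(v[[1L]] + 10L), did_write = TRUE)
    else list(values = v, did_write = FALSE)
  }, duration = durations[["b"]], name = "B")
  cc <- insert_task(rt, list(sp_write(x)),
                    function(v) list(values = list(v[[1L]] * 2L)),
                    duration = durations[["c"]],
                    twin_duration = durations[["twin"]], name = "C")
  d <- insert_task(rt, list(sp_write(x)),
                   function(v) list(values = list(v[[1L]] + 1L)),
                   duration = durations[["d"]], name = "D")
  invisible(list(x = x, refs = list(a = a, b = b, c = cc, d = d)))
}

#' Shared-datum demonstration graph
#'
#' Five user tasks where the task guarded by speculation also uses a datum
#' `y` produced by an unrelated task `E`. When `C` writes `y`, the
#' speculative twin needs its own copy of `y` and an additional select;
#' when `C` only reads `y`, original and twin share it concurrently and no
#' extra copy or select is created.
#'
#' @param rt a fresh `stf_runtime`.
#' @param c_writes_y does `C` write the shared datum?
#' @param b_writes does the uncertain task write?
#' @return list with handles `x`, `y` and the task refs, invisibly.
#' @export
demo_shared_datum <- function(rt, c_writes_y = TRUE, b_writes = FALSE) {
  x <- register_data(rt, 0L, name = "x")
  y <- register_data(rt, 0L, name = "y")
  a <- insert_task(rt, list(sp_write(x)),
                   function(v) list(values = list(2L)), name = "A")
  e <- insert_task(rt, list(sp_write(y)),
                   function(v) list(values = list(5L)), name = "E")
  b <- insert_task(rt, list(sp_maybe_write(x)), function(v) {
    if (b_writes) list(values = list(v[[1L]] + 100L), did_write = TRUE)
    else list(values = v, did_write = FALSE)
  }, name = "B")
  y_acc <- if (c_writes_y) sp_write else sp_read
  cc <- insert_task(rt, list(sp_write(x), y_acc(y)), function(v) {
    out <- list(v[[1L]] + v[[2L]], if (c_writes_y) v[[2L]] + 1L else v[[2L]])
    list(values = out)
  }, name = "C")
  d <- insert_task(rt, list(sp_write(x)),
                   function(v) list(values = list(v[[1L]] * 3L)), name = "D")
  invisible(list(x = x, y = y, refs = list(a = a, e = e, b = b, c = cc,
                                           d = d)))
}

#' Non-consecutive uncertain tasks demonstration graph
#'
#' Six user tasks on one datum where two uncertain tasks are separated by a
#' certain one; the groups they open are linked, and a write by either
#' uncertain task fails the downstream speculation.
#'
#' @param rt a fresh `stf_runtime`.
#' @param b_writes,f_writes outcomes of the two uncertain tasks.
#' @return list with the handle and refs, invisibly.
#' @export
demo_nonconsecutive_uncertain <- function(rt, b_writes = FALSE,
                                          f_writes = FALSE) {
  x <- register_data(rt, 1L, name = "x")
  a <- insert_task(rt, list(sp_write(x)),
                   function(v) list(values = list(3L)), name = "A")
  b <- insert_task(rt, list(sp_maybe_write(x)), function(v) {
    if (b_writes) list(values = list(v[[1L]] + 7L), did_write = TRUE)
    else list(values = v, did_write = FALSE)
  }, name = "B")
  cc <- insert_task(rt, list(sp_write(x)),
                    function(v) list(values = list(v[[1L]] * 2L)),
                    name = "C")
  f <- insert_task(rt, list(sp_maybe_write(x)), function(v) {
    if (f_writes) list(values = list(v[[1L]] - 5L), did_write = TRUE)
    else list(values = v, did_write = FALSE)
  }, name = "F")
  g <- insert_task(rt, list(sp_write(x)),
                   function(v) list(values = list(v[[1L]] + 11L)),
                   name = "G")
  h <- insert_task(rt, list(sp_read(x)),
                   function(v) list(result = v[[1L]]), name = "H")
  invisible(list(x = x, refs = list(a = a, b = b, c = cc, f = f, g = g,
                                    h = h)))
}
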