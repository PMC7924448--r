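#' @importFrom stats runif setNames
#' @importFrom utils head tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a sequential task flow runtime
#'
#' The runtime is the central mutable object of the package. A single
#' (conceptual) thread inserts tasks with [insert_task()], declaring for each
#' task how it accesses registered data (`READ`, `WRITE` or `MAYBE_WRITE`).
#' The runtime derives the dependency DAG so that any execution -- sequential,
#' parallel worker pool, or simulated clock -- produces exactly the payloads
#' of a sequential execution of the inserted tasks.
#'
#' Tasks declaring at least one `MAYBE_WRITE` access are *uncertain*: whether
#' they wrote is only known when they complete (their body reports a
#' did-write flag). For such tasks the runtime automatically builds copy
#' tasks, speculative twins and select tasks, organised in speculative task
#' groups, so that downstream work can start before the uncertain outcome is
#' known.
#'
#' @param executor one of `"sequential"`, `"parallel"`, `"simulated"`; the
#'   engine used by [wait_all()] and friends. `"parallel"` is a deterministic
#'   logical worker pool that ignores task durations; `"simulated"` runs the
#'   same discrete-event engine using the task durations and reports an
#'   abstract-time makespan.
#' @param workers number of workers for the parallel/simulated engines.
#' @param speculation_policy function of `(n_ready, n_workers)` returning
#'   `TRUE` to enable speculation for a group. Called once per group when its
#'   first copy task becomes ready. See [policy_always_on()].
#' @param copy_duration,select_duration default abstract durations for
#'   runtime-inserted copy and select tasks (the unit-cost speedup theory
#'   assumes they are negligible, hence 0).
#' @return an object of class `stf_runtime`.
#' @examples
#' rt <- stf_runtime("sequential")
#' x <- register_data(rt, 1)
#' insert_task(rt, list(sp_write(x)), function(v) list(values = list(v[[1]] + 1)))
#' wait_all(rt)
#' data_value(x)
#' @export
stf_runtime <- function(executor = c("sequential", "parallel", "simulated"),
                        workers = 2L,
                        speculation_policy = policy_always_on(),
                        copy_duration = 0,
                        select_duration = 0) {
  executor <- match.arg(executor)
  stopifnot(is.numeric(workers), length(workers) == 1L, workers >= 1)
  rt <- new.env(parent = emptyenv())
  rt$tasks <- list()
  rt$handles <- list()
  rt$edges_from <- integer(0)
  rt$edges_to <- integer(0)
  rt$groups <- list()
  rt$registry <- new.env(parent = emptyenv()) # handle id -> duplicate entry
  rt$executor <- executor
  rt$workers <- as.integer(workers)
  rt$policy <- speculation_policy
  rt$copy_duration <- copy_duration
  rt$select_duration <- select_duration
  rt$exec <- NULL     # engine state, created lazily
  rt$log <- list()
  class(rt) <- "stf_runtime"
  rt
}

#' @export
print.stf_runtime <- function(x, ...) {
  done <- sum(vapply(x$tasks, function(t) t$state == "DONE", logical(1)))
  cat(sprintf(
    "<stf_runtime> %d task(s) (%d done), %d handle(s), %d edge(s), %d group(s), executor=%s/%d\n",
    length(x$tasks), done, length(x$handles), length(x$edges_from),
    length(x$groups), x$executor, x$workers))
  invisible(x)
}

stf_log <- function(rt, event, task = NA_integer_, info = "") {
  rt$log[[length(rt$log) + 1L]] <- list(seq = length(rt$log) + 1L,
                                        event = event, task = task, info = info)
  invisible(NULL)
}

#' Structured event log of a runtime
#'
#' One record per task-lifecycle event (insert, ready, start, end, enable,
#' disable, group decisions), in the order they happened.
#'
#' @param rt an `stf_runtime`.
#' @return a data.frame with columns `seq`, `event`, `task`, `info`.
#' @export
event_log <- function(rt) {
  stopifnot(inherits(rt, "stf_runtime"))
  if (length(rt$log) == 0L) {
    return(data.frame(seq = integer(0), event = character(0),
                      task = integer(0), info = character(0)))
  }
  data.frame(
    seq = vapply(rt$log, `[[`, integer(1), "seq"),
    event = vapply(rt$log, `[[`, character(1), "event"),
    task = vapply(rt$log, `[[`, integer(1), "task"),
    info = vapply(rt$log, `[[`, character(1), "info"),
    stringsAsFactors = FALSE)
}

check_copyable <- function(x) {
  bad <- function(v) {
    is.environment(v) || inherits(v, "connection") ||
      typeof(v) %in% c("externalptr", "closure", "special", "builtin")
  }
  if (bad(x)) return(FALSE)
  if (is.list(x)) return(all(vapply(x, check_copyable, logical(1))))
  TRUE
}

#' Register a datum with the runtime
#'
#' Payloads follow a value-semantics contract: they must be deep-copyable
#' and comparable with [identical()]. Copy tasks duplicate payloads by plain
#' R value assignment, so reference-semantics objects (environments,
#' connections, external pointers) are rejected.
#'
#' @param rt an `stf_runtime`.
#' @param payload any copyable R value.
#' @param name optional label used in DOT exports.
#' @return an `stf_handle`.
#' @export
register_data <- function(rt, payload, name = NULL) {
  stopifnot(inherits(rt, "stf_runtime"))
  if (!check_copyable(payload)) {
    stop("payload must be copyable by value (no environments, connections or pointers)",
         call. = FALSE)
  }
  new_handle(rt, payload, name = name, internal = FALSE)
}

new_handle <- function(rt, payload, name = NULL, internal = TRUE) {
  h <- new.env(parent = emptyenv())
  h$id <- length(rt$handles) + 1L
  h$name <- name %||% paste0(if (internal) "dup" else "data", h$id)
  h$payload <- payload
  h$last_writer <- NA_integer_
  h$readers <- integer(0)   # readers since last write
  h$internal <- internal
  class(h) <- "stf_handle"
  rt$handles[[h$id]] <- h
  h
}

#' @export
print.stf_handle <- function(x, ...) {
  cat(sprintf("<stf_handle #%d '%s'>\n", x$id, x$name))
  invisible(x)
}

#' Current payload of a data handle
#' @param h an `stf_handle` returned by [register_data()].
#' @return the payload value.
#' @export
data_value <- function(h) {
  stopifnot(inherits(h, "stf_handle"))
  h$payload
}

## ---- access modes -----------------------------------------------------------

make_access <- function(h, mode) {
  stopifnot(inherits(h, "stf_handle"))
  structure(list(handle = h, mode = mode), class = "stf_access")
}

#' Declare how a task accesses a datum
#'
#' `sp_read()` declares read-only access, `sp_write()` a certain write and
#' `sp_maybe_write()` a potential write. A task with at least one
#' `MAYBE_WRITE` access is *uncertain* and its body must report, on
#' completion, whether it actually wrote (`did_write`). For dependency
#' computation a `MAYBE_WRITE` is ordered exactly like a `WRITE`
#' (conservative order), which is what makes the sequential result the
#' reference.
#'
#' @param h an `stf_handle`.
#' @return an access descriptor to pass to [insert_task()].
#' @export
sp_read <- function(h) make_access(h, "READ")

#' @rdname sp_read
#' @export
sp_write <- function(h) make_access(h, "WRITE")

#' @rdname sp_read
#' @export
sp_maybe_write <- function(h) make_access(h, "MAYBE_WRITE")

## ---- task creation ----------------------------------------------------------

new_task <- function(rt, accesses, body, duration, role = "task",
                     uncertain = FALSE, speculative = FALSE, name = NULL,
                     group = NULL, origin = NA_integer_) {
  t <- new.env(parent = emptyenv())
  t$id <- NA_integer_   # assigned when the task enters the graph
  t$name <- name
  t$accesses <- accesses
  t$body <- body
  t$duration <- duration
  t$role <- role             # "task", "copy", "select"
  t$uncertain <- uncertain
  t$speculative <- speculative
  t$origin <- origin         # original task id for a speculative twin
  t$state <- "INSERTED"      # INSERTED -> READY -> RUNNING -> DONE
  t$activation <- "ENABLED"
  t$held <- FALSE            # fate undecided: must not be scheduled yet
  t$started <- FALSE
  t$did_write <- NA
  t$result <- NULL
  t$group <- group
  t$start <- NA_real_
  t$end <- NA_real_
  t$worker <- NA_integer_
  class(t) <- "stf_task"
  t
}

#' @export
print.stf_task <- function(x, ...) {
  cat(sprintf("<stf_task #%d '%s' role=%s state=%s activation=%s%s%s>\n",
              x$id, x$name, x$role, x$state, x$activation,
              if (x$uncertain) " uncertain" else "",
              if (x$speculative) " speculative" else ""))
  invisible(x)
}

add_edge <- function(rt, from, to) {
  if (from == to) return(invisible(NULL))
  sel <- rt$edges_from == from & rt$edges_to == to
  if (!any(sel)) {  # duplicate edges are collapsed
    rt$edges_from <- c(rt$edges_from, from)
    rt$edges_to <- c(rt$edges_to, to)
    t_from <- rt$tasks[[from]]
    t_to <- rt$tasks[[to]]
    t_from$succs <- c(t_from$succs, to)
    t_to$preds <- c(t_to$preds, from)
  }
  invisible(NULL)
}

# Standard STF dependency computation: a READ depends on the last writer of
# the datum; a WRITE/MAYBE_WRITE depends on the last writer and on every
# reader since that write (RAW, WAR, WAW ordering). Handle histories are
# updated as a side effect; a MAYBE_WRITE records the task as writer.
internal_insert <- function(rt, t) {
  t$id <- length(rt$tasks) + 1L
  t$name <- t$name %||% paste0("T", t$id)
  t$preds <- integer(0)
  t$succs <- integer(0)
  rt$tasks[[t$id]] <- t
  for (acc in t$accesses) {
    h <- acc$handle
    if (acc$mode == "READ") {
      if (!is.na(h$last_writer)) add_edge(rt, h$last_writer, t$id)
      h$readers <- union(h$readers, t$id)
    } else {
      if (!is.na(h$last_writer)) add_edge(rt, h$last_writer, t$id)
      for (r in h$readers) add_edge(rt, r, t$id)
      h$last_writer <- t$id
      h$readers <- integer(0)
    }
  }
  stf_log(rt, "insert", t$id, t$role)
  t
}

validate_accesses <- function(accesses) {
  if (!is.list(accesses) ||
      !all(vapply(accesses, inherits, logical(1), "stf_access"))) {
    stop("'accesses' must be a list of sp_read()/sp_write()/sp_maybe_write()",
         call. = FALSE)
  }
  ids <- vapply(accesses, function(a) a$handle$id, integer(1))
  if (anyDuplicated(ids)) {
    stop("a task may access each handle at most once", call. = FALSE)
  }
  invisible(NULL)
}

#' Insert a task into the flow
#'
#' Dependencies on previously inserted tasks are derived from the access
#' declarations. If the task is uncertain (has a `MAYBE_WRITE` access, or
#' `uncertain = TRUE`), the speculative machinery takes over: copy tasks,
#' a speculative twin and select tasks may be created around it. If the task
#' is certain but touches currently duplicated data, it is guarded the same
#' way (a twin running on the duplicates).
#'
#' The body receives `values`, the list of payloads of the accessed handles
#' in declaration order, and must return a list with:
#' \describe{
#'   \item{`values`}{full-length list of payloads; entries at `WRITE` /
#'     `MAYBE_WRITE` positions replace the handle payloads (pass the inputs
#'     through unchanged where nothing was written). `NULL` is allowed for a
#'     read-only task.}
#'   \item{`did_write`}{mandatory logical flag for uncertain tasks: did the
#'     task actually modify any maybe-written datum?}
#'   \item{`result`}{optional value retrievable with [task_result()].}
#' }
#' Bodies must be pure functions of their access payloads (any randomness
#' must come from an explicit RNG-state datum in the access list), so that a
#' speculative twin running on duplicated payloads computes bit-identical
#' values.
#'
#' @param rt an `stf_runtime`.
#' @param accesses list of access descriptors ([sp_read()] etc.).
#' @param body task body, `function(values)`.
#' @param duration nonnegative abstract cost used by the simulated executor.
#' @param uncertain logical; defaults to "has a MAYBE_WRITE access". Stating
#'   `FALSE` for a task with a MAYBE_WRITE access is an error.
#' @param twin_duration duration of the speculative twin, if one is created
#'   (defaults to `duration`).
#' @param name optional label.
#' @return an `stf_task_ref` usable with [task_wait()], [task_result()],
#'   [task_state()].
#' @export
insert_task <- function(rt, accesses, body, duration = 1,
                        uncertain = NULL, twin_duration = NULL, name = NULL) {
  stopifnot(inherits(rt, "stf_runtime"), is.function(body))
  validate_accesses(accesses)
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration < 0) {
    stop("'duration' must be a nonnegative number", call. = FALSE)
  }
  has_mw <- any(vapply(accesses, function(a) a$mode == "MAYBE_WRITE", logical(1)))
  if (is.null(uncertain)) uncertain <- has_mw
  if (has_mw && !uncertain) {
    stop("a task with a MAYBE_WRITE access is uncertain by definition",
         call. = FALSE)
  }
  if (uncertain && !has_mw) {
    stop("an uncertain task must declare at least one MAYBE_WRITE access",
         call. = FALSE)
  }
  t <- new_task(rt, accesses, body, duration, uncertain = uncertain,
                name = name)
  t$twin_duration <- twin_duration %||% duration
  if (uncertain) {
    insert_uncertain_task(rt, t)
  } else {
    insert_guarded_normal_task(rt, t)
  }
  structure(list(rt = rt, id = t$id), class = "stf_task_ref")
}

#' @export
print.stf_task_ref <- function(x, ...) {
  print(x$rt$tasks[[x$id]])
  invisible(x)
}

#' Inspect a task reference
#' @param ref an `stf_task_ref` from [insert_task()].
#' @return `task_state()` returns the lifecycle state, `task_result()` the
#'   value of the body's `result` element (for uncertain tasks, `NULL`
#'   results fall back to the did-write flag, mirroring a boolean-returning
#'   task body).
#' @export
task_state <- function(ref) {
  stopifnot(inherits(ref, "stf_task_ref"))
  ref$rt$tasks[[ref$id]]$state
}

#' @rdname task_state
#' @export
task_result <- function(ref) {
  stopifnot(inherits(ref, "stf_task_ref"))
  t <- ref$rt$tasks[[ref$id]]
  t$result %||% (if (t$uncertain) t$did_write else NULL)
}

## ---- graph accessors --------------------------------------------------------

#' Task graph as tables
#'
#' @param rt an `stf_runtime`.
#' @return `graph_nodes()`: one row per task (id, name, role, flags, state,
#'   activation, duration, group). `graph_edges()`: dependency pairs
#'   `(from, to)`; every edge goes from a lower to a higher insertion index,
#'   so insertion order is a topological order.
#' @export
graph_nodes <- function(rt) {
  stopifnot(inherits(rt, "stf_runtime"))
  data.frame(
    id = vapply(rt$tasks, `[[`, integer(1), "id"),
    name = vapply(rt$tasks, `[[`, character(1), "name"),
    role = vapply(rt$tasks, `[[`, character(1), "role"),
    uncertain = vapply(rt$tasks, `[[`, logical(1), "uncertain"),
    speculative = vapply(rt$tasks, `[[`, logical(1), "speculative"),
    state = vapply(rt$tasks, `[[`, character(1), "state"),
    activation = vapply(rt$tasks, `[[`, character(1), "activation"),
    duration = vapply(rt$tasks, `[[`, numeric(1), "duration"),
    group = vapply(rt$tasks, function(t) {
      if (is.null(t$group)) NA_integer_ else t$group$id
    }, integer(1)),
    stringsAsFactors = FALSE)
}

#' @rdname graph_nodes
#' @export
graph_edges <- function(rt) {
  stopifnot(inherits(rt, "stf_runtime"))
  data.frame(from = rt$edges_from, to = rt$edges_to)
}
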