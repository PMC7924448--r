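# Three interchangeable execution engines over the same task graph:
#   * sequential reference: enabled tasks in insertion order, one worker;
#   * parallel: a deterministic logical worker pool (FIFO ready queue,
#     completion-event order; durations ignored, every task one tick);
#   * simulated: the same list-scheduling discrete-event engine driven by
#     the task durations, yielding a hardware-independent makespan.
# All three execute task bodies for real, so uncertain outcomes and group
# activations are genuine, and all three end with identical payloads.
#
# Scheduling is greedy list scheduling: a ready task goes to the
# earliest-free worker; ties are broken FIFO by insertion index.  At a given
# clock value all completion events are processed (in insertion-index order)
# before any new task starts, so a twin whose cancellation arrives exactly
# at its would-be start time is cancelled, while one that started earlier
# runs to completion ("too late" cancellation is tolerated by design).

run_body <- function(rt, t) {
  if (t$role %in% c("copy", "select")) {
    t$copy_dst$payload <- t$copy_src$payload
    return(invisible(NULL))
  }
  vals <- lapply(t$accesses, function(a) a$handle$payload)
  res <- t$body(vals)
  if (!is.list(res)) {
    stop(sprintf("task %d ('%s'): body must return a list", t$id, t$name),
         call. = FALSE)
  }
  if (t$uncertain) {
    dw <- res$did_write
    if (!is.logical(dw) || length(dw) != 1L || is.na(dw)) {
      stop(sprintf("task %d ('%s'): uncertain body must return did_write = TRUE/FALSE",
                   t$id, t$name), call. = FALSE)
    }
    t$did_write <- dw
  }
  vv <- res$values
  if (!is.null(vv)) {
    if (length(vv) != length(t$accesses)) {
      stop(sprintf("task %d ('%s'): 'values' must have one entry per access",
                   t$id, t$name), call. = FALSE)
    }
    for (i in seq_along(t$accesses)) {
      if (t$accesses[[i]]$mode != "READ") {
        t$accesses[[i]]$handle$payload <- vv[[i]]
      }
    }
  }
  t$result <- res$result
  invisible(NULL)
}

start_task <- function(rt, t, time, worker) {
  t$state <- "RUNNING"
  t$started <- TRUE
  t$start <- time
  t$worker <- worker
  stf_log(rt, "start", t$id, t$activation)
  if (t$activation == "ENABLED") run_body(rt, t)
  invisible(NULL)
}

finish_task <- function(rt, t, time) {
  t$state <- "DONE"
  t$end <- time
  stf_log(rt, "end", t$id)
  on_task_complete(rt, t)
  invisible(NULL)
}

## ---- engine state -----------------------------------------------------------

exec_init <- function(rt) {
  if (!is.null(rt$exec)) return(rt$exec)
  ex <- new.env(parent = emptyenv())
  ex$mode <- rt$executor
  ex$unit_cost <- identical(rt$executor, "parallel")
  ex$workers <- if (identical(rt$executor, "sequential")) 1L else rt$workers
  ex$clock <- 0
  ex$seq_idx <- 1L
  ex$predrem <- integer(0)
  ex$ready <- integer(0)     # pred-free, fate decided
  ex$waiting <- integer(0)   # pred-free, held
  ex$ev_time <- numeric(0)   # scheduled end events
  ex$ev_id <- integer(0)
  ex$busy_until <- rep(0, ex$workers)
  ex$busy <- rep(FALSE, ex$workers)
  ex$n_done <- 0L
  ex$seen <- 0L
  ex$finished <- FALSE
  rt$exec <- ex
  ex
}

absorb_new_tasks <- function(rt) {
  ex <- rt$exec
  n <- length(rt$tasks)
  if (ex$seen >= n) return(invisible(NULL))
  ex$finished <- FALSE
  for (i in (ex$seen + 1L):n) {
    t <- rt$tasks[[i]]
    done_preds <- sum(vapply(t$preds, function(p) {
      rt$tasks[[p]]$state == "DONE"
    }, logical(1)))
    ex$predrem[i] <- length(t$preds) - done_preds
    if (ex$predrem[i] == 0L) push_ready(rt, t)
  }
  ex$seen <- n
  invisible(NULL)
}

push_ready <- function(rt, t) {
  ex <- rt$exec
  if (t$held) {
    ex$waiting <- c(ex$waiting, t$id)
    return(invisible(NULL))
  }
  if (t$role == "copy" && !is.null(t$group) &&
      t$group$policy_state == "UNDEFINED") {
    decide_speculation(rt, t$group, n_ready = length(ex$ready) + 1L)
  }
  t$state <- "READY"
  stf_log(rt, "ready", t$id)
  ex$ready <- c(ex$ready, t$id)
  invisible(NULL)
}

exec_notify_release <- function(rt, t) {
  ex <- rt$exec
  if (is.null(ex)) return(invisible(NULL))
  if (t$id %in% ex$waiting) {
    ex$waiting <- setdiff(ex$waiting, t$id)
    push_ready(rt, t)
  }
  invisible(NULL)
}

task_completed_bookkeeping <- function(rt, t, time) {
  ex <- rt$exec
  finish_task(rt, t, time)
  ex$n_done <- ex$n_done + 1L
  for (s in t$succs) {
    ex$predrem[s] <- ex$predrem[s] - 1L
    if (ex$predrem[s] == 0L) {
      st <- rt$tasks[[s]]
      if (st$state == "INSERTED") push_ready(rt, st)
    }
  }
  invisible(NULL)
}

effective_duration <- function(ex, t) {
  if (t$activation == "DISABLED") return(0)
  if (ex$unit_cost) return(1)
  t$duration
}

## ---- sequential reference ---------------------------------------------------

run_loop_sequential <- function(rt, stop_fn) {
  ex <- rt$exec
  absorb_new_tasks(rt)
  while (ex$seq_idx <= length(rt$tasks)) {
    if (stop_fn(rt)) return(invisible(NULL))
    t <- rt$tasks[[ex$seq_idx]]
    if (t$state == "DONE") { ex$seq_idx <- ex$seq_idx + 1L; next }
    if (t$held) {
      stop(sprintf("internal error: task %d still undecided in sequential run",
                   t$id), call. = FALSE)
    }
    if (t$role == "copy" && !is.null(t$group) &&
        t$group$policy_state == "UNDEFINED") {
      decide_speculation(rt, t$group, n_ready = 1L)
    }
    dur <- if (t$activation == "DISABLED") 0 else t$duration
    start_task(rt, t, ex$clock, 1L)
    ex$clock <- ex$clock + dur
    finish_task(rt, t, ex$clock)
    ex$n_done <- ex$n_done + 1L
    ex$seq_idx <- ex$seq_idx + 1L
  }
  ex$finished <- TRUE
  invisible(NULL)
}

## ---- discrete-event engine --------------------------------------------------

run_loop_engine <- function(rt, stop_fn) {
  ex <- rt$exec
  absorb_new_tasks(rt)
  repeat {
    if (stop_fn(rt)) return(invisible(NULL))
    # 1. completions due at the current clock come first (insertion-index
    #    order), so outcome callbacks can still cancel unstarted tasks that
    #    would otherwise start at this very instant
    due <- which(ex$ev_time <= ex$clock)
    if (length(due) > 0L) {
      ids <- sort(ex$ev_id[due])
      keep <- setdiff(seq_along(ex$ev_id), due)
      ex$ev_time <- ex$ev_time[keep]
      ex$ev_id <- ex$ev_id[keep]
      for (tid in ids) {
        t <- rt$tasks[[tid]]
        ex$busy[t$worker] <- FALSE
        task_completed_bookkeeping(rt, t, ex$clock)
      }
      next
    }
    # 2. start one ready task on the lowest free worker (FIFO by id)
    free <- which(!ex$busy)
    if (length(free) > 0L && length(ex$ready) > 0L) {
      tid <- min(ex$ready)
      ex$ready <- setdiff(ex$ready, tid)
      t <- rt$tasks[[tid]]
      w <- free[1L]
      dur <- effective_duration(ex, t)
      start_task(rt, t, ex$clock, w)
      ex$busy[w] <- TRUE
      ex$busy_until[w] <- ex$clock + dur
      ex$ev_time <- c(ex$ev_time, ex$clock + dur)
      ex$ev_id <- c(ex$ev_id, tid)
      next
    }
    # 3. advance the clock to the next completion
    if (length(ex$ev_id) == 0L) {
      if (ex$n_done == length(rt$tasks)) {
        ex$finished <- TRUE
        return(invisible(NULL))
      }
      stop("internal error: no runnable task but graph not finished (deadlock?)",
           call. = FALSE)
    }
    ex$clock <- min(ex$ev_time)
  }
}

run_loop <- function(rt, stop_fn) {
  ex <- exec_init(rt)
  if (ex$mode == "sequential") run_loop_sequential(rt, stop_fn)
  else run_loop_engine(rt, stop_fn)
  invisible(NULL)
}

## ---- user-facing waits ------------------------------------------------------

#' Wait for tasks to complete
#'
#' `wait_all()` runs the runtime's attached executor until every task is
#' done. `wait_remain(rt, n)` runs until at most `n` tasks are not done.
#' `task_wait(ref)` runs until the referenced task is done and returns its
#' result.
#'
#' @param rt an `stf_runtime`.
#' @param n maximum number of unfinished tasks allowed on return (>= 0).
#' @param ref an `stf_task_ref`.
#' @return `wait_all()` and `wait_remain()` return the runtime invisibly;
#'   `task_wait()` returns the task result (see [task_result()]).
#' @export
wait_all <- function(rt) {
  stopifnot(inherits(rt, "stf_runtime"))
  run_loop(rt, function(rt) FALSE)
  invisible(rt)
}

#' @rdname wait_all
#' @export
wait_remain <- function(rt, n) {
  stopifnot(inherits(rt, "stf_runtime"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    stop("'n' must be a nonnegative count", call. = FALSE)
  }
  run_loop(rt, function(rt) {
    length(rt$tasks) - rt$exec$n_done <= n
  })
  invisible(rt)
}

#' @rdname wait_all
#' @export
task_wait <- function(ref) {
  stopifnot(inherits(ref, "stf_task_ref"))
  rt <- ref$rt
  run_loop(rt, function(rt) rt$tasks[[ref$id]]$state == "DONE")
  task_result(ref)
}

## ---- whole-graph runners ----------------------------------------------------

configure_executor <- function(rt, executor, workers = NULL) {
  if (!is.null(rt$exec)) {
    stop("this runtime has already started executing; build a fresh graph to re-run",
         call. = FALSE)
  }
  rt$executor <- executor
  if (!is.null(workers)) {
    stopifnot(is.numeric(workers), length(workers) == 1L, workers >= 1)
    rt$workers <- as.integer(workers)
  }
  invisible(rt)
}

#' Execute the whole task graph
#'
#' `run_sequential()` is the ground-truth reference: enabled tasks run in
#' insertion order on one worker (uncertain outcomes still drive group
#' activation). `run_parallel()` runs a deterministic logical worker pool
#' (durations ignored). `run_simulated()` runs the discrete-event engine on
#' the task durations and reports the abstract-time makespan. All three
#' leave identical payloads in the data handles.
#'
#' @param rt an `stf_runtime` that has not started executing yet.
#' @param workers worker count for the parallel/simulated engines.
#' @return an `stf_run_trace` (see [run_trace()]), invisibly.
#' @export
run_sequential <- function(rt) {
  configure_executor(rt, "sequential")
  wait_all(rt)
  invisible(run_trace(rt))
}

#' @rdname run_sequential
#' @export
run_parallel <- function(rt, workers = rt$workers) {
  configure_executor(rt, "parallel", workers)
  wait_all(rt)
  invisible(run_trace(rt))
}

#' @rdname run_sequential
#' @export
run_simulated <- function(rt, workers = rt$workers) {
  configure_executor(rt, "simulated", workers)
  wait_all(rt)
  invisible(run_trace(rt))
}

## ---- traces -----------------------------------------------------------------

#' Execution trace of a runtime
#'
#' One record per task with worker assignment and start/end times in
#' abstract units, plus the final activation, the group id and group state.
#'
#' @param rt an `stf_runtime`.
#' @return an object of class `stf_run_trace`: list with `records`
#'   (data.frame) and `makespan`.
#' @export
run_trace <- function(rt) {
  stopifnot(inherits(rt, "stf_runtime"))
  nodes <- graph_nodes(rt)
  rec <- cbind(nodes, data.frame(
    worker = vapply(rt$tasks, `[[`, integer(1), "worker"),
    start = vapply(rt$tasks, `[[`, numeric(1), "start"),
    end = vapply(rt$tasks, `[[`, numeric(1), "end"),
    did_write = vapply(rt$tasks, function(t) as.logical(t$did_write),
                       logical(1)),
    group_state = vapply(rt$tasks, function(t) {
      if (is.null(t$group)) NA_character_ else t$group$policy_state
    }, character(1)),
    group_failed = vapply(rt$tasks, function(t) {
      if (is.null(t$group)) NA else t$group$failed
    }, logical(1))))
  structure(list(records = rec, makespan = makespan(rt)),
            class = "stf_run_trace")
}

#' @export
print.stf_run_trace <- function(x, ...) {
  cat(sprintf("<stf_run_trace> %d record(s), makespan %g\n",
              nrow(x$records), x$makespan))
  invisible(x)
}

#' Makespan of an executed graph
#'
#' Total completion time in abstract units (0 for an empty or unexecuted
#' graph).
#'
#' @param x an `stf_runtime` or `stf_run_trace`.
#' @return a number.
#' @export
makespan <- function(x) {
  if (inherits(x, "stf_run_trace")) return(x$makespan)
  stopifnot(inherits(x, "stf_runtime"))
  ends <- vapply(x$tasks, `[[`, numeric(1), "end")
  ends <- ends[!is.na(ends)]
  if (length(ends) == 0L) 0 else max(ends)
}
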