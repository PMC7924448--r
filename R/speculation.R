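# Speculative machinery: duplicate registry, copy/speculative/select task
# construction at insertion time, speculative task groups (STGs) and the
# runtime enable/disable propagation once uncertain outcomes become known.
#
# The model: each uncertain (or guarded certain) task inserted on currently
# speculated data opens a new group linked to the groups owning those
# duplicates.  A group holds the copy tasks made for it, the original task,
# its speculative twin running on duplicated payloads, and the select tasks
# that overwrite originals with the duplicates when the speculation holds.
# Outcomes flow along parent -> child links: a child group's twin is valid
# exactly when every parent level reported "did not write".  One write
# anywhere invalidates every downstream group (predictive speculation: no
# restart after a failure).

new_group <- function(rt, parents = list(), root = FALSE) {
  g <- new.env(parent = emptyenv())
  g$id <- length(rt$groups) + 1L
  g$root <- root
  g$parents <- parents
  g$children <- list()
  g$main <- NULL          # original task of this level
  g$twins <- list()
  g$originals <- list()
  g$copies <- list()
  g$selects <- list()
  g$policy_state <- "UNDEFINED"    # UNDEFINED / ENABLED / DISABLED
  g$validity <- if (root) "VALID" else "PENDING"
  g$pending_parents <- 0L
  g$outcome <- "pending"           # pending / success / fail
  g$failed <- FALSE                # >= 1 uncertain task of the chain wrote
  g$dead <- FALSE                  # disabled or failed: no further speculation
  class(g) <- "stf_group"
  rt$groups[[g$id]] <- g
  g
}

#' @export
print.stf_group <- function(x, ...) {
  cat(sprintf("<stf_group #%d %s/%s outcome=%s%s>\n", x$id, x$policy_state,
              x$validity, x$outcome, if (x$failed) " failed" else ""))
  invisible(x)
}

#' Speculative task groups of a runtime
#'
#' @param rt an `stf_runtime`.
#' @return data.frame with one row per group: policy state
#'   (UNDEFINED/ENABLED/DISABLED), validity of its speculative path, chain
#'   outcome, failure flag and task counts.
#' @export
group_table <- function(rt) {
  stopifnot(inherits(rt, "stf_runtime"))
  gs <- rt$groups
  data.frame(
    id = vapply(gs, `[[`, integer(1), "id"),
    root = vapply(gs, `[[`, logical(1), "root"),
    policy = vapply(gs, `[[`, character(1), "policy_state"),
    validity = vapply(gs, `[[`, character(1), "validity"),
    outcome = vapply(gs, `[[`, character(1), "outcome"),
    failed = vapply(gs, `[[`, logical(1), "failed"),
    n_copies = vapply(gs, function(g) length(g$copies), integer(1)),
    n_twins = vapply(gs, function(g) length(g$twins), integer(1)),
    n_selects = vapply(gs, function(g) length(g$selects), integer(1)),
    stringsAsFactors = FALSE)
}

## ---- duplicate registry -----------------------------------------------------

reg_key <- function(h) as.character(h$id)

reg_get <- function(rt, h) {
  k <- reg_key(h)
  if (exists(k, envir = rt$registry, inherits = FALSE)) {
    get(k, envir = rt$registry)
  } else NULL
}

reg_put <- function(rt, h, dup, group) {
  # at most one live duplicate per original handle
  assign(reg_key(h), list(orig = h, dup = dup, group = group,
                          read_used = FALSE, nonread_used = FALSE),
         envir = rt$registry)
}

reg_remove <- function(rt, h) {
  k <- reg_key(h)
  if (exists(k, envir = rt$registry, inherits = FALSE)) {
    rm(list = k, envir = rt$registry)
  }
}

reg_mark <- function(rt, h, mode) {
  k <- reg_key(h)
  if (exists(k, envir = rt$registry, inherits = FALSE)) {
    e <- get(k, envir = rt$registry)
    if (mode == "READ") e$read_used <- TRUE else e$nonread_used <- TRUE
    assign(k, e, envir = rt$registry)
  }
}

# Drop registry entries whose duplicate has so far only been consumed in READ
# mode by speculative twins, when the incoming task accesses the original in
# a non-READ mode (the clean copy would go stale for later readers).
clean_read_duplicates <- function(rt, t) {
  for (acc in t$accesses) {
    if (acc$mode == "READ") next
    e <- reg_get(rt, acc$handle)
    if (!is.null(e) && e$read_used && !e$nonread_used) {
      reg_remove(rt, acc$handle)
    }
  }
}

related_groups <- function(rt, t) {
  out <- list()
  seen <- integer(0)
  for (acc in t$accesses) {
    e <- reg_get(rt, acc$handle)
    if (!is.null(e) && !(e$group$id %in% seen)) {
      seen <- c(seen, e$group$id)
      out[[length(out) + 1L]] <- e$group
    }
  }
  out
}

remove_duplicates_of <- function(rt, t) {
  for (acc in t$accesses) reg_remove(rt, acc$handle)
}

## ---- runtime-built tasks ----------------------------------------------------

insert_copy_task <- function(rt, src, group, label) {
  dst <- new_handle(rt, NULL, name = paste0(label, "'"))
  t <- new_task(rt, list(sp_read(src), sp_write(dst)), body = NULL,
                duration = rt$copy_duration, role = "copy", group = group,
                name = paste0("copy(", label, ")"))
  t$copy_src <- src
  t$copy_dst <- dst
  internal_insert(rt, t)
  group$copies[[length(group$copies) + 1L]] <- t
  list(task = t, dup = dst)
}

# A select is a switch: when enabled it overwrites the original payload with
# the duplicate payload (x = x'); disabled it is a no-op.  Its dependencies
# (producing twin, last writer of the original) fall out of the access modes.
insert_select_task <- function(rt, orig, dup, group) {
  t <- new_task(rt, list(sp_read(dup), sp_write(orig)), body = NULL,
                duration = rt$select_duration, role = "select", group = group,
                name = paste0("select(", orig$name, ")"))
  t$copy_src <- dup
  t$copy_dst <- orig
  t$held <- TRUE
  internal_insert(rt, t)
  group$selects[[length(group$selects) + 1L]] <- t
  t
}

## ---- insertion algorithms ---------------------------------------------------

# Uncertain task insertion.  Two branches: if no related live group exists
# (or one is dead), start a fresh speculation chain -- clean duplicates,
# insert t plainly, and register clean pre-task copies of its maybe-written
# data for the benefit of the *next* task.  Otherwise extend the chain:
# build write-target duplicates for the twin, fresh clean duplicates for the
# next level, insert t both as the original and as a speculative twin on the
# duplicates, and append one select per maybe-written datum.
insert_uncertain_task <- function(rt, t) {
  clean_read_duplicates(rt, t)
  groups <- related_groups(rt, t)
  mw <- Filter(function(a) a$mode == "MAYBE_WRITE", t$accesses)
  if (length(groups) == 0L || any(vapply(groups, `[[`, logical(1), "dead"))) {
    remove_duplicates_of(rt, t)
    g <- new_group(rt, root = TRUE)
    for (acc in mw) {
      cp <- insert_copy_task(rt, acc$handle, g, acc$handle$name)
      reg_put(rt, acc$handle, cp$dup, g)
    }
    g$main <- t
    t$group <- g
    internal_insert(rt, t)
  } else {
    g <- new_group(rt, parents = groups)
    link_parents(rt, g)
    twin_map <- list()   # handle id -> handle the twin uses instead
    next_heads <- list() # original handle -> clean duplicate for next level
    selects <- list()
    for (acc in mw) {
      e <- reg_get(rt, acc$handle)
      src <- if (is.null(e)) acc$handle else e$dup
      wcp <- insert_copy_task(rt, src, g, acc$handle$name)   # twin write target
      ccp <- insert_copy_task(rt, src, g, acc$handle$name)   # clean, next level
      twin_map[[reg_key(acc$handle)]] <- wcp$dup
      next_heads[[length(next_heads) + 1L]] <- list(orig = acc$handle,
                                                    dup = ccp$dup)
      selects[[length(selects) + 1L]] <- list(orig = acc$handle,
                                              dup = wcp$dup)
    }
    consumed <- list()
    for (acc in t$accesses) {
      if (acc$mode == "MAYBE_WRITE") next
      e <- reg_get(rt, acc$handle)
      if (acc$mode == "WRITE") {
        # certain writes of an uncertain task: twin writes a duplicate too
        if (!is.null(e)) {
          twin_map[[reg_key(acc$handle)]] <- e$dup
          selects[[length(selects) + 1L]] <- list(orig = acc$handle,
                                                  dup = e$dup)
          consumed[[length(consumed) + 1L]] <- acc$handle
        } else {
          cp <- insert_copy_task(rt, acc$handle, g, acc$handle$name)
          twin_map[[reg_key(acc$handle)]] <- cp$dup
          selects[[length(selects) + 1L]] <- list(orig = acc$handle,
                                                  dup = cp$dup)
        }
      } else if (!is.null(e)) {
        twin_map[[reg_key(acc$handle)]] <- e$dup
        reg_mark(rt, acc$handle, acc$mode)
      }
    }
    g$main <- t
    t$group <- g
    g$originals[[length(g$originals) + 1L]] <- t
    t$held <- TRUE
    internal_insert(rt, t)
    insert_twin(rt, t, twin_map, g)
    for (s in selects) insert_select_task(rt, s$orig, s$dup, g)
    for (h in consumed) reg_remove(rt, h)
    for (nh in next_heads) {
      reg_remove(rt, nh$orig)
      reg_put(rt, nh$orig, nh$dup, g)
    }
  }
  g
}

# Certain task insertion on possibly speculated data.  Plain insertion when
# none of its data is duplicated or the speculation is already known dead.
# Otherwise the task gets a speculative twin: the twin writes the existing
# duplicates (or fresh copies for written data never duplicated) and reads
# duplicates where available; selects bring the duplicate values back.  The
# duplicates consumed by the selects are removed from the registry, so a
# certain write acts as a speculation barrier for the data it writes.
insert_guarded_normal_task <- function(rt, t) {
  clean_read_duplicates(rt, t)
  dup_accs <- Filter(function(a) !is.null(reg_get(rt, a$handle)), t$accesses)
  if (length(dup_accs) == 0L) {
    internal_insert(rt, t)
    return(invisible(NULL))
  }
  groups <- related_groups(rt, t)
  if (any(vapply(groups, `[[`, logical(1), "dead"))) {
    remove_duplicates_of(rt, t)
    internal_insert(rt, t)
    return(invisible(NULL))
  }
  g <- new_group(rt, parents = groups)
  link_parents(rt, g)
  twin_map <- list()
  selects <- list()
  consumed <- list()
  for (acc in t$accesses) {
    e <- reg_get(rt, acc$handle)
    if (acc$mode == "WRITE") {
      if (!is.null(e)) {
        twin_map[[reg_key(acc$handle)]] <- e$dup
        selects[[length(selects) + 1L]] <- list(orig = acc$handle, dup = e$dup)
        consumed[[length(consumed) + 1L]] <- acc$handle
      } else {
        cp <- insert_copy_task(rt, acc$handle, g, acc$handle$name)
        twin_map[[reg_key(acc$handle)]] <- cp$dup
        selects[[length(selects) + 1L]] <- list(orig = acc$handle, dup = cp$dup)
      }
    } else if (!is.null(e)) {
      twin_map[[reg_key(acc$handle)]] <- e$dup
      reg_mark(rt, acc$handle, acc$mode)
    }
  }
  g$main <- t
  t$group <- g
  g$originals[[length(g$originals) + 1L]] <- t
  t$held <- TRUE
  internal_insert(rt, t)
  insert_twin(rt, t, twin_map, g)
  for (s in selects) insert_select_task(rt, s$orig, s$dup, g)
  for (h in consumed) reg_remove(rt, h)
  invisible(g)
}

insert_twin <- function(rt, t, twin_map, g) {
  accs <- lapply(t$accesses, function(acc) {
    rep_h <- twin_map[[reg_key(acc$handle)]]
    if (is.null(rep_h)) acc else make_access(rep_h, acc$mode)
  })
  tw <- new_task(rt, accs, t$body, duration = t$twin_duration %||% t$duration,
                 uncertain = t$uncertain, speculative = TRUE, group = g,
                 name = paste0(t$name, "'"), origin = t$id)
  internal_insert(rt, tw)
  g$twins[[length(g$twins) + 1L]] <- tw
  tw
}

## ---- outcome propagation ----------------------------------------------------

link_parents <- function(rt, g) {
  g$pending_parents <- length(g$parents)
  for (p in g$parents) {
    p$children[[length(p$children) + 1L]] <- g
    if (p$outcome == "success") {
      g$pending_parents <- g$pending_parents - 1L
    } else if (p$outcome == "fail") {
      # parent already failed before this group was built; the insertion
      # branches normally catch this via `dead`, but guard anyway
      set_invalid(rt, g)
      return(invisible(NULL))
    }
  }
  if (g$pending_parents == 0L && g$validity == "PENDING") set_valid(rt, g)
  invisible(NULL)
}

disable_best_effort <- function(rt, t) {
  # Cancelling never blocks: a task whose body already started (or ran) is
  # left alone; correctness rests on select activation only.
  if (!t$started && t$state != "DONE" && t$activation == "ENABLED") {
    t$activation <- "DISABLED"
    stf_log(rt, "disable", t$id)
    TRUE
  } else {
    stf_log(rt, "disable_too_late", t$id)
    FALSE
  }
}

enable_task <- function(rt, t) {
  if (t$activation != "ENABLED") {
    t$activation <- "ENABLED"
    stf_log(rt, "enable", t$id)
  }
}

release_held <- function(rt, t) {
  if (t$held) {
    t$held <- FALSE
    stf_log(rt, "release", t$id)
    if (!is.null(rt$exec)) exec_notify_release(rt, t)
  }
}

# The speculative path of g is valid: the original is not needed (disable it
# if it has not started) and the selects will switch the duplicates in.
set_valid <- function(rt, g) {
  if (g$validity != "PENDING") return(invisible(NULL))
  g$validity <- "VALID"
  stf_log(rt, "group_valid", NA_integer_, paste0("g", g$id))
  for (t in g$originals) { disable_best_effort(rt, t); release_held(rt, t) }
  for (s in g$selects) release_held(rt, s)
  dispatch_outcome_if_ready(rt, g)
  invisible(NULL)
}

# The speculation feeding g is wrong (an upstream uncertain task wrote, or
# the policy disabled an upstream group): twins are cancelled best-effort,
# selects never run, originals run normally.  Failure floods downstream.
set_invalid <- function(rt, g) {
  if (g$validity == "INVALID") return(invisible(NULL))
  g$validity <- "INVALID"
  g$failed <- TRUE
  g$dead <- TRUE
  stf_log(rt, "group_invalid", NA_integer_, paste0("g", g$id))
  for (tw in g$twins) disable_best_effort(rt, tw)
  for (s in g$selects) { disable_best_effort(rt, s); release_held(rt, s) }
  for (t in g$originals) { enable_task(rt, t); release_held(rt, t) }
  settle_outcome(rt, g, "fail")
  invisible(NULL)
}

settle_outcome <- function(rt, g, outcome) {
  if (g$outcome != "pending") return(invisible(NULL))
  g$outcome <- outcome
  stf_log(rt, "group_outcome", NA_integer_, paste0("g", g$id, ":", outcome))
  for (child in g$children) {
    if (outcome == "fail") {
      set_invalid(rt, child)
    } else {
      child$pending_parents <- child$pending_parents - 1L
      if (child$pending_parents == 0L && child$validity == "PENDING") {
        set_valid(rt, child)
      }
    }
  }
  invisible(NULL)
}

dispatch_outcome_if_ready <- function(rt, g) {
  if (g$validity != "VALID" || g$outcome != "pending") return(invisible(NULL))
  if (g$root) return(invisible(NULL))  # settled by the main task's completion
  if (length(g$twins) == 0L) return(invisible(NULL))
  done <- all(vapply(g$twins, function(tw) tw$state == "DONE", logical(1)))
  if (!done) return(invisible(NULL))
  wrote <- vapply(g$twins, function(tw) isTRUE(tw$did_write), logical(1))
  settle_outcome(rt, g, if (any(wrote)) "fail" else "success")
  invisible(NULL)
}

# Completion hook called by every executor once a task is DONE.
on_task_complete <- function(rt, t) {
  g <- t$group
  if (is.null(g)) return(invisible(NULL))
  if (g$root && identical(g$main, t)) {
    # root uncertain task: its did-write decides the fate of all children
    if (isTRUE(t$did_write)) {
      g$failed <- TRUE
      g$dead <- TRUE
      settle_outcome(rt, g, "fail")
    } else {
      settle_outcome(rt, g, "success")
    }
  } else if (t$speculative) {
    dispatch_outcome_if_ready(rt, g)
  }
  invisible(NULL)
}

# Runtime decision whether to speculate, taken when the first copy task of a
# still-undefined group becomes ready.
decide_speculation <- function(rt, g, n_ready) {
  if (g$policy_state != "UNDEFINED") return(invisible(NULL))
  on <- isTRUE(rt$policy(n_ready, rt$workers))
  g$policy_state <- if (on) "ENABLED" else "DISABLED"
  stf_log(rt, "group_policy", NA_integer_, paste0("g", g$id, ":", g$policy_state))
  if (!on) {
    g$dead <- TRUE
    for (cp in g$copies) disable_best_effort(rt, cp)
    for (tw in g$twins) disable_best_effort(rt, tw)
    for (s in g$selects) { disable_best_effort(rt, s); release_held(rt, s) }
    for (t in g$originals) { enable_task(rt, t); release_held(rt, t) }
    if (g$validity == "PENDING") g$validity <- "INVALID"
    settle_outcome(rt, g, "fail")
  }
  invisible(NULL)
}

## ---- policies ---------------------------------------------------------------

#' Speculation decision policies
#'
#' A policy is called once per speculative task group, when the group's
#' first copy task becomes ready, with the number of currently ready tasks
#' and the worker count; it returns `TRUE` to enable the speculation.
#' `policy_always_on()` (the default) always speculates;
#' `policy_always_off()` turns every group into a plain task-based run;
#' `policy_threshold()` speculates only while the scheduler is starved
#' (fewer ready tasks than workers).
#'
#' @return a policy function `function(n_ready, n_workers)`.
#' @export
policy_always_on <- function() function(n_ready, n_workers) TRUE

#' @rdname policy_always_on
#' @export
policy_always_off <- function() function(n_ready, n_workers) FALSE

#' @rdname policy_always_on
#' @export
policy_threshold <- function() function(n_ready, n_workers) n_ready < n_workers
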