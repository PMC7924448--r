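# Expected-speedup models for a chain of N consecutive uncertain tasks
# followed by one certain task, all of cost t, with negligible copy/select
# costs and at least N available workers.
#
# Predictive speculation speculates along the no-write path once; a single
# write ends the speculation and the remaining tasks run normally.  The
# expected saved duration is
#     D_N = sum_{i=1..N} t * i * P_{i+1} * prod_{j<=i} (1 - P_j),
# with P_{N+1} = 1 (the closing certain task always writes), and the
# expected speedup is S = (N+1) t / ((N+1) t - D_N).
#
# Eager speculation restarts after every failure, so every task that does
# not write contributes a full t: F(N) = t * sum_i (1 - P_i), with
# S = (N+1) t / ((N+1) t - F(N)).

check_theory_params <- function(probs, t) {
  if (length(probs) == 0L) {
    stop("'probs' must contain at least one write probability", call. = FALSE)
  }
  if (!is.numeric(probs) || any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    stop("'probs' must be probabilities in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0) {
    stop("'t' must be a positive task cost", call. = FALSE)
  }
  invisible(NULL)
}

#' Expected gain and speedup of predictive speculation
#'
#' For `N = length(probs)` consecutive uncertain tasks with per-task write
#' probabilities `probs`, followed by one certain task, all of cost `t`:
#' `predictive_gain()` returns the expected saved duration (in units of
#' `t`), `predictive_speedup()` the corresponding expected speedup.
#'
#' @param probs numeric vector of per-task write probabilities (the closing
#'   certain task has probability 1 implicitly).
#' @param t task cost (> 0).
#' @return a number: expected gain in `[0, N t]`, or speedup in
#'   `[1, N + 1]`.
#' @examples
#' predictive_gain(rep(0.5, 3))        # 0.875
#' predictive_speedup(0.5)             # 4/3
#' @export
predictive_gain <- function(probs, t = 1) {
  check_theory_params(probs, t)
  n <- length(probs)
  p_ext <- c(probs, 1)
  no_write <- cumprod(1 - probs)
  sum(t * seq_len(n) * p_ext[seq_len(n) + 1L] * no_write)
}

#' @rdname predictive_gain
#' @export
predictive_speedup <- function(probs, t = 1) {
  n <- length(probs)
  gain <- predictive_gain(probs, t)
  (n + 1) * t / ((n + 1) * t - gain)
}

#' Expected gain and speedup of eager speculation
#'
#' Eager speculation re-speculates after every failed prediction, so every
#' uncertain task that does not write saves a full `t`:
#' `F(N) = t * sum(1 - probs)`. Only the performance model is provided; the
#' runtime implements the predictive strategy.
#'
#' @inheritParams predictive_gain
#' @return a number.
#' @examples
#' eager_gain(rep(0, 4))     # 4: every speculation succeeds
#' eager_speedup(rep(0.5, 10))
#' @export
eager_gain <- function(probs, t = 1) {
  check_theory_params(probs, t)
  t * sum(1 - probs)
}

#' @rdname eager_gain
#' @export
eager_speedup <- function(probs, t = 1) {
  n <- length(probs)
  gain <- eager_gain(probs, t)
  (n + 1) * t / ((n + 1) * t - gain)
}

#' Number of speculative tasks required by eager speculation
#'
#' Eagerly covering a chain of `n` consecutive uncertain tasks requires
#' `(n^2 + n)/2 - n` speculative tasks (plus copies and selects).
#'
#' @param n number of consecutive uncertain tasks (>= 1).
#' @return an integer count.
#' @export
eager_task_count <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n %% 1 != 0) {
    stop("'n' must be an integer >= 1", call. = FALSE)
  }
  (n^2 + n) / 2 - n
}

#' Monte Carlo estimate of the predictive gain
#'
#' Simulates `reps` independent chains: each task writes with its
#' probability; the realized saved duration of the predictive scheme is
#' `i * t` when the first writing task has index `i + 1` (tasks `1..i` did
#' not write) and `N * t` when no task writes. The sample mean is an
#' unbiased estimator of [predictive_gain()].
#'
#' @inheritParams predictive_gain
#' @param reps number of simulated chains (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return list with `estimate`, `se` (standard error of the mean), `reps`.
#' @export
mc_gain_estimate <- function(probs, t = 1, reps = 10000L, seed = NULL) {
  check_theory_params(probs, t)
  if (!is.numeric(reps) || length(reps) != 1L || is.na(reps) || reps < 1) {
    stop("'reps' must be >= 1", call. = FALSE)
  }
  reps <- as.integer(reps)
  if (!is.null(seed)) set.seed(seed)
  n <- length(probs)
  # writes[r, i]: did task i write in chain r
  writes <- matrix(runif(reps * n) < rep(probs, each = reps), nrow = reps)
  # index of the first writing task; sentinel column n+1 when none writes
  first_write <- max.col(cbind(writes, TRUE), ties.method = "first")
  gains <- t * (first_write - 1L)
  est <- mean(gains)
  se <- stats::sd(gains) / sqrt(reps)
  list(estimate = est, se = se, reps = reps)
}

#' Expected gain/speedup table for uncertain-task chains
#'
#' Closed-form predictive gain `D` and speedup `S` for chains of
#' `N = 1..n_max` uncertain tasks at each uniform write probability, with
#' unit task cost.
#'
#' @param probs uniform write probabilities, one block of rows per value.
#' @param n_max largest chain length.
#' @param t task cost.
#' @return data.frame with columns `quantity` ("D" or "S"), `p`, and one
#'   column `N1..N<n_max>`.
#' @export
theory_table <- function(probs = c(0.25, 0.5, 0.75), n_max = 7, t = 1) {
  rows <- list()
  for (p in probs) {
    d <- vapply(seq_len(n_max), function(n) predictive_gain(rep(p, n), t),
                numeric(1))
    s <- vapply(seq_len(n_max), function(n) predictive_speedup(rep(p, n), t),
                numeric(1))
    rows[[length(rows) + 1L]] <- c(list(quantity = "D", p = p),
                                   as.list(d))
    rows[[length(rows) + 1L]] <- c(list(quantity = "S", p = p),
                                   as.list(s))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(setNames(r, c("quantity", "p",
                                paste0("N", seq_len(n_max)))))
  }))
  rownames(out) <- NULL
  out
}

#' Round half away from zero
#'
#' Printed reference tables round half-up; base R [round()] rounds half to
#' even, so agreement checks at printed precision use this helper.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
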