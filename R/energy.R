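# Pairwise Lennard-Jones energies in reduced units (epsilon = sigma = 1,
# Boltzmann constant 1, no cutoff, no periodic images; the box only bounds
# move proposals).  The system energy is kept as a symmetric domain-by-domain
# matrix: entry (i, j) is the summed pair energy between all particles of
# domains i and j, the diagonal holds intra-domain energies.  Storing the
# matrix is what lets a single-domain move touch only one row/column -- the
# maybe-write access pattern the task decomposition relies on.

lj_from_d2 <- function(d2) {
  inv6 <- 1 / d2^3          # (sigma/r)^6 with squared distances
  4 * (inv6^2 - inv6)
}

check_coincident <- function(d2, ei, ej, tol = 1e-20) {
  if (any(d2 < tol)) {
    k <- which(d2 < tol, arr.ind = TRUE)[1L, ]
    stop(sprintf("coincident particles: domain %d particle %d and domain %d particle %d (r = 0)",
                 ei, k[[1L]], ej, k[[2L]]), call. = FALSE)
  }
  invisible(NULL)
}

cross_d2 <- function(a, b) {
  # squared distances between every row of a and every row of b
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

domain_cross_energy <- function(a, b, ia = 1L, ib = 2L) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  d2 <- pmax(cross_d2(a, b), 0)
  check_coincident(d2, ia, ib)
  sum(lj_from_d2(d2))
}

domain_intra_energy <- function(a, ia = 1L) {
  n <- nrow(a)
  if (n < 2L) return(0)
  d2 <- pmax(cross_d2(a, a), 0)
  ut <- upper.tri(d2)
  check_coincident(ifelse(ut, d2, Inf), ia, ia)
  sum(lj_from_d2(d2[ut]))
}

#' Lennard-Jones pair energy
#'
#' `4 (r^-12 - r^-6)` in reduced units; the minimum, -1, is at
#' `r = 2^(1/6)`.
#'
#' @param r pair distance(s) (> 0).
#' @return energy value(s).
#' @export
lj_pair_energy <- function(r) {
  if (any(r <= 0)) stop("pair distance must be positive", call. = FALSE)
  lj_from_d2(r^2)
}

#' Full pairwise energy matrix of a particle system
#'
#' Evaluates the Lennard-Jones energy between every particle pair and fills
#' the symmetric domain-pair matrix (diagonal: intra-domain energy).
#'
#' @param domains list of `P x 3` position matrices.
#' @param box box edge lengths (unused by the energy itself; kept for
#'   interface symmetry with the move proposal, which is box-bounded).
#' @return a `D x D` symmetric matrix.
#' @export
compute_energy <- function(domains, box = NULL) {
  nd <- length(domains)
  if (nd < 1L) stop("need at least one domain", call. = FALSE)
  e <- matrix(0, nd, nd)
  for (i in seq_len(nd)) {
    e[i, i] <- domain_intra_energy(domains[[i]], i)
    if (i < nd) {
      for (j in (i + 1L):nd) {
        e[i, j] <- e[j, i] <- domain_cross_energy(domains[[i]], domains[[j]],
                                                  i, j)
      }
    }
  }
  e
}

#' Incremental energy update after a single-domain move
#'
#' Recomputes only row/column `index` (and the diagonal entry) of the
#' energy matrix against the moved domain's new positions; every other
#' entry is untouched.
#'
#' @param energy current `D x D` energy matrix, consistent with the
#'   pre-move positions.
#' @param moved new `P x 3` positions of domain `index`.
#' @param index which domain moved.
#' @param domains list of all domains at their pre-move positions (entry
#'   `index` is ignored).
#' @param box see [compute_energy()].
#' @return the updated energy matrix.
#' @export
update_energy <- function(energy, moved, index, domains, box = NULL) {
  nd <- length(domains)
  if (index < 1L || index > nd) stop("domain index out of range", call. = FALSE)
  e <- energy
  e[index, index] <- domain_intra_energy(moved, index)
  for (j in seq_len(nd)) {
    if (j == index) next
    e[index, j] <- e[j, index] <- domain_cross_energy(moved, domains[[j]],
                                                      index, j)
  }
  e
}

#' Total system energy from the domain-pair matrix
#'
#' Half-sum of the off-diagonal entries (each cross pair is stored twice)
#' plus the diagonal sum.
#'
#' @param energy a `D x D` energy matrix.
#' @return a number, in reduced energy units.
#' @export
total_energy <- function(energy) {
  (sum(energy) - sum(diag(energy))) / 2 + sum(diag(energy))
}
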