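#' Brute-force rigidity oracle via the generic rigidity matrix
#'
#' Independent check of the pebble game. Every body receives a 6-dimensional
#' velocity screw (omega, v); each bar of a multigraph edge is realised as a
#' generic bar between random points p on body i and q on body j and
#' contributes one row constraining the relative velocity along p - q:
#' `((v_i + omega_i x p) - (v_j + omega_j x q)) . (p - q) = 0`.
#' The internal degrees of freedom are the nullity of the matrix minus the 6
#' trivial rigid motions; two bodies are mutually rigid iff their screws are
#' identical in every nullspace vector. The construction is repeated at
#' several seeds and the generic (maximal-rank) outcome is kept, guarding
#' against accidental degeneracies of one random placement.
#'
#' @param graph A `body_bar_graph` with at most `max_bodies` bodies.
#' @param seed Integer seed for the random generic placements.
#' @param n_seeds Number of placements tried (default 3).
#' @param max_bodies Refusal threshold for the dense linear algebra
#'   (default 60).
#' @param tol Numeric tolerance on normalized nullspace entries (default
#'   1e-8).
#' @return List with `free_dof`, `pairwise_rigid` (logical n x n matrix) and
#'   `components` (list of body-id vectors, matching the partition induced by
#'   pairwise rigidity).
#' @export
rigidity_matrix_oracle <- function(graph, seed = 1L, n_seeds = 3L,
                                   max_bodies = 60L, tol = 1e-8) {
  n <- graph$n_bodies
  if (n > max_bodies) {
    stop("oracle refuses graphs with more than ", max_bodies,
         " bodies (dense linear algebra)", call. = FALSE)
  }
  if (n == 0) {
    return(list(free_dof = 0L, pairwise_rigid = matrix(logical(0), 0, 0),
                components = list()))
  }

  edges <- graph$edges
  best <- NULL
  for (k in seq_len(n_seeds)) {
    set.seed(seed + k - 1L)
    res <- .oracle_once(n, edges, tol)
    if (is.null(best) || res$rank > best$rank) best <- res
  }

  pr <- best$pairwise
  comp_id <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp_id[i] == 0L) {
      cid <- cid + 1L
      comp_id[pr[i, ]] <- cid
    }
  }
  components <- unname(split(seq_len(n), comp_id))
  components <- components[order(vapply(components, min, 0L))]

  list(free_dof = as.integer(6L * n - best$rank - 6L),
       pairwise_rigid = pr,
       components = components)
}

.oracle_once <- function(n, edges, tol) {
  centers <- matrix(stats::runif(3 * n, -5, 5), n, 3)
  m_rows <- sum(edges$mult)
  if (m_rows == 0) {
    ## no constraints: nullspace is everything, no pair rigid
    pr <- diag(TRUE, n)
    return(list(rank = 0L, pairwise = pr))
  }

  M <- matrix(0, m_rows, 6 * n)
  row <- 0L
  for (r in seq_len(nrow(edges))) {
    i <- edges$body_a[r]
    j <- edges$body_b[r]
    for (b in seq_len(edges$mult[r])) {
      row <- row + 1L
      p <- centers[i, ] + stats::rnorm(3)
      q <- centers[j, ] + stats::rnorm(3)
      d <- p - q
      M[row, (6 * (i - 1) + 1):(6 * (i - 1) + 3)] <- .cross3(p, d)
      M[row, (6 * (i - 1) + 4):(6 * (i - 1) + 6)] <- d
      M[row, (6 * (j - 1) + 1):(6 * (j - 1) + 3)] <- -.cross3(q, d)
      M[row, (6 * (j - 1) + 4):(6 * (j - 1) + 6)] <- -d
    }
  }

  sv <- svd(M, nu = 0, nv = 6 * n)
  d <- sv$d
  rank_tol <- max(dim(M)) * .Machine$double.eps * max(d, 1)
  rank_tol <- max(rank_tol, 1e-10 * max(d, 1))
  rank <- sum(d > rank_tol)
  null_basis <- sv$v[, seq(rank + 1, 6 * n), drop = FALSE]

  pr <- matrix(FALSE, n, n)
  diag(pr) <- TRUE
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      bi <- null_basis[(6 * (i - 1) + 1):(6 * i), , drop = FALSE]
      for (j in seq(i + 1, n)) {
        bj <- null_basis[(6 * (j - 1) + 1):(6 * j), , drop = FALSE]
        if (max(abs(bi - bj)) < max(tol, 1e-8)) {
          pr[i, j] <- TRUE
          pr[j, i] <- TRUE
        }
      }
    }
  }
  list(rank = as.integer(rank), pairwise = pr)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
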