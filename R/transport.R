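# Exact discrete optimal transport by the transportation simplex.
#
# The mixture-Wasserstein distance needs the optimal value of a tiny
# transport problem (at most a few dozen model components against three
# environment sources), so an exact network-simplex on the transportation
# polytope is the right tool: deterministic, no tolerance tuning, no
# external solver. Verified in the test suite against exhaustive
# enumeration of basic feasible solutions on small instances.

#' Solve a discrete transport problem exactly
#'
#' Minimises `sum(P * cost)` over nonnegative plans `P` with row sums `a`
#' and column sums `b` (both nonnegative, equal total mass), using the
#' transportation simplex: northwest-corner initial basis, MODI potentials,
#' most-negative entering rule with smallest-index tie-breaking.
#'
#' @param a,b marginal weight vectors (sum to the same total).
#' @param cost `length(a)` x `length(b)` cost matrix.
#' @return list with `plan` (optimal transport matrix) and `cost` (optimal
#'   objective value).
#' @export
transport_plan <- function(a, b, cost) {
  m <- length(a); n <- length(b)
  stopifnot(nrow(cost) == m, ncol(cost) == n)
  if (any(a < 0) || any(b < 0)) stop("marginals must be nonnegative",
                                     call. = FALSE)
  if (abs(sum(a) - sum(b)) > 1e-9) {
    stop("marginals must have equal total mass", call. = FALSE)
  }
  b[n] <- b[n] + (sum(a) - sum(b))  # absorb rounding in the last demand

  # northwest-corner start: advances one index per placement, giving
  # exactly m + n - 1 basic cells (zeros included under degeneracy)
  X <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  ra <- a; rb <- b
  i <- 1L; j <- 1L
  repeat {
    q <- min(ra[i], rb[j])
    X[i, j] <- q
    basis[i, j] <- TRUE
    ra[i] <- ra[i] - q
    rb[j] <- rb[j] - q
    if (i == m && j == n) break
    if (i == m) j <- j + 1L
    else if (j == n) i <- i + 1L
    else if (ra[i] <= rb[j]) i <- i + 1L
    else j <- j + 1L
  }

  tol <- 1e-12 * (1 + max(abs(cost)))
  for (iter in seq_len(10000L)) {
    # MODI potentials from the spanning-tree basis
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1] <- 0
    bcells <- which(basis, arr.ind = TRUE)
    repeat {
      progressed <- FALSE
      for (k in seq_len(nrow(bcells))) {
        bi <- bcells[k, 1]; bj <- bcells[k, 2]
        if (!is.na(u[bi]) && is.na(v[bj])) {
          v[bj] <- cost[bi, bj] - u[bi]; progressed <- TRUE
        } else if (is.na(u[bi]) && !is.na(v[bj])) {
          u[bi] <- cost[bi, bj] - v[bj]; progressed <- TRUE
        }
      }
      if (!progressed) break
    }
    if (anyNA(u) || anyNA(v)) stop("degenerate transport basis", call. = FALSE)

    rc <- cost - outer(u, rep(1, n)) - outer(rep(1, m), v)
    rc[basis] <- 0
    if (min(rc) >= -tol) break
    ent <- which(rc == min(rc))[1]        # column-major smallest index
    ei <- (ent - 1L) %% m + 1L
    ej <- (ent - 1L) %/% m + 1L

    # unique cycle: path from row node ei to column node ej in the basis
    # tree (nodes 1..m rows, m+1..m+n columns), plus the entering cell
    adj <- vector("list", m + n)
    for (k in seq_len(nrow(bcells))) {
      bi <- bcells[k, 1]; bj <- m + bcells[k, 2]
      adj[[bi]] <- c(adj[[bi]], bj)
      adj[[bj]] <- c(adj[[bj]], bi)
    }
    parent <- rep(NA_integer_, m + n)
    parent[ei] <- 0L
    queue <- ei
    while (length(queue)) {
      node <- queue[1]; queue <- queue[-1]
      for (nb in adj[[node]]) {
        if (is.na(parent[nb])) {
          parent[nb] <- node
          queue <- c(queue, nb)
        }
      }
    }
    path <- m + ej
    while (path[1] != ei) path <- c(parent[path[1]], path)

    # edges along the path alternate -, +, -, ... (entering cell is +)
    L <- length(path) - 1L
    minus_cells <- matrix(0L, 0, 2)
    plus_cells <- matrix(0L, 0, 2)
    for (k in seq_len(L)) {
      nd1 <- path[k]; nd2 <- path[k + 1L]
      cell <- if (nd1 <= m) c(nd1, nd2 - m) else c(nd2, nd1 - m)
      if (k %% 2L == 1L) minus_cells <- rbind(minus_cells, cell)
      else plus_cells <- rbind(plus_cells, cell)
    }
    theta_vals <- X[minus_cells]
    theta <- min(theta_vals)
    leave <- minus_cells[which(theta_vals == theta)[1], , drop = FALSE]

    X[minus_cells] <- X[minus_cells] - theta
    X[plus_cells] <- X[plus_cells] + theta
    X[ei, ej] <- theta
    basis[leave] <- FALSE
    basis[ei, ej] <- TRUE
    if (iter == 10000L) stop("transport simplex failed to converge",
                             call. = FALSE)
  }
  list(plan = X, cost = sum(X * cost))
}
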