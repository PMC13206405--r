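# Exhaustive oracle for tiny transport problems: enumerate every basic
# feasible solution (spanning tree of the bipartite supply/demand graph),
# solve its flows by leaf elimination, and take the cheapest feasible one.
# The optimum of a transportation LP is attained at such a vertex.

enumerate_transport <- function(a, b, C) {
  m <- length(a); n <- length(b)
  nodes <- m + n
  edges <- cbind(rep(seq_len(m), n), rep(seq_len(n), each = m))
  best <- Inf
  for (sel in utils::combn(nrow(edges), nodes - 1, simplify = FALSE)) {
    E <- edges[sel, , drop = FALSE]
    deg <- tabulate(c(E[, 1], m + E[, 2]), nodes)
    bal <- c(a, b)
    flow <- rep(NA_real_, nrow(E))
    alive <- rep(TRUE, nrow(E))
    ok <- TRUE
    for (round in seq_len(nrow(E))) {
      leaf_edge <- NA_integer_
      for (k in which(alive)) {
        nd_r <- E[k, 1]; nd_c <- m + E[k, 2]
        if (deg[nd_r] == 1) { leaf_edge <- k; leaf <- nd_r; other <- nd_c; break }
        if (deg[nd_c] == 1) { leaf_edge <- k; leaf <- nd_c; other <- nd_r; break }
      }
      if (is.na(leaf_edge)) { ok <- FALSE; break }  # cycle: not a tree
      q <- bal[leaf]
      if (q < -1e-12) { ok <- FALSE; break }
      flow[leaf_edge] <- q
      bal[leaf] <- 0
      bal[other] <- bal[other] - q
      deg[leaf] <- deg[leaf] - 1L
      deg[other] <- deg[other] - 1L
      alive[leaf_edge] <- FALSE
    }
    if (!ok || any(flow < -1e-12)) next
    cost <- sum(flow * C[cbind(E[, 1], E[, 2])])
    if (cost < best) best <- cost
  }
  best
}
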