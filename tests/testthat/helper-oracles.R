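# Independent brute-force oracles used to check the implementation.

# Shortest-path counts from source s by breadth-first search.
# adj: adjacency list (list of integer vectors), n nodes.
bfs_dist_sigma <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

.adj_from_edges <- function(nodes, ea, eb) {
  adj <- rep(list(integer(0)), length(nodes))
  ia <- match(ea, nodes); ib <- match(eb, nodes)
  for (k in seq_along(ia)) {
    adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
    adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
  }
  lapply(adj, unique)
}

# Betweenness by explicit geodesic counting over unordered pairs {s, t}:
# B_i = sum sigma_si * sigma_it / sigma_st over pairs with
# d_si + d_it = d_st < Inf.
oracle_betweenness <- function(nodes, ea, eb) {
  n <- length(nodes)
  adj <- .adj_from_edges(nodes, ea, eb)
  bfs <- lapply(seq_len(n), function(s) bfs_dist_sigma(adj, s))
  B <- stats::setNames(rep(0, n), nodes)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    dst <- bfs[[s]]$dist[t]
    if (is.infinite(dst)) next
    for (i in seq_len(n)) {
      if (i == s || i == t) next
      if (bfs[[s]]$dist[i] + bfs[[i]]$dist[t] == dst)
        B[i] <- B[i] + bfs[[s]]$sigma[i] * bfs[[i]]$sigma[t] / bfs[[s]]$sigma[t]
    }
  }
  B
}

# Closeness per connected component: (n_comp - 1) / sum of distances.
oracle_closeness <- function(nodes, ea, eb) {
  n <- length(nodes)
  adj <- .adj_from_edges(nodes, ea, eb)
  out <- stats::setNames(rep(0, n), nodes)
  for (i in seq_len(n)) {
    d <- bfs_dist_sigma(adj, i)$dist
    reach <- which(is.finite(d) & seq_len(n) != i)
    if (length(reach)) out[i] <- length(reach) / sum(d[reach])
  }
  out
}

# Exhaustive hypergeometric upper tail including x = n.
oracle_hypergeom <- function(M, N_set, m, n) {
  xs <- n:min(N_set, m)
  xs <- xs[m - xs <= M - N_set]
  if (!length(xs)) return(0)
  sum(choose(N_set, xs) * choose(M - N_set, m - xs)) / choose(M, m)
}

# Naive full running-sum enrichment score (checks the extremum shortcut).
oracle_es <- function(scores, hit, weight = 1) {
  n <- length(scores)
  k <- sum(hit)
  w <- abs(scores)^weight
  nr <- sum(w[hit])
  inc <- if (nr > 0) w / nr else rep(1 / k, n)
  step <- ifelse(hit, inc, -1 / (n - k))
  run <- cumsum(step)
  mx <- max(run, 0); mn <- min(run, 0)
  if (mx >= -mn) mx else mn  # positive side wins exact ties
}

# Random small graph as a CellNetwork (possibly disconnected).
random_network <- function(n_nodes, p_edge = 0.4) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  make_network(pairs[keep, 1], pairs[keep, 2])
}
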