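# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most naive formulation of each quantity.

# Pearson r by the raw sum formula
naive_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# grey relational coefficients and degrees by an explicit double loop
brute_gra <- function(parent, subs, rho = 0.5) {
  subs <- as.matrix(subs)
  n_sub <- nrow(subs); N <- ncol(subs)
  delta <- matrix(0, n_sub, N)
  for (i in seq_len(n_sub))
    for (k in seq_len(N))
      delta[i, k] <- abs(parent[k] - subs[i, k])
  d_min <- min(delta); d_max <- max(delta)
  eps <- matrix(0, n_sub, N)
  for (i in seq_len(n_sub))
    for (k in seq_len(N))
      eps[i, k] <- (d_min + rho * d_max) / (delta[i, k] + rho * d_max)
  list(eps = eps, grd = rowMeans(eps))
}

# normalized degree/betweenness/closeness from scratch (BFS all pairs),
# matching the normalisations used for undirected connected graphs:
# betweenness / ((n-1)(n-2)/2), closeness = (n-1)/sum(d)
brute_centrality <- function(edges) {
  nodes <- sort(unique(c(edges[, 1L], edges[, 2L])))
  n <- length(nodes)
  adj <- lapply(nodes, function(v)
    unique(c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L])))
  names(adj) <- nodes
  idx <- seq_len(n); names(idx) <- nodes

  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  order_from <- vector("list", n)
  for (s in nodes) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    queue <- s; visited <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.infinite(dist[s, w])) {
          dist[s, w] <- dist[s, v] + 1
          queue <- c(queue, w); visited <- c(visited, w)
        }
        if (dist[s, w] == dist[s, v] + 1)
          sigma[s, w] <- sigma[s, w] + sigma[s, v]
      }
    }
    order_from[[idx[s]]] <- visited
  }

  btw <- stats::setNames(numeric(n), nodes)
  for (v in nodes)
    for (s in nodes)
      for (t in nodes)
        if (s < t && s != v && t != v && is.finite(dist[s, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t])
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  btw <- btw / ((n - 1) * (n - 2) / 2)

  cls <- stats::setNames(numeric(n), nodes)
  for (v in nodes) {
    d <- dist[v, ]; d <- d[names(d) != v & is.finite(d)]
    cls[v] <- length(d) / sum(d) * (length(d) / (n - 1))
  }
  deg <- stats::setNames(vapply(adj, length, 0L), nodes)
  list(betweenness = btw, closeness = cls, degree = deg)
}

# a small positively oriented efficacy panel for weighting tests
toy_panel <- function() {
  efficacy_panel(matrix(c(2, 6, 4,
                          1, 3, 5), nrow = 3,
                        dimnames = list(c("g1", "g2", "g3"),
                                        c("ind1", "ind2"))))
}

# entropy weights evaluated directly from the defining formulas
naive_ewm <- function(values) {
  n <- nrow(values)
  d <- apply(values, 2L, function(col) {
    xp <- (col - min(col)) / (max(col) - min(col))
    p <- xp / sum(xp)
    p <- p[p > 0]
    1 - (-sum(p * log(p)) / log(n))
  })
  d / sum(d)
}
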