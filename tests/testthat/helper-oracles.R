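# Independent brute-force oracles. Deliberately naive: direct formula
# evaluation, explicit loops, no shared code with the package internals.

# Hypergeometric upper tail 1 - sum_{i=0}^{t-1} C(T1,i) C(Q-T1,T2-i) / C(Q,T2)
oracle_ms <- function(t, T1, T2, Q) {
  if (t == 0) return(1)
  acc <- 0
  for (i in 0:(t - 1)) {
    acc <- acc + choose(T1, i) * choose(Q - T1, T2 - i) / choose(Q, T2)
  }
  1 - acc
}

# Two-pass textbook Pearson correlation
oracle_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Plug-in MI by explicit double loop, natural log
oracle_mi <- function(dx, dy) {
  n <- length(dx)
  total <- 0
  for (a in unique(dx)) for (b in unique(dy)) {
    p_ab <- sum(dx == a & dy == b) / n
    if (p_ab > 0) {
      total <- total + p_ab *
        log(p_ab / ((sum(dx == a) / n) * (sum(dy == b) / n)))
    }
  }
  total
}

# Plug-in CMI by explicit triple loop
oracle_cmi <- function(dx, dy, dz) {
  n <- length(dx)
  total <- 0
  for (c_ in unique(dz)) for (a in unique(dx)) for (b in unique(dy)) {
    p_abc <- sum(dx == a & dy == b & dz == c_) / n
    if (p_abc > 0) {
      p_c <- sum(dz == c_) / n
      p_ac <- sum(dx == a & dz == c_) / n
      p_bc <- sum(dy == b & dz == c_) / n
      total <- total + p_abc * log(p_c * p_abc / (p_ac * p_bc))
    }
  }
  total
}

# LA by direct formula with explicit rank-based normal scores
oracle_la <- function(x, y, m) {
  n <- length(x)
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  nm <- qnorm(rank(m, ties.method = "average") / (n + 1))
  sum(zx * zy * nm) / n
}

# --- graph oracles (adjacency matrix in, explicit path enumeration) ------

# All shortest paths s -> t as lists of vertex sequences, from BFS distances
.all_shortest_paths <- function(adj, dmat, s, t) {
  if (!is.finite(dmat[s, t])) return(list())
  if (s == t) return(list(s))
  res <- list()
  for (u in which(adj[, t] == 1)) {
    if (is.finite(dmat[s, u]) && dmat[s, u] == dmat[s, t] - 1) {
      for (p in .all_shortest_paths(adj, dmat, s, u)) {
        res[[length(res) + 1L]] <- c(p, t)
      }
    }
  }
  res
}

.bfs_dist <- function(adj) {
  n <- nrow(adj)
  dmat <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dmat[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) {
        for (u in which(adj[v, ] == 1)) {
          if (!is.finite(dmat[s, u])) {
            dmat[s, u] <- d
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  dmat
}

# node betweenness, edge betweenness, component closeness, local clustering
oracle_topology <- function(adj) {
  n <- nrow(adj)
  dmat <- .bfs_dist(adj)
  btw <- numeric(n)
  edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  eb <- numeric(nrow(edges))
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(dmat[s, t])) next
    paths <- .all_shortest_paths(adj, dmat, s, t)
    np <- length(paths)
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / np
      if (length(p) > 1) {
        for (k in seq_len(length(p) - 1L)) {
          a <- min(p[k], p[k + 1L]); b <- max(p[k], p[k + 1L])
          idx <- which(edges[, 1] == a & edges[, 2] == b)
          eb[idx] <- eb[idx] + 1 / np
        }
      }
    }
  }
  clo <- numeric(n)
  for (v in seq_len(n)) {
    members <- which(is.finite(dmat[v, ]))
    clo[v] <- if (length(members) < 2) 0 else
      (length(members) - 1) / sum(dmat[v, setdiff(members, v)])
  }
  clus <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    clus[v] <- if (k < 2) 0 else
      sum(adj[nb, nb, drop = FALSE]) / 2 / choose(k, 2)
  }
  list(degree = rowSums(adj), betweenness = btw, closeness = clo,
       clustering = clus, edges = edges, edge_betweenness = eb)
}

# Newman-Girvan modularity by explicit edge counting
oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (c_ in unique(membership)) {
    nodes <- which(membership == c_)
    e_c <- sum(adj[nodes, nodes, drop = FALSE]) / 2
    d_c <- sum(deg[nodes])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# random undirected graph as adjacency matrix
random_adj <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1L, p)
  adj + t(adj)
}

adj_to_igraph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(nrow(adj)))
  g
}
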