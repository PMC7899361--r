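# Independent centrality oracle: exhaustive simple-path enumeration, valid
# for the small graphs (<= 7 nodes) it is used on. Deliberately shares no
# code with the package implementation.

# All simple paths from s to t as lists of vertex indices.
enumerate_paths <- function(adj, s, t) {
  paths <- list()
  rec <- function(v, visited) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- visited
      return(invisible())
    }
    for (w in which(adj[v, ])) {
      if (!(w %in% visited)) rec(w, c(visited, w))
    }
  }
  rec(s, s)
  paths
}

# Degree, normalized betweenness and Wasserman-Faust closeness by brute force.
brute_centralities <- function(nodes, edge_i, edge_j) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n)
  for (r in seq_along(edge_i)) {
    a <- match(edge_i[r], nodes)
    b <- match(edge_j[r], nodes)
    adj[a, b] <- adj[b, a] <- TRUE
  }
  degree <- rowSums(adj)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  btw_raw <- numeric(n)
  if (n >= 2L) {
    for (s in 1:(n - 1)) {
      for (t in (s + 1):n) {
        paths <- enumerate_paths(adj, s, t)
        if (length(paths) == 0L) next
        lens <- vapply(paths, length, integer(1)) - 1L
        dist[s, t] <- dist[t, s] <- min(lens)
        shortest <- paths[lens == min(lens)]
        sigma <- length(shortest)
        for (v in setdiff(seq_len(n), c(s, t))) {
          through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
          btw_raw[v] <- btw_raw[v] + through / sigma
        }
      }
    }
  }
  betweenness <- if (n > 2L) btw_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  closeness <- vapply(seq_len(n), function(i) {
    reach <- which(is.finite(dist[i, ]) & seq_len(n) != i)
    if (length(reach) == 0L || n == 1L) return(0)
    k <- length(reach) + 1L # component size
    ((k - 1) / sum(dist[i, reach])) * ((k - 1) / (n - 1))
  }, numeric(1))
  tibble::tibble(metabolite = nodes, degree = as.numeric(degree),
                 betweenness = betweenness, closeness = closeness)
}

# Random edge set on up to `max_n` labelled nodes with no isolated vertices
# (returned nodes are exactly the incident ones).
random_edge_set <- function(max_n = 7) {
  n <- sample(2:max_n, 1)
  labels <- sprintf("N%d", seq_len(n))
  all_pairs <- t(utils::combn(labels, 2))
  keep <- runif(nrow(all_pairs)) < runif(1, 0.2, 0.8)
  if (!any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
  tibble::tibble(metabolite_i = all_pairs[keep, 1],
                 metabolite_j = all_pairs[keep, 2])
}
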