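# Independent oracles used to cross-check the package implementations.
# Deliberately naive: explicit loops, textbook formulas, no shared code
# with the functions under test.

# brute-force between-community mean nearest taxon distance:
# explicit double loop over taxa, both directions averaged
brute_bmntd <- function(counts, D, weighted = TRUE) {
  n <- nrow(counts)
  out <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      if (k == l) next
      sk <- which(counts[k, ] > 0)
      sl <- which(counts[l, ] > 0)
      wk <- if (weighted) counts[k, sk] / sum(counts[k, ]) else
        rep(1 / length(sk), length(sk))
      wl <- if (weighted) counts[l, sl] / sum(counts[l, ]) else
        rep(1 / length(sl), length(sl))
      d_kl <- 0
      for (i in seq_along(sk)) {
        d_kl <- d_kl + wk[i] * min(D[sk[i], sl])
      }
      d_lk <- 0
      for (j in seq_along(sl)) {
        d_lk <- d_lk + wl[j] * min(D[sl[j], sk])
      }
      out[k, l] <- (d_kl + d_lk) / 2
    }
  }
  out
}

# Floyd-Warshall all-pairs shortest paths with path counts, from an
# adjacency matrix (0/1, symmetric, zero diagonal)
brute_shortest_paths <- function(adj) {
  V <- nrow(adj)
  d <- matrix(Inf, V, V)
  cnt <- matrix(0, V, V)
  for (i in seq_len(V)) {
    d[i, i] <- 0
    cnt[i, i] <- 1
    for (j in seq_len(V)) {
      if (i != j && adj[i, j] > 0) {
        d[i, j] <- 1
        cnt[i, j] <- 1
      }
    }
  }
  for (k in seq_len(V)) {
    for (i in seq_len(V)) {
      for (j in seq_len(V)) {
        if (i == j || i == k || j == k) next
        alt <- d[i, k] + d[k, j]
        if (alt < d[i, j]) {
          d[i, j] <- alt
          cnt[i, j] <- cnt[i, k] * cnt[k, j]
        } else if (is.finite(alt) && alt == d[i, j]) {
          cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
        }
      }
    }
  }
  list(dist = d, count = cnt)
}

# brute-force vertex betweenness (undirected, unweighted)
brute_betweenness <- function(adj) {
  sp <- brute_shortest_paths(adj)
  V <- nrow(adj)
  btw <- numeric(V)
  for (v in seq_len(V)) {
    for (s in seq_len(V - 1)) {
      for (t in seq(s + 1, V)) {
        if (s == v || t == v || !is.finite(sp$dist[s, t])) next
        if (is.finite(sp$dist[s, v]) && is.finite(sp$dist[v, t]) &&
            sp$dist[s, v] + sp$dist[v, t] == sp$dist[s, t]) {
          btw[v] <- btw[v] + sp$count[s, v] * sp$count[v, t] / sp$count[s, t]
        }
      }
    }
  }
  btw
}

# textbook haversine, degrees in, km out, mean Earth radius 6371 km
haversine_ref <- function(lat1, lon1, lat2, lon2, r = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# small labelled count matrix builder
make_counts <- function(values, sample_ids = NULL, taxon_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- sample_ids %||% sprintf("S%d", seq_len(nrow(m)))
  colnames(m) <- taxon_ids %||% sprintf("t%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjacency matrix from a cooccurrence_network object
network_adjacency <- function(net) {
  taxa <- net$vertices$taxon_id
  adj <- matrix(0, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
  for (e in seq_len(nrow(net$edges))) {
    a <- net$edges$taxon_a[e]
    b <- net$edges$taxon_b[e]
    adj[a, b] <- 1
    adj[b, a] <- 1
  }
  adj
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
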