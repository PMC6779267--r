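# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own code paths (and igraph) so that
# graph measures, modularity and the KS distance are checked against a second,
# independent route.

# --- fixtures ---------------------------------------------------------------

random_connectome <- function(n, seed, density = 0.5, partition = NULL) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- ifelse(stats::runif(sum(ut)) < density,
                 stats::runif(sum(ut), 0.1, 2), 0)
  w[ut] <- vals
  w <- w + t(w)
  if (is.null(partition)) partition <- rep(c("A", "B"), length.out = n)
  structural_connectome(w, partition = partition)
}

random_binary_graph <- function(n, seed, density = 0.4) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(stats::runif(n * (n - 1) / 2) < density)
  a <- a + t(a)
  binary_graph(a)
}

adjacency_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) { a[e[1], e[2]] <- 1; a[e[2], e[1]] <- 1 }
  binary_graph(a)
}

make_stack <- function(mats, partition = NULL) {
  labels <- sprintf("R%03d", seq_len(nrow(mats[[1]])))
  mats <- lapply(mats, function(m) { dimnames(m) <- list(labels, labels); m })
  if (is.null(partition)) partition <- rep("ALL", nrow(mats[[1]]))
  structure(list(subjects = mats, labels = labels, partition = partition,
                 template = Reduce(`+`, mats) > 0),
            class = "connectome_stack")
}

phase_series_from <- function(phases, tr = 1) {
  structure(list(phases = phases, tr = tr,
                 labels = sprintf("R%03d", seq_len(ncol(phases)))),
            class = "phase_series")
}

fc_from_matrix <- function(v) {
  diag(v) <- 1
  labels <- sprintf("R%03d", seq_len(nrow(v)))
  dimnames(v) <- list(labels, labels)
  structure(list(values = v, labels = labels), class = "static_fc")
}

tiny_cfg <- function(seed = 1L, n_samples = 120L, dt = 0.05, burn_in = 10,
                     tr = 0.72) {
  simulation_config(dt = dt, tr = tr, n_samples = n_samples,
                    burn_in = burn_in, seed = seed)
}

# --- brute-force shortest paths (Floyd-Warshall) ----------------------------

bf_distances <- function(w_len) {
  n <- nrow(w_len)
  d <- w_len
  d[d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# closeness = 1 / mean distance over reachable nodes
bf_closeness <- function(weights) {
  w_len <- weights
  w_len[w_len > 0] <- 1 / w_len[w_len > 0]
  d <- bf_distances(w_len)
  vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, -i]; di <- di[is.finite(di)]
    if (!length(di) || mean(di) == 0) 0 else 1 / mean(di)
  }, numeric(1))
}

# betweenness by enumerating all simple paths between each unordered pair
bf_betweenness <- function(weights) {
  n <- nrow(weights)
  w_len <- weights
  w_len[w_len > 0] <- 1 / w_len[w_len > 0]
  btw <- numeric(n)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(path, len) {
      v <- path[length(path)]
      if (v == to) { paths[[length(paths) + 1]] <<- list(path, len); return() }
      for (u in which(w_len[v, ] > 0)) if (!(u %in% path))
        walk(c(path, u), len + w_len[v, u])
    }
    walk(from, 0)
    paths
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- all_paths(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, `[[`, numeric(1), 2)
    short <- ps[lens <= min(lens) + 1e-12]
    through <- table(unlist(lapply(short, function(p)
      setdiff(p[[1]], c(s, t)))))
    if (length(through))
      btw[as.integer(names(through))] <-
        btw[as.integer(names(through))] + as.numeric(through) / length(short)
  }
  btw
}

# --- brute-force binary-graph efficiencies (BFS) ----------------------------

bf_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (u in which(adj[v, ] > 0))
      if (!is.finite(d[u])) { d[u] <- d[v] + 1; nxt <- c(nxt, u) }
    frontier <- nxt
  }
  d
}

bf_global_efficiency <- function(adj) {
  n <- nrow(adj)
  tot <- 0
  for (s in seq_len(n)) {
    d <- bf_bfs_dist(adj, s)
    inv <- 1 / d[-s]
    inv[!is.finite(inv)] <- 0
    tot <- tot + sum(inv)
  }
  tot / (n * (n - 1))
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    bf_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

# --- other oracles ----------------------------------------------------------

bf_modularity <- function(w, partition) {
  w <- pmax(w, 0); diag(w) <- 0
  v <- sum(w)
  s <- rowSums(w)
  q <- 0
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w)))
    if (partition[i] == partition[j])
      q <- q + (w[i, j] - s[i] * s[j] / v)
  q / v
}

bf_ks <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}
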