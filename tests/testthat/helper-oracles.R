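# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: naive loops and exhaustive enumeration only.

# O(n^3) topological overlap by triple loop.
brute_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Naive UPGMA agglomeration: returns the sorted merge heights and the
# membership at each merge step (as a list of partitions).
brute_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  dm <- d
  active <- seq_len(n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_val <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      val <- mean(d[clusters[[i]], clusters[[j]]])
      if (val < best_val) { best_val <- val; best <- c(i, j) }
    }
    heights <- c(heights, best_val)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Exhaustive betweenness: enumerate every shortest path between every
# unordered pair by depth-first search over the BFS level structure.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  bfs_dist <- function(s) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] > 0)
      for (w in nb) if (dist[w] == Inf) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
    }
    dist
  }
  all_paths <- function(s, t, dist) {
    # enumerate all shortest s->t paths walking backwards from t
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1L]] <<- c(s, rev(acc)); return() }
      preds <- which(adj[v, ] > 0 & dist == dist[v] - 1)
      for (p in preds) walk(p, c(acc, v))
    }
    walk(t, integer(0))
    paths
  }
  for (s in seq_len(n - 1)) {
    dist <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (!is.finite(dist[t])) next
      paths <- all_paths(s, t, dist)
      if (!length(paths)) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        bc[inner] <- bc[inner] + 1 / length(paths)
      }
    }
  }
  names(bc) <- rownames(adj)
  bc
}

# Upper-tail hypergeometric by direct combinatorial enumeration.
brute_hyper_tail <- function(k_obs, set_size, bg_size, module_size) {
  ks <- k_obs:min(set_size, module_size)
  sum(choose(set_size, ks) * choose(bg_size - set_size, module_size - ks)) /
    choose(bg_size, module_size)
}

# A random symmetric adjacency in [0,1] with unit diagonal.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# A small two-group expression fixture with optional mean shifts.
toy_expression <- function(n_genes = 5, n_ref = 3, n_test = 3, seed = 1,
                           shift = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * (n_ref + n_test)), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              c(sprintf("r%d", seq_len(n_ref)),
                                sprintf("t%d", seq_len(n_test)))))
  if (!is.null(shift)) x[seq_along(shift), n_ref + seq_len(n_test)] <-
      x[seq_along(shift), n_ref + seq_len(n_test)] + shift
  groups <- coexdiff:::sample_groups(colnames(x),
                                     rep(c("ctrl", "case"), c(n_ref, n_test)),
                                     reference = "ctrl")
  list(expr = x, groups = groups)
}

# Wrap a hand-built adjacency/correlation pair as a network object.
toy_network <- function(adjacency, correlation = NULL, tom = NULL, beta = 1L) {
  structure(list(gene_ids = rownames(adjacency),
                 correlation = correlation %||% adjacency,
                 adjacency = adjacency,
                 tom = tom %||% adjacency, beta = beta),
            class = "coexpression_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
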