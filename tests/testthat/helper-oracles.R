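# Independent oracles used across the suite. Each reimplements the quantity
# it checks by the most transparent possible route (brute force, enumeration,
# closed form), never by calling the code under test.

# Kruskal's algorithm, plain union-find over the complete graph.
kruskal_total_weight <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[upper.tri(d)])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  total <- 0; taken <- 0L
  for (e in ord) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      total <- total + d[i, j]
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  total
}

# all-pairs BFS diameter on an adjacency matrix
bfs_diameter <- function(a) {
  n <- nrow(a)
  best <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(a[v, ] > 0 & is.na(dist))
      dist[nb] <- dist[v] + 1L
      queue <- c(queue, nb)
    }
    best <- max(best, max(dist))
  }
  best
}

# triple-loop topological overlap for an unweighted tree adjacency
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- matrix(1, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
      out[i, j] <- (l + a[i, j]) / (min(sum(a[i, ]), sum(a[j, ])) + 1 - a[i, j])
    }
  }
  out
}

# all 16 labeled spanning trees on 4 nodes, as edge matrices, via Pruefer
# enumeration (sequences of length 2 over 4 labels)
all_trees_4 <- function() {
  decode <- function(pruefer, n = 4L) {
    degree <- rep(1L, n)
    for (x in pruefer) degree[x] <- degree[x] + 1L
    edges <- matrix(0L, n - 1, 2)
    k <- 0L
    for (x in pruefer) {
      leaf <- min(which(degree == 1L))
      k <- k + 1L
      edges[k, ] <- c(leaf, x)
      degree[leaf] <- degree[leaf] - 1L
      degree[x] <- degree[x] - 1L
    }
    edges[n - 1, ] <- which(degree == 1L)
    edges
  }
  out <- list()
  for (p1 in 1:4) for (p2 in 1:4) out[[length(out) + 1]] <- decode(c(p1, p2))
  out
}

# canonical string key of a tree's edge set (for counting topologies)
tree_key <- function(edges_idx) {
  e <- t(apply(edges_idx, 1, sort))
  paste(sort(paste(e[, 1], e[, 2], sep = "-")), collapse = "|")
}

# random expression-like matrix with dimnames
rand_expr <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
           dimnames = list(paste0("g", seq_len(n_genes)),
                           paste0("s", seq_len(n_samples))))
  })
}

# k planted patterns equally spaced on a circle in a random 2-plane of
# zero-mean sample space: for k = 3 the patterns sum to zero with pairwise
# correlation -0.5, so a cluster mixing two patterns has a center its
# members correlate with at only 0.5 and keeps being split
planted_patterns <- function(k, n_samples, seed = 1) {
  withr::with_seed(seed, {
    m <- scale(matrix(rnorm(n_samples * 2), n_samples, 2), scale = FALSE)
    q <- qr.Q(qr(m))
    ang <- 2 * pi * (seq_len(k) - 1) / k
    p <- cbind(cos(ang), sin(ang)) %*% t(q)
    rownames(p) <- paste0("pat", seq_len(k))
    p
  })
}

# star-recovery check used by selection/evaluation/acceptance tests
is_planted_star <- function(tree, truth) {
  a <- tree_adjacency(tree)
  deg <- rowSums(a)
  if (sum(deg == 3) != 1 || max(deg) != 3) return(FALSE)
  hub <- names(deg)[deg == 3]
  if (hub != truth$root) return(FALSE)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  comp <- igraph::components(igraph::delete_vertices(g, hub))$membership
  got <- split(names(comp), comp)
  all(vapply(truth$arms, function(x) {
    any(vapply(got, function(y) setequal(x, y), logical(1)))
  }, logical(1)))
}

# Rand index between two partitions given as membership vectors
rand_index <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  mean(same_x == same_y)
}
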