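#' Sample trees
#'
#' A `sample_tree` is an undirected, connected, acyclic weighted graph whose
#' nodes are samples: the representation used for per-module minimum spanning
#' trees, reference path trees and random null trees. A tree on `n` samples
#' has exactly `n - 1` edges.
#'
#' @param sample_ids Character vector of unique sample ids (the node set).
#' @param edges Data frame with columns `from`, `to`, `weight`; one row per
#'   undirected edge.
#' @return An object of class `sample_tree` with fields `sample_ids` and
#'   `edges`.
#' @export
#' @examples
#' tr <- sample_tree(c("a", "b", "c"),
#'                   data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1))
#' tree_diameter(tr)
sample_tree <- function(sample_ids, edges) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in tree", call. = FALSE)
  edges <- data.frame(
    from = as.character(edges$from),
    to = as.character(edges$to),
    weight = as.numeric(edges$weight),
    stringsAsFactors = FALSE
  )
  n <- length(sample_ids)
  if (n >= 2) {
    if (nrow(edges) != n - 1) {
      stop(sprintf("a tree on %d samples must have %d edges, got %d",
                   n, n - 1, nrow(edges)), call. = FALSE)
    }
    bad <- setdiff(c(edges$from, edges$to), sample_ids)
    if (length(bad)) stop("edge endpoints not in sample_ids: ", paste(bad, collapse = ", "), call. = FALSE)
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                       vertices = sample_ids)
    if (!igraph::is_connected(g) || igraph::any_loop(g) || igraph::any_multiple(g)) {
      stop("edges do not form a tree (disconnected, self-loop or multi-edge)", call. = FALSE)
    }
  } else if (nrow(edges) != 0) {
    stop("single-node tree must have no edges", call. = FALSE)
  }
  structure(list(sample_ids = sample_ids, edges = edges), class = "sample_tree")
}

#' @export
print.sample_tree <- function(x, ...) {
  cat(sprintf("sample_tree: %d samples, %d edges, total weight %.4g\n",
              length(x$sample_ids), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

as_igraph <- function(tree) {
  g <- igraph::graph_from_data_frame(tree$edges[, c("from", "to")], directed = FALSE,
                                     vertices = tree$sample_ids)
  igraph::E(g)$weight <- tree$edges$weight
  g
}

#' Binary adjacency matrix of a tree
#'
#' @param tree A [sample_tree()].
#' @return Symmetric 0/1 matrix with zero diagonal, rows/columns ordered and
#'   named by `tree$sample_ids`.
#' @export
tree_adjacency <- function(tree) {
  ids <- tree$sample_ids
  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(tree$edges)) {
    i <- match(tree$edges$from, ids)
    j <- match(tree$edges$to, ids)
    a[cbind(i, j)] <- 1L
    a[cbind(j, i)] <- 1L
  }
  a
}

#' Per-module sample distance matrix
#'
#' Euclidean distances between sample expression profiles restricted to a
#' module's genes, computed on the row-standardized matrix (each gene scaled
#' to mean 0, sd 1 across samples) so no single high-magnitude gene dominates.
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param gene_ids Character vector of module member genes (subset of
#'   `rownames(expr)`).
#' @param standardize Standardize gene rows first (default `TRUE`).
#' @return Symmetric samples x samples distance matrix with zero diagonal.
#' @export
module_distance_matrix <- function(expr, gene_ids, standardize = TRUE) {
  assert_expression_matrix(expr)
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) stop("empty module: no genes to compute distances on", call. = FALSE)
  missing <- setdiff(gene_ids, rownames(expr))
  if (length(missing)) stop("module genes not in matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  m <- expr[gene_ids, , drop = FALSE]
  if (standardize) m <- standardize_rows(m)
  d <- as.matrix(stats::dist(t(m)))
  dimnames(d) <- list(colnames(expr), colnames(expr))
  d
}

# pick the index of a minimum entry; ties broken by smallest (row, col) pair
min_entry_index <- function(mat) {
  idx <- which(mat == min(mat), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  idx[1, ]
}

#' Minimum spanning tree over samples
#'
#' Grows an MST component-by-component: starting from the all-singleton
#' forest, each iteration picks one of the currently smallest components
#' (ties resolved uniformly at random under `seed`), computes its
#' single-linkage distance to every other component, and adds the minimising
#' edge. The result attains the minimum total spanning weight of the complete
#' graph on `d`.
#'
#' @param d Symmetric sample distance matrix with dimnames (see
#'   [module_distance_matrix()]).
#' @param seed Integer seed controlling the (inconsequential for total
#'   weight) random choice among equally small components.
#' @return A [sample_tree()] whose edge weights are the corresponding `d`
#'   entries.
#' @export
#' @examples
#' x <- matrix(c(0, 1, 3, 7), 1, dimnames = list("g1", paste0("s", 1:4)))
#' d <- as.matrix(dist(t(rbind(x, x))))  # two identical genes
#' boruvka_mst(d, seed = 1)
boruvka_mst <- function(d, seed = 1L) {
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must have sample dimnames", call. = FALSE)
  n <- nrow(d)
  if (n == 1) {
    warning("single-sample input: returning an edgeless tree")
    return(sample_tree(ids, data.frame(from = character(), to = character(), weight = numeric())))
  }
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(d < 0)) {
    stop("`d` must be symmetric and non-negative with a zero diagonal", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    comp <- seq_len(n)              # component label per sample
    edges_i <- integer(n - 1)
    edges_j <- integer(n - 1)
    for (step in seq_len(n - 1)) {
      sizes <- table(comp)
      small_labels <- as.integer(names(sizes)[sizes == min(sizes)])
      pick <- if (length(small_labels) == 1) small_labels else {
        small_labels[sample.int(length(small_labels), 1)]
      }
      inside <- which(comp == pick)
      outside <- which(comp != pick)
      sub <- d[inside, outside, drop = FALSE]
      best <- min_entry_index(sub)
      i <- inside[best[1]]
      j <- outside[best[2]]
      edges_i[step] <- min(i, j)
      edges_j[step] <- max(i, j)
      comp[comp == comp[j]] <- comp[i]
    }
    sample_tree(ids, data.frame(from = ids[edges_i], to = ids[edges_j],
                                weight = d[cbind(edges_i, edges_j)]))
  })
}

#' Tree diameter
#'
#' Number of edges on the longest shortest path between any two nodes: a
#' path on `n` samples has diameter `n - 1`, a star has diameter 2. Used as a
#' path-likeness statistic for recovered progressions.
#'
#' @param tree A [sample_tree()].
#' @return Integer diameter (0 for a single-node tree).
#' @export
tree_diameter <- function(tree) {
  if (length(tree$sample_ids) < 2) return(0L)
  g <- as_igraph(tree)
  as.integer(igraph::diameter(g, weights = NA))
}

#' Path tree from a sample ordering
#'
#' Represents a known sample ordering (e.g. the true time order of a series)
#' as a unit-weight path graph, the comparator used when evaluating recovered
#' progressions.
#'
#' @param sample_order Character vector of unique sample ids in order.
#' @return A [sample_tree()] connecting consecutive samples with weight 1.
#' @export
path_tree <- function(sample_order) {
  sample_order <- as.character(sample_order)
  if (length(sample_order) < 2) stop("need at least 2 samples", call. = FALSE)
  if (anyDuplicated(sample_order)) stop("duplicate sample ids in ordering", call. = FALSE)
  k <- length(sample_order)
  sample_tree(sample_order,
              data.frame(from = sample_order[-k], to = sample_order[-1], weight = 1))
}

#' Uniformly random labeled tree
#'
#' Draws a spanning tree uniformly over all `n^(n-2)` labeled trees on `n`
#' nodes (Pruefer-sequence sampling), the exchangeable null model for tree
#' topologies. Edges carry unit weights.
#'
#' @param n Number of nodes (>= 2).
#' @param seed Integer seed.
#' @param sample_ids Optional node names; defaults to `t1..tn`.
#' @return A [sample_tree()].
#' @export
random_spanning_tree <- function(n, seed = 1L, sample_ids = NULL) {
  n <- as.integer(n)
  if (n < 2) stop("need n >= 2 nodes", call. = FALSE)
  ids <- sample_ids %||% paste0("t", seq_len(n))
  withr::with_seed(as.integer(seed), {
    g <- igraph::sample_tree(n, method = "prufer")
    el <- igraph::as_edgelist(g, names = FALSE)
    sample_tree(ids, data.frame(from = ids[el[, 1]], to = ids[el[, 2]], weight = 1))
  })
}
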