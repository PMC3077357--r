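#' Topological overlap matrix of a tree
#'
#' For the unweighted adjacency `A` of a tree, the topological overlap of
#' nodes `i != j` is `(l_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij)`, where
#' `l_ij` counts shared neighbours and `k_i` is the node degree; the diagonal
#' is 1. Two nodes overlap strongly when they are adjacent or share
#' neighbours, so the matrix captures local topology and is comparable
#' between trees on the same samples.
#'
#' @param tree A [sample_tree()] with at least 2 nodes.
#' @return Symmetric numeric matrix with unit diagonal, dimnames =
#'   sample ids.
#' @export
tom_matrix <- function(tree) {
  a <- tree_adjacency(tree)
  if (nrow(a) < 2) stop("need a tree on >= 2 samples", call. = FALSE)
  storage.mode(a) <- "double"
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Topological overlap distance between two trees
#'
#' L1 distance between topological overlap matrices, summed over unordered
#' node pairs. Zero exactly when the two trees have identical adjacency;
#' symmetric in its arguments. Used to compare a recovered progression tree
#' with a reference ordering (as a unit-weight [path_tree()]).
#'
#' @param tree_a,tree_b [sample_tree()]s over the same sample set.
#' @return List with `distance`, and the echoed `tree_a_id`/`tree_b_id`.
#' @param tree_a_id,tree_b_id Optional labels carried into the report.
#' @export
tom_distance <- function(tree_a, tree_b, tree_a_id = "tree_a", tree_b_id = "tree_b") {
  if (!setequal(tree_a$sample_ids, tree_b$sample_ids) ||
      length(tree_a$sample_ids) != length(tree_b$sample_ids)) {
    stop("trees are over different sample sets", call. = FALSE)
  }
  ids <- sort(tree_a$sample_ids)
  ta <- tom_matrix(tree_a)[ids, ids]
  tb <- tom_matrix(tree_b)[ids, ids]
  diffs <- abs(ta - tb)
  list(distance = sum(diffs[upper.tri(diffs)]),
       tree_a_id = tree_a_id, tree_b_id = tree_b_id)
}

#' Random-tree null distribution
#'
#' Draws uniformly random labeled trees on the reference tree's samples and
#' summarises (i) their topological overlap distance to the reference and
#' (ii) their diameters, together with the empirical probability that a
#' random tree's diameter is at least `query_diameter`. A recovered
#' progression whose diameter is improbably large under this null is
#' path-like beyond chance.
#'
#' @param reference A [sample_tree()] (e.g. the true sample order as a path).
#' @param n_trees Number of random trees (default 1000).
#' @param seed Integer seed.
#' @param query_diameter Diameter whose null exceedance probability is
#'   reported; defaults to the reference tree's own diameter.
#' @return List with `tom_distances`, `diameters`, their means and sds, and
#'   `p_diameter_ge` = P(random diameter >= query_diameter).
#' @export
random_tree_null <- function(reference, n_trees = 1000L, seed = 1L,
                             query_diameter = NULL) {
  n <- length(reference$sample_ids)
  if (n < 2) stop("reference tree needs >= 2 samples", call. = FALSE)
  query_diameter <- query_diameter %||% tree_diameter(reference)
  seeds <- derive_seeds(seed, n_trees, stream = 303L)
  tomd <- numeric(n_trees)
  diam <- integer(n_trees)
  for (b in seq_len(n_trees)) {
    tr <- random_spanning_tree(n, seed = seeds[b], sample_ids = reference$sample_ids)
    tomd[b] <- tom_distance(tr, reference)$distance
    diam[b] <- tree_diameter(tr)
  }
  list(tom_distances = tomd, diameters = diam,
       tom_mean = mean(tomd), tom_sd = stats::sd(tomd),
       diameter_mean = mean(diam), diameter_sd = stats::sd(diam),
       query_diameter = query_diameter,
       p_diameter_ge = mean(diam >= query_diameter))
}

#' Bootstrap robustness of the recovered progression
#'
#' Repeatedly subsamples a fraction of the genes without replacement, reruns
#' the full pipeline (clustering, per-module MSTs, concordance, module
#' selection, overall MST) on the subsample, and records the topological
#' overlap distance between each bootstrap tree and the reference ordering.
#' Small, stable distances across iterations indicate the progression does
#' not hinge on particular genes.
#'
#' @param expr The full genes x samples matrix.
#' @param cfg An [spd_config()].
#' @param reference_order Character vector: the reference sample ordering.
#' @param gene_fraction Fraction of genes drawn per iteration (default 0.9).
#' @param n_iterations Number of bootstrap iterations (default 100).
#' @param selection `"rerun-auto"` reruns [auto_select_block()] inside each
#'   iteration (manual selection is impossible in a loop); `"fixed"` reuses
#'   `fixed_ids` against each iteration's module ids.
#' @param fixed_ids Module ids for `selection = "fixed"`.
#' @param min_block Passed to [auto_select_block()].
#' @param seed Integer root seed.
#' @return List of class `bootstrap_report`: `tom_distances` (NA where an
#'   iteration failed), `mean`, `sd`, `n_iterations`, `gene_fraction`,
#'   `selection`.
#' @export
bootstrap_spd <- function(expr, cfg = spd_config(), reference_order,
                          gene_fraction = 0.9, n_iterations = 100L,
                          selection = c("rerun-auto", "fixed"), fixed_ids = NULL,
                          min_block = 2L, seed = 1L) {
  assert_expression_matrix(expr)
  selection <- match.arg(selection)
  if (gene_fraction <= 0 || gene_fraction > 1) stop("gene_fraction must be in (0, 1]", call. = FALSE)
  reference <- path_tree(reference_order)
  n_genes <- nrow(expr)
  keep_n <- max(2L, round(gene_fraction * n_genes))
  subsample_seeds <- derive_seeds(seed, n_iterations, stream = 404L)
  run_seeds <- derive_seeds(seed, n_iterations, stream = 405L)
  tomd <- rep(NA_real_, n_iterations)
  for (b in seq_len(n_iterations)) {
    genes <- if (keep_n == n_genes) rownames(expr) else {
      withr::with_seed(subsample_seeds[b],
                       sort(sample.int(n_genes, keep_n)))
    }
    sub <- expr[genes, , drop = FALSE]
    cfg_b <- cfg
    cfg_b$seed <- run_seeds[b]
    res <- tryCatch({
      fit <- run_spd(sub, cfg_b,
                     select = if (selection == "fixed") fixed_ids else NULL,
                     auto_select = selection == "rerun-auto",
                     min_block = min_block)
      tom_distance(fit$overall_tree, reference)$distance
    }, error = function(e) NA_real_)
    tomd[b] <- res
  }
  structure(list(tom_distances = tomd,
                 mean = mean(tomd, na.rm = TRUE),
                 sd = stats::sd(tomd[!is.na(tomd)]),
                 n_iterations = as.integer(n_iterations),
                 gene_fraction = gene_fraction,
                 selection = selection),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("bootstrap_report: %d iterations (%.0f%% of genes, %s selection)\n",
              x$n_iterations, 100 * x$gene_fraction, x$selection))
  cat(sprintf("  TOM distance to reference: mean %.4g, sd %.4g, %d failed\n",
              x$mean, x$sd, sum(is.na(x$tom_distances))))
  invisible(x)
}
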