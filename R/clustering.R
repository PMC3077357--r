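#' Gene module discovery by iterative consensus k-means
#'
#' Genes are partitioned by divisive bisection: each cluster is split in two
#' by a consensus over many random-restart 2-means runs, recursing until the
#' cluster is coherent (average gene-to-center Pearson correlation at or
#' above `coherence_threshold`), has a single gene, or cannot be split.
#' Highly correlated modules are then merged to a fixpoint, and modules
#' smaller than `min_module_size` are set aside as unassigned. Gene rows are
#' z-scored before clustering so Euclidean 2-means is not dominated by
#' expression magnitude.
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param cfg An [spd_config()]; `kmeans_runs`, `coherence_threshold`,
#'   `merge_threshold`, `min_module_size` and `seed` are used.
#' @return A `module_set`: list with `modules` (named list of gene-id
#'   vectors, names `M1`, `M2`, ...), `coherence` (named numeric) and
#'   `unassigned` (character vector of genes in undersized modules).
#' @seealso [module_coherence()], [consensus_split()], [merge_modules()]
#' @export
iterative_consensus_cluster <- function(expr, cfg = spd_config()) {
  assert_expression_matrix(expr)
  cfg <- validate_config(cfg)
  z <- standardize_rows(expr)
  split_seeds <- derive_seeds(cfg$seed, 4 * nrow(expr) + 8, stream = 101L)
  counter <- 0L

  leaves <- list()
  stack <- list(rownames(expr))
  while (length(stack)) {
    genes <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sub <- z[genes, , drop = FALSE]
    coh <- if (length(genes) == 1) 1 else tryCatch(module_coherence(sub),
                                                   spd_degenerate_module = function(e) -Inf)
    if (length(genes) == 1 || coh >= cfg$coherence_threshold) {
      leaves[[length(leaves) + 1L]] <- list(gene_ids = genes, coherence = coh)
      next
    }
    counter <- counter + 1L
    parts <- tryCatch(
      consensus_split(sub, runs = cfg$kmeans_runs, seed = split_seeds[counter]),
      spd_split_failure = function(e) NULL
    )
    if (is.null(parts)) {
      leaves[[length(leaves) + 1L]] <- list(gene_ids = genes, coherence = coh)
    } else {
      # depth-first, left part processed first for determinism
      stack[[length(stack) + 1L]] <- parts[[2]]
      stack[[length(stack) + 1L]] <- parts[[1]]
    }
  }

  ms <- new_module_set(lapply(leaves, `[[`, "gene_ids"),
                       vapply(leaves, `[[`, numeric(1), "coherence"),
                       unassigned = character())
  ms <- merge_modules(ms, expr, cfg$merge_threshold)
  apply_min_size(ms, cfg$min_module_size)
}

new_module_set <- function(gene_lists, coherence, unassigned) {
  names(gene_lists) <- paste0("M", seq_along(gene_lists))
  names(coherence) <- names(gene_lists)
  structure(list(modules = gene_lists, coherence = coherence,
                 unassigned = as.character(unassigned)),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules (%d genes), %d unassigned genes\n",
              length(x$modules), sum(lengths(x$modules)), length(x$unassigned)))
  if (length(x$modules)) {
    smry <- sprintf("  %s: %d genes, coherence %.3f", names(x$modules),
                    lengths(x$modules), x$coherence)
    cat(paste(utils::head(smry, 10), collapse = "\n"), "\n")
    if (length(smry) > 10) cat(sprintf("  ... and %d more\n", length(smry) - 10))
  }
  invisible(x)
}

apply_min_size <- function(ms, min_module_size) {
  small <- lengths(ms$modules) < min_module_size
  unassigned <- c(ms$unassigned, unlist(ms$modules[small], use.names = FALSE))
  new_module_set(unname(ms$modules[!small]), unname(ms$coherence[!small]), unassigned)
}

#' Module coherence
#'
#' Average Pearson correlation between each gene in a cluster and the
#' cluster's per-sample mean profile. A single-gene cluster has coherence 1.
#' If the cluster mean is constant across samples (e.g. two perfectly
#' anti-correlated genes) the cluster has no common profile and a
#' `spd_degenerate_module` error is raised; callers treat such clusters as
#' incoherent.
#'
#' @param expr_module Numeric matrix of the cluster's gene rows (genes x
#'   samples).
#' @return Coherence in \[-1, 1\].
#' @export
module_coherence <- function(expr_module) {
  if (!is.matrix(expr_module) || nrow(expr_module) < 1) {
    stop("need a genes x samples matrix with >= 1 gene", call. = FALSE)
  }
  center <- colMeans(expr_module)
  if (stats::sd(center) == 0) {
    stop(structure(class = c("spd_degenerate_module", "error", "condition"),
                   list(message = "cluster mean is constant across samples",
                        call = sys.call(-1))))
  }
  if (nrow(expr_module) == 1) return(1)
  mean(apply(expr_module, 1, safe_cor, y = center))
}

# Lloyd's 2-means under the caller's RNG state. Initial centers are two
# distinct data rows; an emptied cluster is re-seeded at the point farthest
# from the surviving center, so both sides of the bipartition stay non-empty.
kmeans2 <- function(x, max_iter = 100L) {
  n <- nrow(x)
  stopifnot(n >= 2)
  first <- sample.int(n, 1)
  diffs <- sweep(x, 2, x[first, ])
  distinct <- which(rowSums(diffs^2) > 0)
  if (!length(distinct)) stop_split_failure()
  second <- if (length(distinct) == 1) distinct else distinct[sample.int(length(distinct), 1)]
  ctr <- x[c(first, second), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d1 <- rowSums(sweep(x, 2, ctr[1, ])^2)
    d2 <- rowSums(sweep(x, 2, ctr[2, ])^2)
    lab <- ifelse(d2 < d1, 2L, 1L)
    for (k in 1:2) {
      if (!any(lab == k)) {
        far <- which.max(if (k == 1) d2 else d1)
        lab[far] <- k
      }
    }
    if (identical(lab, assign_old)) break
    assign_old <- lab
    ctr <- rbind(colMeans(x[lab == 1L, , drop = FALSE]),
                 colMeans(x[lab == 2L, , drop = FALSE]))
  }
  lab
}

stop_split_failure <- function() {
  stop(structure(class = c("spd_split_failure", "error", "condition"),
                 list(message = "all gene rows identical; cluster cannot be split",
                      call = sys.call(-1))))
}

#' Consensus bipartition of a gene cluster
#'
#' Runs 2-means `runs` times with random initialization on the gene rows,
#' collects the 0/1 labels into a genes x runs matrix, and applies 2-means
#' once more to the rows of that label matrix: genes that co-segregate across
#' runs land on the same side regardless of any per-run label flip (a global
#' 0/1 swap of one column is a rigid transformation of all label vectors).
#'
#' @param expr_cluster Numeric matrix of the cluster's gene rows (callers
#'   standardize rows first; [iterative_consensus_cluster()] does).
#' @param runs Number of pooled k-means runs.
#' @param seed Integer seed; the split is deterministic given it.
#' @return List of two non-empty character vectors of gene ids.
#' @export
consensus_split <- function(expr_cluster, runs = 50L, seed = 1L) {
  stopifnot(is.matrix(expr_cluster), nrow(expr_cluster) >= 2, runs >= 1)
  if (all(rowSums(sweep(expr_cluster, 2, expr_cluster[1, ])^2) == 0)) stop_split_failure()
  withr::with_seed(as.integer(seed), {
    labels <- matrix(0L, nrow(expr_cluster), runs)
    for (r in seq_len(runs)) labels[, r] <- kmeans2(expr_cluster) - 1L
    consensus <- if (runs == 1L) labels[, 1] + 1L else kmeans2(labels)
    genes <- rownames(expr_cluster)
    list(genes[consensus == 1L], genes[consensus == 2L])
  })
}

module_centers <- function(z, gene_lists) {
  t(vapply(gene_lists, function(g) colMeans(z[g, , drop = FALSE]), numeric(ncol(z))))
}

#' Merge highly correlated modules
#'
#' Repeatedly merges the module pair whose centers (per-sample means of the
#' standardized member rows) have the highest Pearson correlation, as long as
#' that correlation exceeds `merge_threshold`; centers and coherences are
#' recomputed after every merge. At the fixpoint no pair of module centers
#' correlates above the threshold.
#'
#' @param modules A `module_set`.
#' @param expr The full genes x samples matrix the modules were derived from.
#' @param merge_threshold Center correlation above which modules merge.
#' @return A `module_set` (module ids renumbered).
#' @export
merge_modules <- function(modules, expr, merge_threshold = 0.9) {
  stopifnot(inherits(modules, "module_set"))
  assert_expression_matrix(expr)
  z <- standardize_rows(expr)
  gene_lists <- unname(modules$modules)
  repeat {
    if (length(gene_lists) < 2) break
    centers <- module_centers(z, gene_lists)
    cc <- suppressWarnings(stats::cor(t(centers)))
    cc[is.na(cc)] <- 0
    diag(cc) <- -Inf
    best <- max(cc)
    if (best <= merge_threshold) break
    pair <- min_entry_index(-cc)   # highest correlation; ties -> smallest indices
    i <- min(pair); j <- max(pair)
    gene_lists[[i]] <- c(gene_lists[[i]], gene_lists[[j]])
    gene_lists[[j]] <- NULL
  }
  coherence <- vapply(gene_lists, function(g) {
    if (length(g) == 1) 1 else tryCatch(module_coherence(z[g, , drop = FALSE]),
                                        spd_degenerate_module = function(e) NA_real_)
  }, numeric(1))
  new_module_set(gene_lists, coherence, modules$unassigned)
}
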