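#' Concordance statistic between a distance matrix and a tree
#'
#' The total edge weight jointly defined by a gene module and a tree: the sum
#' over tree edges `(i, j)` of the module's sample distance `d[i, j]`
#' (equivalently `sum(A * D) / 2` for adjacency `A`). Small values mean the
#' tree connects samples that the module places close together, i.e. the
#' module's gradual expression change is concordant with the tree's
#' progression. Only closeness along edges is scored; distances between
#' unconnected samples are deliberately ignored so that progressions that
#' drift away from an initial state and return (e.g. the cell cycle) are not
#' penalised.
#'
#' @param d Symmetric sample distance matrix with dimnames.
#' @param tree A [sample_tree()] on exactly the same sample set.
#' @return Non-negative scalar.
#' @export
concordance_statistic <- function(d, tree) {
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must have sample dimnames", call. = FALSE)
  if (!setequal(ids, tree$sample_ids) || length(ids) != length(tree$sample_ids)) {
    stop("distance matrix and tree are over different sample sets", call. = FALSE)
  }
  i <- match(tree$edges$from, ids)
  j <- match(tree$edges$to, ids)
  sum(d[cbind(i, j)])
}

#' Permutation p-value for module-tree concordance
#'
#' Tests whether the observed concordance statistic is smaller than expected
#' when the link between samples' expression profiles and their tree
#' positions is broken. Each permutation relabels the samples of the module's
#' distance matrix uniformly at random (equivalent to permuting the columns
#' of the module's expression data) and recomputes the statistic against the
#' fixed tree. The p-value is `(1 + b) / (1 + n_perm)` where `b` counts
#' permutations with a strictly smaller statistic; the add-one smoothing
#' keeps p positive while leaving the conventional 0.002 threshold attainable
#' at 1000 permutations (p = 1/1001).
#'
#' @param module_expr Module gene rows (genes x samples matrix), or a
#'   precomputed distance matrix via `d`.
#' @param tree A [sample_tree()] over the same samples.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; p-values are reproducible given it.
#' @param d Optional distance matrix overriding `module_expr`.
#' @return P-value in (0, 1\].
#' @export
permutation_pvalue <- function(module_expr = NULL, tree, n_perm = 1000L, seed = 1L,
                               d = NULL) {
  if (is.null(d)) {
    stopifnot(is.matrix(module_expr))
    z <- standardize_rows(module_expr)
    d <- as.matrix(stats::dist(t(z)))
    dimnames(d) <- list(colnames(module_expr), colnames(module_expr))
  }
  ids <- rownames(d)
  n <- nrow(d)
  off <- d[upper.tri(d)]
  if (length(unique(off)) == 1) {
    warning("degenerate distance matrix (all off-diagonal entries equal); p = 1")
    return(1)
  }
  observed <- concordance_statistic(d, tree)
  ei <- match(tree$edges$from, ids)
  ej <- match(tree$edges$to, ids)
  withr::with_seed(as.integer(seed), {
    smaller <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      if (sum(d[cbind(p[ei], p[ej])]) < observed) smaller <- smaller + 1L
    }
    (1 + smaller) / (1 + n_perm)
  })
}

#' Progression similarity between gene modules
#'
#' Scores every module against every module's tree with the permutation
#' concordance test and counts, for each module pair `(i, j)`, the number of
#' trees concordant with both. A tree is concordant with a module when its
#' permutation p-value falls below `cfg$p_threshold`; each tree is concordant
#' with its own module by construction (the test result is still recorded).
#' Modules sharing many concordant trees support a common progression even
#' when their expression profiles are uncorrelated.
#'
#' @param modules A `module_set` from [iterative_consensus_cluster()].
#' @param trees Named list of [sample_tree()]s, one per module (names match
#'   module ids); typically each module's own MST from [boruvka_mst()].
#' @param expr The full genes x samples matrix.
#' @param cfg An [spd_config()]; `n_permutations`, `p_threshold` and `seed`
#'   are used.
#' @param shared_permutations Reuse one permutation stream for every
#'   (module, tree) pair instead of drawing independent streams (default
#'   `FALSE`; independent draws are the canonical behaviour, sharing cuts
#'   cost for large module counts).
#' @return An object of class `progression_similarity`: list with
#'   `module_ids`, integer matrix `S`, and `records`, a data frame with one
#'   row per (module, tree) pair and columns `module_id`, `tree_id`,
#'   `statistic`, `p_value`, `concordant`.
#' @export
progression_similarity <- function(modules, trees, expr, cfg = spd_config(),
                                   shared_permutations = FALSE) {
  stopifnot(inherits(modules, "module_set"))
  cfg <- validate_config(cfg)
  ids <- names(modules$modules)
  if (!setequal(names(trees), ids)) stop("trees must be named by module id", call. = FALSE)
  m <- length(ids)
  z <- standardize_rows(expr)
  dmats <- lapply(modules$modules, function(g) {
    d <- as.matrix(stats::dist(t(z[g, , drop = FALSE])))
    dimnames(d) <- list(colnames(expr), colnames(expr))
    d
  })
  pair_seeds <- if (shared_permutations) {
    matrix(derive_seeds(cfg$seed, 1, stream = 202L), m, m)
  } else {
    matrix(derive_seeds(cfg$seed, m * m, stream = 202L), m, m)
  }
  records <- vector("list", m * m)
  concord <- matrix(FALSE, m, m, dimnames = list(ids, ids))  # [module, tree]
  k <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      k <- k + 1L
      stat <- concordance_statistic(dmats[[i]], trees[[ids[j]]])
      pv <- suppressWarnings(
        permutation_pvalue(d = dmats[[i]], tree = trees[[ids[j]]],
                           n_perm = cfg$n_permutations, seed = pair_seeds[i, j])
      )
      conc <- if (i == j) TRUE else pv < cfg$p_threshold
      concord[i, j] <- conc
      records[[k]] <- data.frame(module_id = ids[i], tree_id = ids[j],
                                 statistic = stat, p_value = pv, concordant = conc)
    }
  }
  S <- matrix(0L, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      S[i, j] <- sum(concord[i, ] & concord[j, ])
    }
  }
  structure(list(module_ids = ids, S = S, records = do.call(rbind, records)),
            class = "progression_similarity")
}

#' @export
print.progression_similarity <- function(x, ...) {
  cat(sprintf("progression_similarity: %d modules; %d concordant (module, tree) pairs\n",
              length(x$module_ids), sum(x$records$concordant)))
  invisible(x)
}

#' Write the concordance records and similarity matrix
#'
#' @param ps A [progression_similarity()] result.
#' @param records_path TSV path for the per-pair test records.
#' @param matrix_path TSV path for the module x module similarity counts.
#' @return `ps`, invisibly.
#' @export
write_similarity <- function(ps, records_path = NULL, matrix_path = NULL) {
  stopifnot(inherits(ps, "progression_similarity"))
  if (!is.null(records_path)) {
    utils::write.table(ps$records, records_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(matrix_path)) {
    df <- data.frame(module_id = rownames(ps$S), ps$S, check.names = FALSE)
    utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(ps)
}
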