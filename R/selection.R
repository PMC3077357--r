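#' Reorder the similarity matrix for inspection
#'
#' Average-linkage hierarchical clustering (Euclidean metric) of the columns
#' of the progression similarity matrix; the dendrogram leaf order places
#' mutually concordant modules in contiguous diagonal blocks, so a block of
#' uniformly high counts can be read off a heatmap and selected.
#'
#' @param S A [progression_similarity()] object or a named square numeric
#'   matrix.
#' @return Character vector: module ids in display order.
#' @export
reorder_similarity <- function(S) {
  S <- similarity_matrix(S)
  if (nrow(S) == 1) return(rownames(S))
  hc <- stats::hclust(stats::dist(t(S)), method = "average")
  rownames(S)[hc$order]
}

similarity_matrix <- function(S) {
  if (inherits(S, "progression_similarity")) S <- S$S
  if (!is.matrix(S) || nrow(S) != ncol(S) || is.null(rownames(S))) {
    stop("S must be a named square matrix or a progression_similarity object", call. = FALSE)
  }
  S
}

#' Record a manual module selection
#'
#' Module selection is by design a manual step: the analyst inspects the
#' reordered similarity matrix and picks a diagonal block of mutually
#' concordant modules. This helper only validates the chosen ids.
#'
#' @param S A [progression_similarity()] object or named square matrix.
#' @param module_ids Character vector of chosen module ids.
#' @return The validated (unique, input-ordered) id vector.
#' @export
select_modules <- function(S, module_ids) {
  S <- similarity_matrix(S)
  module_ids <- unique(as.character(module_ids))
  bad <- setdiff(module_ids, rownames(S))
  if (length(bad)) {
    stop(sprintf("unknown module id(s): %s (valid ids: %s)",
                 paste(bad, collapse = ", "), paste(rownames(S), collapse = ", ")),
         call. = FALSE)
  }
  if (!length(module_ids)) stop("no modules selected", call. = FALSE)
  module_ids
}

#' Heuristic block selection (advisory)
#'
#' Convenience substitute for manual inspection: after [reorder_similarity()],
#' returns the contiguous block of at least `min_block` modules that
#' maximises `block size * minimum entry` of its similarity submatrix,
#' preferring the larger block on ties. Weighting by size mirrors what an
#' analyst does with the heatmap -- take the largest diagonal block whose
#' entries are all clearly above background -- and avoids the degenerate
#' choice of a tight pair of mutually redundant modules, which spans too few
#' expression directions to pin down a progression. This heuristic is
#' advisory only; manual selection of a high-valued diagonal block is the
#' canonical procedure, and automated block finding is known to be fragile
#' across datasets.
#'
#' @param S A [progression_similarity()] object or named square matrix.
#' @param min_block Smallest admissible block size (default 2).
#' @return Character vector of module ids in the chosen block.
#' @export
auto_select_block <- function(S, min_block = 2L) {
  S <- similarity_matrix(S)
  ord <- reorder_similarity(S)
  m <- length(ord)
  min_block <- min(as.integer(min_block), m)
  So <- S[ord, ord, drop = FALSE]
  best <- NULL
  for (start in seq_len(m - min_block + 1L)) {
    for (end in seq(start + min_block - 1L, m)) {
      block <- So[start:end, start:end, drop = FALSE]
      size <- end - start + 1L
      score <- size * min(block)
      if (is.null(best) || score > best$score ||
          (score == best$score && size > best$size)) {
        best <- list(score = score, size = size, ids = ord[start:end])
      }
    }
  }
  best$ids
}

#' Overall MST over the selected modules' genes
#'
#' Builds the progression hypothesis: Euclidean sample distances over the
#' union of the selected modules' genes (standardized rows), then the minimum
#' spanning tree of that distance matrix.
#'
#' @param expr The full genes x samples matrix.
#' @param modules A `module_set`.
#' @param selected_ids Module ids whose genes are combined.
#' @param seed Integer seed passed to [boruvka_mst()].
#' @return A [sample_tree()].
#' @export
overall_mst <- function(expr, modules, selected_ids, seed = 1L) {
  stopifnot(inherits(modules, "module_set"))
  selected_ids <- unique(as.character(selected_ids))
  bad <- setdiff(selected_ids, names(modules$modules))
  if (length(bad)) stop("unknown module id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!length(selected_ids)) stop("no modules selected", call. = FALSE)
  genes <- unique(unlist(modules$modules[selected_ids], use.names = FALSE))
  if (!length(genes)) stop("selected modules contain no genes", call. = FALSE)
  d <- module_distance_matrix(expr, genes)
  boruvka_mst(d, seed = seed)
}
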