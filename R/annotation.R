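#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric probability of drawing at least the observed
#' number of gene-set members when `length(module_genes)` genes are sampled
#' without replacement from the universe: `P(X >= k)` with the observed
#' overlap included, no continuity correction. The gene set is intersected
#' with the universe before testing; a module gene outside the universe is
#' an error (it would silently inflate the background otherwise).
#'
#' @param module_genes Character vector of module gene ids.
#' @param set_genes Character vector of gene-set ids.
#' @param universe Character vector: the analysis universe (typically the
#'   post-filter gene set the modules were derived from).
#' @return P-value in (0, 1].
#' @export
#' @examples
#' # universe 20, set 5, module 5, full overlap: p = 1 / choose(20, 5)
#' u <- paste0("g", 1:20)
#' hypergeometric_enrichment(u[1:5], u[1:5], u)
hypergeometric_enrichment <- function(module_genes, set_genes, universe) {
  module_genes <- unique(as.character(module_genes))
  universe <- unique(as.character(universe))
  outside <- setdiff(module_genes, universe)
  if (length(outside)) {
    stop("module gene(s) outside the universe: ", paste(outside, collapse = ", "),
         call. = FALSE)
  }
  set_genes <- intersect(unique(as.character(set_genes)), universe)
  k <- length(intersect(module_genes, set_genes))
  stats::phyper(k - 1, m = length(set_genes),
                n = length(universe) - length(set_genes),
                k = length(module_genes), lower.tail = FALSE)
}

#' Enrichment of all modules against a gene-set collection
#'
#' Runs [hypergeometric_enrichment()] for every (module, gene set) pair.
#' Benjamini-Hochberg adjustment across sets (within each module) is
#' available but off by default, matching uncorrected reporting at a fixed
#' significance level.
#'
#' @param modules A `module_set`, or a named list of gene-id vectors.
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]).
#' @param universe Analysis universe; defaults to the union of module and
#'   unassigned genes.
#' @param adjust Apply BH adjustment across sets within each module?
#' @return Data frame with columns `module_id`, `set_name`, `overlap`, `p`,
#'   `adjusted_p` (NA unless `adjust = TRUE`), ordered by `p` within module.
#' @export
enrich_modules <- function(modules, gene_sets, universe = NULL, adjust = FALSE) {
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  stopifnot(is.list(mods), !is.null(names(mods)), is.list(gene_sets), !is.null(names(gene_sets)))
  universe <- universe %||% unique(c(unlist(mods, use.names = FALSE),
                                     if (inherits(modules, "module_set")) modules$unassigned))
  out <- do.call(rbind, lapply(names(mods), function(id) {
    p <- vapply(gene_sets, function(s) hypergeometric_enrichment(mods[[id]], s, universe),
                numeric(1))
    ov <- vapply(gene_sets, function(s) length(intersect(mods[[id]], intersect(s, universe))),
                 integer(1))
    df <- data.frame(module_id = id, set_name = names(gene_sets),
                     overlap = ov, p = p,
                     adjusted_p = if (adjust) stats::p.adjust(p, "BH") else NA_real_)
    df[order(df$p), ]
  }))
  rownames(out) <- NULL
  out
}
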