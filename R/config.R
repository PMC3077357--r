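#' Analysis configuration
#'
#' Bundles the tunable parameters of a progression-discovery run. Defaults
#' follow the method's standard operating point: 50 k-means restarts per
#' consensus split, cluster coherence threshold 0.7, module-merge correlation
#' threshold 0.9, minimum module size 5 genes, 1000 permutations with a
#' concordance p-value threshold of 0.002.
#'
#' @param kmeans_runs Number of random-restart k-means runs pooled into each
#'   consensus split (positive integer).
#' @param coherence_threshold Minimum average gene-to-center Pearson
#'   correlation for a cluster to be accepted as a coherent module, in (0, 1].
#' @param merge_threshold Module-center Pearson correlation above which two
#'   modules are merged, in (0, 1].
#' @param min_module_size Modules with fewer genes are set aside as
#'   unassigned (positive integer).
#' @param n_permutations Column permutations per concordance test.
#' @param p_threshold Permutation p-value below which a module and a tree are
#'   called concordant, in (0, 1).
#' @param top_n_variance_genes Keep only this many top-variance genes before
#'   clustering, or `"all"` to skip filtering.
#' @param seed Root seed; every random choice in a run derives from it.
#'
#' @return An object of class `spd_config` (a validated named list).
#' @export
#' @examples
#' cfg <- spd_config(seed = 7, n_permutations = 200)
#' cfg$p_threshold
spd_config <- function(kmeans_runs = 50L,
                       coherence_threshold = 0.7,
                       merge_threshold = 0.9,
                       min_module_size = 5L,
                       n_permutations = 1000L,
                       p_threshold = 0.002,
                       top_n_variance_genes = "all",
                       seed = 1L) {
  cfg <- list(
    kmeans_runs = as.integer(kmeans_runs),
    coherence_threshold = as.numeric(coherence_threshold),
    merge_threshold = as.numeric(merge_threshold),
    min_module_size = as.integer(min_module_size),
    n_permutations = as.integer(n_permutations),
    p_threshold = as.numeric(p_threshold),
    top_n_variance_genes = if (identical(top_n_variance_genes, "all")) "all" else as.integer(top_n_variance_genes),
    seed = as.integer(seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$kmeans_runs >= 1L,
    cfg$coherence_threshold > 0, cfg$coherence_threshold <= 1,
    cfg$merge_threshold > 0, cfg$merge_threshold <= 1,
    cfg$min_module_size >= 1L,
    cfg$n_permutations >= 1L,
    cfg$p_threshold > 0, cfg$p_threshold < 1,
    identical(cfg$top_n_variance_genes, "all") || cfg$top_n_variance_genes >= 1L
  )
  structure(cfg, class = "spd_config")
}

#' Read or write a run configuration
#'
#' Configurations round-trip through YAML or JSON; the format is chosen from
#' the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param cfg An [spd_config()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_config()` returns an `spd_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "spd_config"))
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  }
  do.call(spd_config, x)
}
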