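#' Run the full progression-discovery pipeline in memory
#'
#' Executes the four stages on an expression matrix: (1) cluster genes into
#' coherent modules, (2) build one sample MST per module, (3) test every
#' module against every tree and assemble the progression similarity matrix,
#' (4) combine the selected modules' genes into the overall MST. If neither
#' `select` nor `auto_select` is given, the run stops after stage 3 with the
#' reordered similarity matrix ready for manual inspection; rerunning with
#' `select` completes stage 4.
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param cfg An [spd_config()]; all randomness derives from `cfg$seed`.
#' @param select Optional character vector of module ids to combine
#'   (manual selection, the canonical procedure).
#' @param auto_select Use the advisory [auto_select_block()] heuristic
#'   instead of manual selection.
#' @param min_block Passed to [auto_select_block()].
#' @return An object of class `spd_result`: list with `config`, `modules`
#'   (a `module_set`), `trees` (named list of per-module MSTs),
#'   `similarity` (a `progression_similarity`), `display_order`,
#'   `selected_ids` (NULL until selection), `selected_genes`,
#'   `overall_tree` (NULL until selection), and `selection_mode`
#'   (`"manual"`, `"auto"` or `"pending"`).
#' @export
#' @examples
#' sim <- simulate_progression(10, "path", n_prog_modules = 2,
#'                             genes_per_module = 6, pattern = "monotone",
#'                             noise_sd = 0.05, seed = 3)
#' cfg <- spd_config(kmeans_runs = 10, n_permutations = 100,
#'                   p_threshold = 0.02, seed = 3)
#' fit <- run_spd(sim$expr, cfg, auto_select = TRUE)
#' fit$overall_tree
run_spd <- function(expr, cfg = spd_config(), select = NULL, auto_select = FALSE,
                    min_block = 2L) {
  assert_expression_matrix(expr)
  cfg <- validate_config(cfg)
  if (!identical(cfg$top_n_variance_genes, "all")) {
    expr <- variance_filter(expr, cfg$top_n_variance_genes)
  }
  stage_seeds <- derive_seeds(cfg$seed, 3, stream = 1L)

  cfg_cluster <- cfg
  cfg_cluster$seed <- stage_seeds[1]
  modules <- iterative_consensus_cluster(expr, cfg_cluster)
  if (!length(modules$modules)) {
    stop("no module of size >= min_module_size survived clustering", call. = FALSE)
  }

  tree_seeds <- derive_seeds(stage_seeds[2], length(modules$modules))
  trees <- lapply(seq_along(modules$modules), function(i) {
    boruvka_mst(module_distance_matrix(expr, modules$modules[[i]]), seed = tree_seeds[i])
  })
  names(trees) <- names(modules$modules)

  cfg_conc <- cfg
  cfg_conc$seed <- stage_seeds[3]
  sim <- progression_similarity(modules, trees, expr, cfg_conc)
  display_order <- reorder_similarity(sim)

  res <- structure(list(config = cfg, modules = modules, trees = trees,
                        similarity = sim, display_order = display_order,
                        selected_ids = NULL, selected_genes = NULL,
                        overall_tree = NULL, selection_mode = "pending"),
                   class = "spd_result")
  if (auto_select && is.null(select)) {
    select <- auto_select_block(sim, min_block = min_block)
    res$selection_mode <- "auto"
  } else if (!is.null(select)) {
    res$selection_mode <- "manual"
  }
  if (!is.null(select)) {
    ids <- select_modules(sim, select)
    res$selected_ids <- ids
    res$selected_genes <- unique(unlist(modules$modules[ids], use.names = FALSE))
    overall_seed <- derive_seeds(cfg$seed, 1, stream = 2L)
    res$overall_tree <- overall_mst(expr, modules, ids, seed = overall_seed)
    n_conc <- min(diag(sim$S[ids, ids, drop = FALSE]))
    if (n_conc <= 1 && length(ids) > 1) {
      message("note: selected modules share few concordant trees; ",
              "the overall tree is a low-confidence progression hypothesis")
    }
  }
  res
}

#' @export
print.spd_result <- function(x, ...) {
  cat("spd_result\n")
  cat(sprintf("  modules: %d (%d genes clustered, %d unassigned)\n",
              length(x$modules$modules), sum(lengths(x$modules$modules)),
              length(x$modules$unassigned)))
  cat(sprintf("  selection: %s", x$selection_mode))
  if (!is.null(x$selected_ids)) {
    cat(sprintf(" [%s; %d genes]", paste(x$selected_ids, collapse = ", "),
                length(x$selected_genes)))
  }
  cat("\n")
  if (!is.null(x$overall_tree)) {
    cat(sprintf("  overall tree: %d samples, diameter %d\n",
                length(x$overall_tree$sample_ids), tree_diameter(x$overall_tree)))
  } else {
    cat("  overall tree: pending (inspect similarity matrix, then rerun with `select`)\n")
  }
  invisible(x)
}

#' Run the pipeline against files, writing all artifacts
#'
#' File-based front end to [run_spd()]: reads the expression matrix, runs
#' the staged pipeline, and writes the module tables, per-module trees,
#' concordance records, similarity matrix, overall tree and a JSON run
#' manifest into `out_dir`. Without a selection, stages 1-3 are written and
#' the manifest marks stage 4 pending.
#'
#' @param input Path to the expression TSV/CSV.
#' @param out_dir Output directory (created if needed).
#' @param cfg An [spd_config()].
#' @param select Optional module ids (manual selection).
#' @param auto_select Use the advisory block heuristic.
#' @param delimiter Input field delimiter.
#' @param min_block Passed to [auto_select_block()].
#' @return The run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(input, out_dir, cfg = spd_config(), select = NULL,
                         auto_select = FALSE, delimiter = "\t", min_block = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expr <- read_expression_matrix(input, delimiter)
  fit <- run_spd(expr, cfg, select = select, auto_select = auto_select,
                 min_block = min_block)

  paths <- list(
    config = file.path(out_dir, "config.yaml"),
    module_table = file.path(out_dir, "modules.tsv"),
    module_summary = file.path(out_dir, "module_summary.tsv"),
    concordance = file.path(out_dir, "concordance.tsv"),
    similarity = file.path(out_dir, "similarity_matrix.tsv")
  )
  write_config(fit$config, paths$config)
  write_module_table(fit$modules, paths$module_table, paths$module_summary)
  write_similarity(fit$similarity, paths$concordance, paths$similarity)
  tree_dir <- file.path(out_dir, "module_trees")
  dir.create(tree_dir, showWarnings = FALSE)
  for (id in names(fit$trees)) {
    write_tree(fit$trees[[id]], file.path(tree_dir, paste0(id, ".tsv")))
  }
  paths$module_trees <- tree_dir
  if (!is.null(fit$overall_tree)) {
    paths$overall_tree <- file.path(out_dir, "overall_tree.tsv")
    write_tree(fit$overall_tree, paths$overall_tree)
    paths$selection <- file.path(out_dir, "selection.json")
    jsonlite::write_json(list(selected_module_ids = fit$selected_ids,
                              selected_gene_ids = fit$selected_genes,
                              display_order = fit$display_order,
                              selection_mode = fit$selection_mode),
                         paths$selection, auto_unbox = TRUE, pretty = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("spd")),
    input = normalizePath(input),
    config = unclass(fit$config),
    seed = fit$config$seed,
    stages = list(cluster = TRUE, module_trees = TRUE, concordance = TRUE,
                  selection = !is.null(fit$overall_tree)),
    display_order = fit$display_order,
    selected_module_ids = fit$selected_ids,
    selection_mode = fit$selection_mode,
    artifacts = lapply(paths, function(p) normalizePath(p))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Evaluate a recovered tree against a reference ordering
#'
#' Compares a tree (e.g. a written overall MST) with a reference sample
#' ordering: topological overlap distance to the reference path, the tree's
#' diameter, and a random-tree null summary for both.
#'
#' @param tree A [sample_tree()] or path to an edge-list TSV.
#' @param reference_order Character vector of sample ids in reference order,
#'   or path to a one-id-per-line text file.
#' @param n_null Random trees for the null summary (default 1000); 0 skips
#'   the null.
#' @param seed Integer seed for the null draw.
#' @return List with `tom_distance`, `diameter`, and `null` (see
#'   [random_tree_null()]), or NULL null when skipped.
#' @export
evaluate_tree <- function(tree, reference_order, n_null = 1000L, seed = 1L) {
  if (is.character(tree) && length(tree) == 1) tree <- read_tree(tree)
  if (length(reference_order) == 1 && file.exists(reference_order)) {
    reference_order <- trimws(readLines(reference_order, warn = FALSE))
    reference_order <- reference_order[nzchar(reference_order)]
  }
  reference <- path_tree(reference_order)
  out <- list(
    tom_distance = tom_distance(tree, reference, "tree", "reference")$distance,
    diameter = tree_diameter(tree),
    null = NULL
  )
  if (n_null > 0) {
    nl <- random_tree_null(reference, n_trees = n_null, seed = seed,
                           query_diameter = out$diameter)
    out$null <- nl[c("tom_mean", "tom_sd", "diameter_mean", "diameter_sd",
                     "query_diameter", "p_diameter_ge")]
  }
  out
}
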