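#' Read a gene-expression matrix
#'
#' Reads a delimited text file with gene ids in the first column and sample
#' ids in the header row, as produced by most array/RNA-seq summarisation
#' pipelines (values are assumed already log-transformed / normalized
#' upstream). Gene rows containing any missing value are dropped with a
#' warning reporting the count.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter (default tab). No auto-detection is
#'   attempted, for reproducibility.
#' @return Numeric genes x samples matrix with gene rownames and sample
#'   colnames; at least 2 genes and 2 samples.
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter, check.names = FALSE,
                          row.names = NULL, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (ncol(df) < 3) stop("need at least 2 sample columns", call. = FALSE)
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in header", call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- is.na(num) & !is.na(vals) & !(toupper(trimws(vals)) %in% c("NA", "NAN", ""))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed numeric value '%s' at gene '%s', sample '%s'",
                 vals[w[1], w[2]], gene_ids[w[1]], sample_ids[w[2]]), call. = FALSE)
  }
  keep <- !apply(is.na(num), 1, any)
  if (any(!keep)) {
    warning(sprintf("dropped %d gene row(s) containing missing values", sum(!keep)))
  }
  num <- num[keep, , drop = FALSE]
  dimnames(num) <- list(gene_ids[keep], sample_ids)
  assert_expression_matrix(num)
  num
}

#' Write a gene-expression matrix
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param path Output file path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, delimiter = "\t") {
  assert_expression_matrix(expr)
  df <- data.frame(gene_id = rownames(expr),
                   format(expr, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(expr))
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep the highest-variance genes
#'
#' Ranks genes by their sample variance and keeps the top `top_n`, preserving
#' the original row order among survivors; ties are broken by input order.
#' The usual first step when an array contains many flat genes.
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param top_n Number of genes to keep, or `"all"`.
#' @return The filtered matrix.
#' @export
variance_filter <- function(expr, top_n) {
  assert_expression_matrix(expr)
  if (identical(top_n, "all")) return(expr)
  top_n <- as.integer(top_n)
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  if (top_n >= nrow(expr)) {
    if (top_n > nrow(expr)) warning("top_n exceeds gene count; returning all genes")
    return(expr)
  }
  v <- apply(expr, 1, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(top_n)])  # ties: order() is stable
  expr[keep, , drop = FALSE]
}

#' Write a sample tree
#'
#' @param tree A [sample_tree()].
#' @param path Output path.
#' @param format `"edgelist"` (3-column TSV: `sample_id_a`, `sample_id_b`,
#'   `weight`), `"graphml"`, or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, format = c("edgelist", "graphml", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "sample_tree"))
  if (format == "edgelist") {
    df <- data.frame(sample_id_a = tree$edges$from,
                     sample_id_b = tree$edges$to,
                     weight = sprintf("%.8g", tree$edges$weight))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(tree), path, format = format)
  }
  invisible(path)
}

#' Read a sample tree from an edge-list TSV
#'
#' @param path Path to a file written by [write_tree()] with
#'   `format = "edgelist"`.
#' @param sample_ids Optional full node set (needed only to represent
#'   isolated nodes, which a tree on >= 2 samples never has).
#' @return A [sample_tree()].
#' @export
read_tree <- function(path, sample_ids = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  ids <- sample_ids %||% unique(c(df$sample_id_a, df$sample_id_b))
  sample_tree(ids, data.frame(from = df$sample_id_a, to = df$sample_id_b,
                              weight = df$weight))
}

#' Write module assignment tables
#'
#' Writes the gene-to-module map (`gene_id`, `module_id`; unassigned genes
#' carry module_id `"unassigned"`) and a per-module summary (`module_id`,
#' `size`, `coherence`).
#'
#' @param modules A `module_set` from [iterative_consensus_cluster()].
#' @param path Path for the gene-level table.
#' @param summary_path Optional path for the per-module summary.
#' @return `path`, invisibly.
#' @export
write_module_table <- function(modules, path, summary_path = NULL) {
  stopifnot(inherits(modules, "module_set"))
  rows <- do.call(rbind, c(
    lapply(names(modules$modules), function(id) {
      data.frame(gene_id = modules$modules[[id]], module_id = id)
    }),
    if (length(modules$unassigned)) {
      list(data.frame(gene_id = modules$unassigned, module_id = "unassigned"))
    }
  ))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    smry <- data.frame(module_id = names(modules$modules),
                       size = lengths(modules$modules),
                       coherence = sprintf("%.6g", modules$coherence))
    utils::write.table(smry, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene ids (the
#' de-facto standard for pathway collections). A two-column variant
#' (name, genes...) is accepted when `description = FALSE`.
#'
#' @param path Path to a GMT file.
#' @param description Does the file carry a description column (default
#'   `TRUE`)?
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path, description = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-seq_len(if (description) 2 else 1)])
    genes[nzchar(genes)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT file", call. = FALSE)
  sets
}
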