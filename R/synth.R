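#' Simulate expression data with a planted progression
#'
#' Generates a genes x samples matrix in which several gene modules change
#' gradually along a planted sample arrangement, plus unstructured noise
#' genes, so the whole pipeline can be exercised against a known truth.
#'
#' Samples lie along either a `"path"` (positions equally spaced on
#' \[0, 1\]) or a `"star"`: one root plus `n_arms` arms, progression
#' coordinate = depth along the arm. Each progression module has a latent
#' mean curve over that arrangement:
#' \describe{
#'   \item{monotone}{a linear ramp, direction alternating between modules;}
#'   \item{unimodal}{a Gaussian bump centred mid-progression, sd 0.18 of the
#'     progression length, shifted per module;}
#'   \item{sinusoid}{`sin(2*pi*frequency*s + phase)` with a module-specific
#'     phase (evenly spaced by default), emulating phase-shifted cell-cycle
#'     programs. The default `frequency = 0.75` spans three quarters of a
#'     period: a time course that does not quite close its loop, keeping the
#'     two ends of the progression geometrically separated (a fully closed
#'     cycle cannot be represented by an acyclic tree).}
#' }
#' On a star, every module responds on every arm with an arm-specific random
#' slope and sign (lineages share programs but at differing rates and
#' directions), and the last `n_arm_specific` modules respond on a single arm
#' only (assigned round-robin). Arm programs are redrawn until the planted
#' star is geometrically identifiable from any sub-block of at least three
#' shared modules (see the vignette); draws where two arms are nearly
#' collinear plant an arrangement that is not the minimum-spanning geometry
#' of its own noiseless data. Each member gene is the module curve scaled
#' by a positive loading drawn Uniform(0.5, 1.5) -- co-expressed but not
#' identical -- plus i.i.d. Gaussian noise of sd `noise_sd`. Noise genes are
#' i.i.d. standard Gaussian. Columns are emitted in a random order (the
#' pipeline must never learn the arrangement from column position); the
#' truth retains it.
#'
#' @param n_samples Total number of samples (>= 3).
#' @param topology `"path"` or `"star"`.
#' @param n_prog_modules Number of planted progression modules.
#' @param genes_per_module Genes per planted module.
#' @param n_noise_genes Number of unstructured genes.
#' @param pattern Latent curve family (see Details).
#' @param noise_sd Gaussian noise sd added to module genes.
#' @param seed Integer seed; output is deterministic given it.
#' @param frequency Cycles spanned by the sinusoid pattern (default 0.75).
#' @param phases Optional per-module sinusoid phases (radians).
#' @param n_arms Number of arms for `topology = "star"` (default 3).
#' @param n_arm_specific For stars: how many of the modules respond on one
#'   arm only (default 0).
#' @param shuffle Emit columns in random order (default `TRUE`).
#' @return List with `expr` (the matrix) and `truth`, a list with fields
#'   `topology`, `sample_order` (path) or `root`/`arms` (star: named list of
#'   in-order sample ids per arm), `module_gene_ids` (list),
#'   `noise_gene_ids`, `noise_sd`, `seed`.
#' @export
#' @examples
#' sim <- simulate_progression(12, "path", n_prog_modules = 3,
#'                             genes_per_module = 8, n_noise_genes = 10,
#'                             pattern = "sinusoid", noise_sd = 0.05, seed = 1)
#' dim(sim$expr)
simulate_progression <- function(n_samples,
                                 topology = c("path", "star"),
                                 n_prog_modules = 3L,
                                 genes_per_module = 20L,
                                 n_noise_genes = 0L,
                                 pattern = c("monotone", "unimodal", "sinusoid"),
                                 noise_sd = 0.1,
                                 seed = 1L,
                                 frequency = 0.75,
                                 phases = NULL,
                                 n_arms = 3L,
                                 n_arm_specific = 0L,
                                 shuffle = TRUE) {
  topology <- match.arg(topology)
  pattern <- match.arg(pattern)
  n_samples <- as.integer(n_samples)
  if (n_samples < 3) stop("need n_samples >= 3", call. = FALSE)
  stopifnot(n_prog_modules >= 1, genes_per_module >= 1, n_noise_genes >= 0,
            noise_sd >= 0, n_arm_specific <= n_prog_modules)

  withr::with_seed(as.integer(seed), {
    if (topology == "path") {
      ids <- sprintf("s%02d", seq_len(n_samples))
      s <- (seq_len(n_samples) - 1) / (n_samples - 1)
      truth <- list(topology = "path", sample_order = ids)
      # module m latent value at each sample
      curves <- vapply(seq_len(n_prog_modules), function(m) {
        latent_curve(s, pattern, m, n_prog_modules, frequency, phases)
      }, numeric(n_samples))
    } else {
      if (n_arms < 2) stop("need n_arms >= 2", call. = FALSE)
      per_arm <- (n_samples - 1) %/% n_arms
      if (per_arm < 1 || (n_samples - 1) %% n_arms != 0) {
        stop("star topology needs n_samples = 1 + n_arms * arm_length", call. = FALSE)
      }
      root <- "root"
      arms <- lapply(seq_len(n_arms), function(a) sprintf("a%d_%02d", a, seq_len(per_arm)))
      names(arms) <- paste0("arm", seq_len(n_arms))
      ids <- c(root, unlist(arms, use.names = FALSE))
      depth <- c(0, rep(seq_len(per_arm) / per_arm, times = n_arms))
      arm_of <- c(0L, rep(seq_len(n_arms), each = per_arm))
      truth <- list(topology = "star", root = root, arms = arms)
      # Per-(module, arm) response matrix. Shared modules respond on every
      # arm with module- and arm-specific rates and directions (lineages run
      # the same programs at differing rates and signs); arm-specific
      # modules respond on a single arm only. Responses are redrawn until
      # the planted star is geometrically identifiable: in the space spanned
      # by any subset of at least three shared programs (together with any
      # of the arm-specific ones), every base-to-base distance must exceed
      # the larger of the two root-to-base distances by >= 10%. Module
      # selection can legitimately return such sub-blocks, and with
      # unconstrained slopes two arms can be nearly collinear in a
      # sub-block's space by chance -- the planted star is then not the
      # minimum-spanning geometry of its own noiseless data and no method
      # could recover it from those modules.
      n_shared <- n_prog_modules - n_arm_specific
      shape <- switch(pattern,
                      monotone = depth,
                      unimodal = exp(-(depth - 0.5)^2 / (2 * 0.18^2)) - exp(-0.5^2 / (2 * 0.18^2)),
                      sinusoid = sin(2 * pi * frequency * depth))
      bases <- vapply(seq_len(n_arms), function(a) which(arm_of == a)[1], integer(1))
      min_shared_block <- min(3L, n_shared)
      shared_subsets <- unlist(lapply(seq(min_shared_block, n_shared), function(z) {
        utils::combn(seq_len(n_shared), z, simplify = FALSE)
      }), recursive = FALSE)
      specific_subsets <- if (n_arm_specific > 0) {
        spec_ids <- seq(n_shared + 1L, n_prog_modules)
        unlist(lapply(0:n_arm_specific, function(z) {
          utils::combn(spec_ids, z, simplify = FALSE)
        }), recursive = FALSE)
      } else list(integer(0))
      accepted <- FALSE
      for (try in seq_len(4000L)) {
        slope <- matrix(0, n_prog_modules, n_arms)
        slope[seq_len(n_shared), ] <-
          stats::runif(n_shared * n_arms, 0.5, 1.5) *
          sample(c(-1, 1), n_shared * n_arms, replace = TRUE)
        if (n_arm_specific > 0) {
          spec <- seq(n_shared + 1L, n_prog_modules)
          own_arm <- ((seq_along(spec) - 1L) %% n_arms) + 1L
          for (k in seq_along(spec)) {
            slope[spec[k], own_arm[k]] <- sample(c(-1, 1), 1) * stats::runif(1, 1, 1.5)
          }
        }
        curves <- vapply(seq_len(n_prog_modules), function(m) {
          v <- numeric(n_samples)
          on_arm <- arm_of > 0L
          v[on_arm] <- slope[m, arm_of[on_arm]] * shape[on_arm]
          v / stats::sd(v)
        }, numeric(n_samples))
        ok <- TRUE
        for (ss in shared_subsets) {
          for (ps in specific_subsets) {
            sub <- c(ss, ps)
            dd <- as.matrix(stats::dist(curves[, sub, drop = FALSE]))
            r <- dd[1, bases]
            for (a in seq_len(n_arms - 1)) {
              for (b in seq(a + 1, n_arms)) {
                if (dd[bases[a], bases[b]] < 1.1 * max(r[a], r[b])) ok <- FALSE
              }
            }
            if (!ok) break
          }
          if (!ok) break
        }
        if (ok) { accepted <- TRUE; break }
      }
      if (!accepted) {
        stop("could not draw arm programs with subset-separable arms; increase the number of modules",
             call. = FALSE)
      }
    }

    # scale every latent curve to unit variance across samples: `noise_sd`
    # then means "noise relative to unit signal" for every pattern and
    # topology alike
    curves <- apply(curves, 2, function(v) if (stats::sd(v) > 0) v / stats::sd(v) else v)

    module_gene_ids <- lapply(seq_len(n_prog_modules), function(m) {
      sprintf("mod%02d_g%03d", m, seq_len(genes_per_module))
    })
    names(module_gene_ids) <- sprintf("planted%02d", seq_len(n_prog_modules))
    noise_gene_ids <- if (n_noise_genes > 0) sprintf("noise_g%04d", seq_len(n_noise_genes)) else character()

    rows <- vector("list", n_prog_modules + (n_noise_genes > 0))
    for (m in seq_len(n_prog_modules)) {
      loadings <- stats::runif(genes_per_module, 0.5, 1.5)
      rows[[m]] <- outer(loadings, curves[, m]) +
        matrix(stats::rnorm(genes_per_module * n_samples, 0, noise_sd),
               genes_per_module, n_samples)
    }
    if (n_noise_genes > 0) {
      rows[[n_prog_modules + 1L]] <- matrix(stats::rnorm(n_noise_genes * n_samples),
                                            n_noise_genes, n_samples)
    }
    expr <- do.call(rbind, rows)
    dimnames(expr) <- list(c(unlist(module_gene_ids, use.names = FALSE), noise_gene_ids), ids)
    if (shuffle) expr <- expr[, sample.int(n_samples), drop = FALSE]

    truth <- c(truth, list(module_gene_ids = module_gene_ids,
                           noise_gene_ids = noise_gene_ids,
                           noise_sd = noise_sd, seed = as.integer(seed)))
    list(expr = expr, truth = truth)
  })
}

latent_curve <- function(s, pattern, m, n_modules, frequency, phases) {
  switch(pattern,
         monotone = if (m %% 2 == 1) s else -s,
         unimodal = {
           center <- 0.35 + 0.3 * (m - 1) / max(1, n_modules - 1)
           exp(-(s - center)^2 / (2 * 0.18^2))
         },
         sinusoid = {
           phi <- if (!is.null(phases)) phases[m] else 2 * pi * (m - 1) / n_modules
           sin(2 * pi * frequency * s + phi)
         })
}

#' Simulate a structureless expression matrix
#'
#' Pure i.i.d. standard Gaussian matrix, used for calibration checks (e.g.
#' verifying that concordance p-values are uniform when no progression
#' exists).
#'
#' @param n_samples,n_genes Positive dimensions.
#' @param seed Integer seed.
#' @return Numeric genes x samples matrix with dimnames.
#' @export
simulate_null <- function(n_samples, n_genes, seed = 1L) {
  n_samples <- as.integer(n_samples); n_genes <- as.integer(n_genes)
  if (n_samples < 2 || n_genes < 1) stop("need n_samples >= 2 and n_genes >= 1", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    m <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  })
}

#' Write or read a planted truth record
#'
#' @param truth The `truth` component of [simulate_progression()].
#' @param path JSON file path.
#' @return `read_truth()` returns the truth list; `write_truth()` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
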