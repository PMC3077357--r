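test_that("the concordance statistic is the sum of tree-edge distances", {
  ids <- paste0("s", 1:4)
  d0 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  tr <- path_tree(ids)
  expect_equal(concordance_statistic(d0, tr), 0)

  # 4 collinear samples at 0, 1, 2, 3 with their path tree: unit edges sum to 3
  d <- as.matrix(dist(0:3)); dimnames(d) <- list(ids, ids)
  expect_equal(concordance_statistic(d, tr), 3)

  # star centered at s1: D[1,2] + D[1,3] + D[1,4], cross-checked by direct sum
  dr <- withr::with_seed(4, {m <- matrix(runif(16), 4); m <- m + t(m); diag(m) <- 0; m})
  dimnames(dr) <- list(ids, ids)
  star <- sample_tree(ids, data.frame(from = "s1", to = ids[2:4], weight = 1))
  expect_equal(concordance_statistic(dr, star), dr[1, 2] + dr[1, 3] + dr[1, 4])

  bad <- path_tree(paste0("t", 1:4))
  expect_error(concordance_statistic(d, bad), "different sample sets")
})

test_that("a module's own MST minimizes the statistic over all spanning trees of K4", {
  trees <- all_trees_4()
  ids <- paste0("s", 1:4)
  for (s in 1:50) {
    pts <- withr::with_seed(s, matrix(rnorm(4 * 3), 4, 3))
    d <- as.matrix(dist(pts)); dimnames(d) <- list(ids, ids)
    own <- boruvka_mst(d, seed = s)
    own_stat <- concordance_statistic(d, own)
    all_stats <- vapply(trees, function(e) sum(d[e]), numeric(1))
    expect_equal(own_stat, min(all_stats))
  }
})

test_that("permutation p-values behave at the boundary cases", {
  # n = 2: the single off-diagonal entry makes the statistic permutation-
  # invariant, flagged as degenerate with p = 1
  e2 <- rand_expr(3, 2, seed = 1)
  tr2 <- path_tree(colnames(e2))
  expect_warning(p2 <- permutation_pvalue(e2, tr2, n_perm = 50, seed = 1), "degenerate")
  expect_equal(p2, 1)

  # equidistant samples (one-hot genes): degenerate distance matrix, p = 1
  const <- diag(3)
  dimnames(const) <- list(paste0("g", 1:3), paste0("s", 1:3))
  expect_warning(p <- permutation_pvalue(const, path_tree(colnames(const)),
                                         n_perm = 100, seed = 1),
                 "degenerate")
  expect_equal(p, 1)

  # same seed: bit-identical p-values
  e <- rand_expr(6, 8, seed = 9)
  tr <- random_spanning_tree(8, seed = 2, sample_ids = colnames(e))
  expect_identical(permutation_pvalue(e, tr, n_perm = 200, seed = 33),
                   permutation_pvalue(e, tr, n_perm = 200, seed = 33))
})

test_that("a strict monotone gradient against its own path attains p = 1/(n_perm + 1)", {
  # exhaustive check at n = 6 first: no permutation yields a strictly
  # smaller statistic than the sorted order
  vals <- c(0.0, 1.0, 2.1, 3.3, 4.6, 6.0)
  ids <- paste0("s", 1:6)
  d <- as.matrix(dist(vals)); dimnames(d) <- list(ids, ids)
  tr <- path_tree(ids)
  observed <- concordance_statistic(d, tr)
  perms <- rbind(1:6)
  # enumerate all 720 permutations
  allp <- as.matrix(expand.grid(rep(list(1:6), 6)))
  allp <- allp[apply(allp, 1, function(r) length(unique(r)) == 6), , drop = FALSE]
  ei <- match(tr$edges$from, ids); ej <- match(tr$edges$to, ids)
  stats <- apply(allp, 1, function(p) sum(d[cbind(p[ei], p[ej])]))
  expect_equal(sum(stats < observed), 0)

  # hence the permutation p-value is exactly 1/(n_perm + 1)
  expr <- rbind(g1 = vals, g2 = 2 * vals + 1)
  colnames(expr) <- ids
  p <- permutation_pvalue(expr, tr, n_perm = 1000, seed = 5)
  expect_equal(p, 1 / 1001)
})

test_that("progression similarity counts trees concordant with module pairs", {
  # single module: concordant with its own tree by construction
  sim <- simulate_progression(10, "path", n_prog_modules = 1, genes_per_module = 8,
                              pattern = "monotone", noise_sd = 0.05, seed = 3)
  ms <- spd:::new_module_set(list(rownames(sim$expr)), 1, character())
  tr <- boruvka_mst(module_distance_matrix(sim$expr, rownames(sim$expr)), seed = 1)
  ps <- progression_similarity(ms, list(M1 = tr), sim$expr,
                               spd_config(n_permutations = 100, seed = 1))
  expect_identical(ps$S, matrix(1L, 1, 1, dimnames = list("M1", "M1")))

  # two modules with identical expression: S is all 2s
  expr <- rand_expr(6, 9, seed = 12)
  expr2 <- rbind(expr, expr)
  rownames(expr2) <- paste0("g", 1:12)
  ms2 <- spd:::new_module_set(list(paste0("g", 1:6), paste0("g", 7:12)),
                              c(1, 1), character())
  trees2 <- lapply(ms2$modules, function(g) {
    boruvka_mst(module_distance_matrix(expr2, g), seed = 1)
  })
  ps2 <- progression_similarity(ms2, trees2, expr2,
                                spd_config(n_permutations = 400, p_threshold = 0.01, seed = 2))
  expect_true(all(ps2$S == 2L))

  # planted gradient shared by two modules, third pure noise
  sim3 <- simulate_progression(8, "path", n_prog_modules = 2, genes_per_module = 6,
                               pattern = "monotone", noise_sd = 0.02, seed = 8)
  noise <- simulate_null(8, 6, seed = 99)
  colnames(noise) <- colnames(sim3$expr)
  rownames(noise) <- paste0("n", 1:6)
  expr3 <- rbind(sim3$expr, noise)
  mods3 <- c(sim3$truth$module_gene_ids, list(noise = rownames(noise)))
  ms3 <- spd:::new_module_set(unname(mods3), rep(1, 3), character())
  trees3 <- lapply(seq_along(ms3$modules), function(i) {
    boruvka_mst(module_distance_matrix(expr3, ms3$modules[[i]]), seed = i)
  })
  names(trees3) <- names(ms3$modules)
  ps3 <- progression_similarity(ms3, trees3, expr3,
                                spd_config(n_permutations = 1000, seed = 4))
  expect_equal(ps3$S["M1", "M2"], 2L)
  expect_equal(ps3$S["M1", "M3"], 0L)
  expect_equal(ps3$S["M2", "M3"], 0L)

  # invariants: symmetry and S[i, j] <= min(S[i, i], S[j, j])
  S <- ps3$S
  expect_identical(S, t(S))
  for (i in 1:3) for (j in 1:3) {
    expect_lte(S[i, j], min(S[i, i], S[j, j]))
  }
})

test_that("null modules give uniform p-values against an independent tree", {
  # KS calibration at reduced size; the acceptance suite runs the full 500
  ids <- colnames(simulate_null(10, 2, seed = 1))
  tr <- random_spanning_tree(10, seed = 77, sample_ids = ids)
  pv <- vapply(1:150, function(r) {
    m <- simulate_null(10, 8, seed = 5000 + r)
    permutation_pvalue(m, tr, n_perm = 100, seed = r)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("shared permutation streams change cost bookkeeping, not own-tree calls", {
  expr <- rbind(rand_expr(5, 8, seed = 61),
                withr::with_seed(62, matrix(rnorm(40), 5, 8,
                  dimnames = list(paste0("h", 1:5), paste0("s", 1:8)))))
  ms <- spd:::new_module_set(list(rownames(expr)[1:5], rownames(expr)[6:10]),
                             c(1, 1), character())
  trees <- lapply(ms$modules, function(g) {
    boruvka_mst(module_distance_matrix(expr, g), seed = 1)
  })
  cfg <- spd_config(n_permutations = 100, seed = 3)
  a <- progression_similarity(ms, trees, expr, cfg, shared_permutations = TRUE)
  b <- progression_similarity(ms, trees, expr, cfg, shared_permutations = TRUE)
  expect_identical(a$records, b$records)
  # own-module pairs remain concordant by construction under either scheme
  own <- a$records[a$records$module_id == a$records$tree_id, ]
  expect_true(all(own$concordant))
})
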