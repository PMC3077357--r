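test_that("module coherence matches the direct formula and handles degeneracy", {
  # identical rows with nonzero variance: perfect coherence
  m <- matrix(rep(c(1, 3, 2, 5), 4), 4, 4, byrow = TRUE)
  expect_equal(module_coherence(m), 1)

  # anti-correlated pair: cluster mean constant -> degenerate
  g <- c(1, 2, 3, 4)
  expect_error(module_coherence(rbind(g, -g)), class = "spd_degenerate_module")

  # hand-computed: rows (1,2,3), (2,4,6), (3,2,1); center (2, 8/3, 10/3)
  rows <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1))
  center <- colMeans(rows)
  expected <- mean(c(cor(rows[1, ], center), cor(rows[2, ], center), cor(rows[3, ], center)))
  expect_equal(module_coherence(rows), expected)

  # single gene
  expect_equal(module_coherence(matrix(c(1, 2, 5), 1)), 1)
})

test_that("consensus split recovers a planted two-group structure exactly", {
  pats <- planted_patterns(2, 12, seed = 5)  # correlation -1 at k=2: maximally split
  p <- pats[1, ]; q <- planted_patterns(3, 12, seed = 6)[2, ]  # corr(p, q) ~ 0
  x <- rbind(matrix(rep(p, 10), 10, byrow = TRUE),
             matrix(rep(q, 10), 10, byrow = TRUE))
  rownames(x) <- c(paste0("p", 1:10), paste0("q", 1:10))
  parts <- consensus_split(x, runs = 50, seed = 2)
  expect_true(setequal(parts[[1]], rownames(x)[1:10]) ||
                setequal(parts[[1]], rownames(x)[11:20]))
  expect_setequal(c(parts[[1]], parts[[2]]), rownames(x))

  # runs = 1 equals the single run's partition; deterministic given seed
  one_a <- consensus_split(x, runs = 1, seed = 7)
  one_b <- consensus_split(x, runs = 1, seed = 7)
  expect_identical(one_a, one_b)

  # two distinct genes: forced bipartition
  two <- rbind(a = c(0, 1, 2), b = c(5, 1, 0))
  parts2 <- consensus_split(two, runs = 5, seed = 1)
  expect_setequal(lengths(parts2), c(1L, 1L))

  # identical rows cannot be split
  same <- matrix(rep(c(1, 2, 3), 4), 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:4), NULL))
  expect_error(consensus_split(same, runs = 3, seed = 1), class = "spd_split_failure")
})

test_that("iterative clustering recovers planted modules and applies the size filter", {
  pats <- planted_patterns(3, 20, seed = 9)
  expr <- do.call(rbind, lapply(1:3, function(k) {
    withr::with_seed(100 + k, {
      sweep(matrix(rnorm(20 * 20, 0, 0.05), 20, 20), 2, pats[k, ], `+`)
    })
  }))
  dimnames(expr) <- list(paste0("g", 1:60), paste0("s", 1:20))
  cfg <- spd_config(kmeans_runs = 30, coherence_threshold = 0.7, min_module_size = 5, seed = 1)
  ms <- iterative_consensus_cluster(expr, cfg)
  expect_length(ms$modules, 3)
  truth <- rep(1:3, each = 20)
  for (mod in ms$modules) {
    expect_length(unique(truth[match(mod, rownames(expr))]), 1)
  }
  expect_length(ms$unassigned, 0)
  expect_true(all(ms$coherence >= cfg$coherence_threshold))

  # a single coherent pattern stays one module
  one <- sweep(matrix(rnorm(12 * 20, 0, 0.02), 12, 20), 2, pats[1, ], `+`)
  dimnames(one) <- list(paste0("h", 1:12), paste0("s", 1:20))
  ms1 <- iterative_consensus_cluster(one, cfg)
  expect_length(ms1$modules, 1)
  expect_length(ms1$modules[[1]], 12)
})

test_that("planted memberships are recovered exactly across 10 seeds (Rand index 1)", {
  for (s in 1:10) {
    pats <- planted_patterns(3, 16, seed = 200 + s)
    expr <- do.call(rbind, lapply(1:3, function(k) {
      withr::with_seed(300 + 10 * s + k, {
        sweep(matrix(rnorm(12 * 16, 0, 0.1), 12, 16), 2, pats[k, ], `+`)
      })
    }))
    dimnames(expr) <- list(paste0("g", 1:36), paste0("s", 1:16))
    ms <- iterative_consensus_cluster(expr, spd_config(kmeans_runs = 30, seed = s))
    truth <- rep(1:3, each = 12)
    got <- integer(36)
    for (i in seq_along(ms$modules)) got[match(ms$modules[[i]], rownames(expr))] <- i
    expect_equal(rand_index(truth, got), 1)
  }
})

test_that("clustering output is a partition and deterministic given the seed", {
  sim <- simulate_progression(12, "path", n_prog_modules = 3, genes_per_module = 8,
                              n_noise_genes = 20, pattern = "sinusoid",
                              noise_sd = 0.1, seed = 42)
  cfg <- spd_config(kmeans_runs = 20, seed = 5)
  a <- iterative_consensus_cluster(sim$expr, cfg)
  b <- iterative_consensus_cluster(sim$expr, cfg)
  expect_identical(a, b)
  all_genes <- c(unlist(a$modules, use.names = FALSE), a$unassigned)
  expect_setequal(all_genes, rownames(sim$expr))
  expect_identical(anyDuplicated(all_genes), 0L)
  expect_true(all(lengths(a$modules) >= cfg$min_module_size))
  # no pair of retained centers correlates above the merge threshold
  if (length(a$modules) >= 2) {
    z <- spd:::standardize_rows(sim$expr)
    centers <- t(sapply(a$modules, function(g) colMeans(z[g, , drop = FALSE])))
    cc <- cor(t(centers))
    expect_true(max(cc[upper.tri(cc)]) <= cfg$merge_threshold)
  }
})

test_that("merging collapses correlated modules greedily to a fixpoint", {
  base <- planted_patterns(2, 10, seed = 3)
  p <- base[1, ]
  expr <- rbind(
    a1 = p + withr::with_seed(1, rnorm(10, 0, 0.01)),
    a2 = p + withr::with_seed(2, rnorm(10, 0, 0.01)),
    b1 = -p + withr::with_seed(3, rnorm(10, 0, 0.01)),
    b2 = -p + withr::with_seed(4, rnorm(10, 0, 0.01))
  )
  colnames(expr) <- paste0("s", 1:10)
  ms <- spd:::new_module_set(list(c("a1"), c("a2"), c("b1"), c("b2")),
                             rep(1, 4), character())
  merged <- merge_modules(ms, expr, merge_threshold = 0.9)
  # identical centers merge; center correlation -1 pairs do not
  expect_length(merged$modules, 2)
  expect_setequal(lengths(merged$modules), c(2L, 2L))

  # three modules with pairwise center correlations (~0.95, ~0.95, ~0.99),
  # threshold 0.9: greedy-max merging runs to a single module
  q <- planted_patterns(3, 40, seed = 8)[1:2, ]
  mk <- function(w, nm, k) {
    v <- w[1] * q[1, ] + w[2] * q[2, ]
    v <- v / sd(v)
    m <- matrix(rep(v, k), k, byrow = TRUE) +
      withr::with_seed(sum(w * 100) + k, matrix(rnorm(k * 40, 0, 0.005), k, 40))
    rownames(m) <- paste0(nm, seq_len(k))
    m
  }
  expr3 <- rbind(mk(c(1, 0.12), "x", 3), mk(c(1, -0.12), "y", 3), mk(c(1, 0), "z", 3))
  colnames(expr3) <- paste0("s", 1:40)
  ms3 <- spd:::new_module_set(split(rownames(expr3), rep(1:3, each = 3)),
                              rep(1, 3), character())
  z3 <- spd:::standardize_rows(expr3)
  centers <- t(sapply(ms3$modules, function(g) colMeans(z3[g, , drop = FALSE])))
  cc <- cor(t(centers))
  expect_true(all(cc[upper.tri(cc)] > 0.9))  # construction sanity
  merged3 <- merge_modules(ms3, expr3, merge_threshold = 0.9)
  expect_length(merged3$modules, 1)
  expect_length(merged3$modules[[1]], 9)
})
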