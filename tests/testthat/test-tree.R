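test_that("module distance matrices match a brute-force double loop", {
  # identical sample columns: all-zero distances
  expr <- matrix(rep(c(1, 2, 3), 4), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_true(all(module_distance_matrix(expr, paste0("g", 1:3)) == 0))

  # one gene: 1-D absolute differences (unstandardized to keep numbers plain)
  e1 <- rbind(g1 = c(0, 1, 3), g2 = c(0, 1, 3))
  colnames(e1) <- paste0("s", 1:3)
  d <- module_distance_matrix(e1, "g1", standardize = FALSE)
  expect_equal(d["s1", "s2"], 1)
  expect_equal(d["s1", "s3"], 3)
  expect_equal(d["s2", "s3"], 2)

  # random 5 x 4 submatrix vs direct double loop on the standardized rows
  expr2 <- rand_expr(8, 4, seed = 21)
  genes <- paste0("g", c(1, 3, 5, 6, 8))
  d2 <- module_distance_matrix(expr2, genes)
  z <- spd:::standardize_rows(expr2[genes, ])
  for (i in 1:4) for (j in 1:4) {
    expect_equal(d2[i, j], sqrt(sum((z[, i] - z[, j])^2)))
  }
  expect_error(module_distance_matrix(expr2, character()), "empty module")
  expect_error(module_distance_matrix(expr2, "nope"), "not in matrix")
})

test_that("MST construction is exact: 1-D path, n = 2, and the Kruskal oracle", {
  # samples on a line at 0, 1, 3, 7: MST is the sorted path with weights 1, 2, 4
  x <- rbind(g1 = c(0, 1, 3, 7))
  d <- as.matrix(dist(c(0, 1, 3, 7)))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  tr <- boruvka_mst(d, seed = 1)
  expect_equal(sort(tr$edges$weight), c(1, 2, 4))
  expect_equal(sum(tr$edges$weight), 7)
  expect_equal(tree_diameter(tr), 3)

  d2 <- matrix(c(0, 2.5, 2.5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- boruvka_mst(d2, seed = 1)
  expect_equal(nrow(tr2$edges), 1)
  expect_equal(tr2$edges$weight, 2.5)

  # 20 random Euclidean instances: total weight equals Kruskal every time
  for (s in 1:20) {
    pts <- withr::with_seed(s, matrix(rnorm(6 * 3), 6, 3))
    dd <- as.matrix(dist(pts))
    dimnames(dd) <- list(paste0("s", 1:6), paste0("s", 1:6))
    expect_equal(sum(boruvka_mst(dd, seed = s)$edges$weight),
                 kruskal_total_weight(dd))
  }
})

test_that("MST output satisfies tree invariants and igraph agreement on many instances", {
  for (s in 1:50) {
    n <- withr::with_seed(1000 + s, sample(2:15, 1))
    pts <- withr::with_seed(2000 + s, matrix(rnorm(n * 2), n, 2))
    dd <- as.matrix(dist(pts))
    dimnames(dd) <- list(paste0("s", 1:n), paste0("s", 1:n))
    tr <- boruvka_mst(dd, seed = s)
    expect_s3_class(tr, "sample_tree")        # constructor validates tree-ness
    expect_equal(nrow(tr$edges), n - 1)
    g <- igraph::graph_from_adjacency_matrix(dd, weighted = TRUE, mode = "undirected")
    expect_equal(sum(tr$edges$weight),
                 sum(igraph::E(igraph::mst(g))$weight))
  }
})

test_that("tree diameter matches a BFS oracle on canonical and random trees", {
  expect_equal(tree_diameter(path_tree(paste0("s", 1:17))), 16)
  star <- sample_tree(paste0("s", 1:17),
                      data.frame(from = "s1", to = paste0("s", 2:17), weight = 1))
  expect_equal(tree_diameter(star), 2)
  for (s in 1:10) {
    tr <- random_spanning_tree(12, seed = 500 + s)
    expect_equal(tree_diameter(tr), bfs_diameter(tree_adjacency(tr)))
  }
})

test_that("path trees connect consecutive samples and ignore direction", {
  tr <- path_tree(c("s1", "s2", "s3"))
  a <- tree_adjacency(tr)
  expect_equal(a["s1", "s2"], 1L)
  expect_equal(a["s2", "s3"], 1L)
  expect_equal(a["s1", "s3"], 0L)
  rev_tr <- path_tree(c("s3", "s2", "s1"))
  expect_identical(tree_adjacency(rev_tr)[rownames(a), colnames(a)], a)
  expect_error(path_tree(c("s1", "s1", "s2")), "duplicate")
})

test_that("random labeled trees are uniform over topologies (n = 3 enumeration)", {
  counts <- table(vapply(1:9000, function(s) {
    tr <- random_spanning_tree(3, seed = s)
    idx <- cbind(match(tr$edges$from, tr$sample_ids), match(tr$edges$to, tr$sample_ids))
    tree_key(idx)
  }, ""))
  expect_length(counts, 3)
  expect_gt(chisq.test(counts)$p.value, 0.01)
  expect_error(random_spanning_tree(1, seed = 1), "n >= 2")
  # n = 2: always the single edge
  expect_equal(nrow(random_spanning_tree(2, seed = 3)$edges), 1)
})

test_that("tree constructor rejects malformed edge sets", {
  expect_error(sample_tree(c("a", "b", "c"),
                           data.frame(from = "a", to = "b", weight = 1)),
               "must have 2 edges")
  expect_error(sample_tree(c("a", "b", "c"),
                           data.frame(from = c("a", "a"), to = c("b", "b"), weight = 1)),
               "do not form a tree")
})
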