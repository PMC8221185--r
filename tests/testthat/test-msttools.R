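test_that("Kruskal picks the maximum-weight spanning tree", {
  adj <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                         c("A", "B", "C")))
  adj["A", "B"] <- adj["B", "A"] <- 0.9
  adj["B", "C"] <- adj["C", "B"] <- 0.8
  adj["A", "C"] <- adj["C", "A"] <- 0.1
  tree <- max_spanning_tree(adj)
  expect_equal(nrow(tree$edges), 2)
  expect_equal(sum(tree$edges$weight), 1.7)
  expect_equal(tree$edges[, c("i", "j")],
               data.frame(i = c(1L, 2L), j = c(2L, 3L)),
               ignore_attr = TRUE)
  # hub with dominant weights -> star rooted at the hub
  set.seed(31)
  a <- hub_dominant_adjacency(6, hub = 2)
  star <- max_spanning_tree(a)
  deg <- tabulate(c(star$edges$i, star$edges$j), 6)
  expect_equal(deg[2], 5)
  expect_error(max_spanning_tree(matrix(0, 1, 1)), "2 nodes")
  expect_error(max_spanning_tree(matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
})

test_that("Kruskal matches exhaustive spanning-tree enumeration", {
  set.seed(32)
  for (rep in 1:100) {
    n <- sample(4:6, 1)
    a <- random_adjacency(n)
    tree <- max_spanning_tree(a)
    expect_equal(sum(tree$edges$weight), best_tree_weight(a),
                 tolerance = 1e-12)
    # tree invariants: n-1 edges, acyclic and connected via igraph
    g <- igraph::graph_from_edgelist(cbind(tree$edges$i, tree$edges$j),
                                     directed = FALSE)
    expect_true(igraph::is_connected(g))
    expect_equal(igraph::ecount(g), n - 1)
  }
})

test_that("line and star measure normalizations match hand computation", {
  star5 <- mst_measures(star_tree(5))
  expect_equal(star5$leaf_fraction, 1)
  expect_equal(star5$max_degree, 1)
  expect_equal(star5$diameter, 0.5)
  expect_equal(star5$max_bc, 1)
  expect_equal(star5$tree_hierarchy, 0.5)
  path5 <- mst_measures(path_tree(5))
  expect_equal(path5$leaf_fraction, 0.5)
  expect_equal(path5$diameter, 1)
  expect_equal(path5$max_bc, 2 / 3)
  expect_equal(path5$tree_hierarchy, 0.375)
})

test_that("line and star extremes have their deterministic raw measures", {
  for (n in c(5, 10, 63)) {
    line <- mst_measures(path_tree(n))
    expect_equal(line$raw_max_degree, 2)
    expect_equal(line$raw_leaf_count, 2)
    expect_equal(line$raw_diameter, n - 1)
    star <- mst_measures(star_tree(n))
    expect_equal(star$raw_max_degree, n - 1)
    expect_equal(star$raw_leaf_count, n - 1)
    expect_equal(star$raw_diameter, 2)
  }
  # normalized diameters bracket the line/star extremes at 63 nodes
  expect_equal(mst_measures(star_tree(63))$diameter, 2 / 62)
  expect_equal(mst_measures(path_tree(63))$diameter, 1)
})

test_that("binarization preserves topology and the weighted mean PLI", {
  set.seed(33)
  a <- random_adjacency(7)
  tree <- max_spanning_tree(a)
  btree <- binarize(tree)
  expect_equal(btree$edges[, c("i", "j")], tree$edges[, c("i", "j")])
  expect_true(all(btree$edges$weight == 1))
  m1 <- mst_measures(tree)
  m2 <- mst_measures(btree)
  for (f in c("diameter", "leaf_fraction", "max_bc", "max_degree",
              "tree_hierarchy", "node_bc", "node_degree"))
    expect_equal(m2[[f]], m1[[f]])
  expect_equal(m2$mst_pli, mean(tree$edges$weight))
  two <- max_spanning_tree(matrix(c(0, 0.9, 0, 0.9, 0, 0.8,
                                    0, 0.8, 0), 3))
  expect_equal(mst_measures(binarize(two))$mst_pli, 0.85)
})

test_that("random trees satisfy the structural tree invariants", {
  set.seed(34)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    edges <- prufer_to_edges(sample(n, n - 2, replace = TRUE), n)
    a <- matrix(0, n, n)
    a[edges] <- 1
    a <- a + t(a)
    m <- mst_measures(max_spanning_tree(a))
    expect_gte(m$raw_leaf_count, 2)
    expect_equal(sum(m$node_degree) * (n - 1), 2 * (n - 1))
    expect_gte(m$raw_diameter, 2)
  }
})

test_that("morphing a path into a star moves all measures star-ward", {
  # re-attach the far end of the path to node 1, one leaf at a time:
  # step k keeps the path 1..(n-k) and hangs nodes (n-k+1)..n off node 1
  n <- 9
  lf <- mk <- dm <- numeric(0)
  for (k in 0:(n - 3)) {
    path_part <- cbind(seq_len(n - k - 1), 2:(n - k))
    star_part <- if (k > 0) cbind(rep(1, k), (n - k + 1):n) else NULL
    e <- rbind(path_part, star_part)
    adj <- matrix(0, n, n)
    adj[e] <- 1
    adj <- adj + t(adj)
    m <- mst_measures(max_spanning_tree(adj))
    lf <- c(lf, m$leaf_fraction)
    mk <- c(mk, m$max_degree)
    dm <- c(dm, m$diameter)
  }
  expect_true(all(diff(lf) >= 0))
  expect_true(all(diff(mk) >= 0))
  expect_true(all(diff(dm) <= 0))
  expect_gt(lf[length(lf)], lf[1])
  expect_gt(mk[length(mk)], mk[1])
  expect_lt(dm[length(dm)], dm[1])
})

test_that("measure tables align trees with trial metadata", {
  cfg <- planted_config(3, nch = 5, seed = 41)
  st <- planted_stack(cfg)
  msts <- mst_stack(st)
  expect_equal(length(msts$trees), 9 * 2 * 5)
  tab <- mst_measure_table(msts)
  expect_equal(nrow(tab$global), 90)
  expect_equal(nrow(tab$nodal), 90 * 5)
  expect_true(all(c("diameter", "leaf_fraction", "max_bc",
                    "max_degree", "tree_hierarchy", "mst_pli") %in%
                    names(tab$global)))
  expect_true(all(tab$global$leaf_fraction > 0 &
                    tab$global$leaf_fraction <= 1))
  expect_true(all(tab$nodal$node %in% st$channel_labels))
})
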