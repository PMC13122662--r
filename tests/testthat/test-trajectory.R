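test_that("inter-cluster distances reduce to Euclidean for identity covariance", {
  ## two clusters whose sample covariance is exactly the identity
  base <- rbind(c(-1, 0.5), c(1, -0.5), c(-1, -0.5), c(1, 0.5), c(0, 0))
  ## var_x = 4/4 = 1, var_y = 1/4... construct exactly:
  base <- rbind(c(-sqrt(2), 0), c(sqrt(2), 0), c(0, -sqrt(2)),
                c(0, sqrt(2)), c(0, 0))
  ## cov(base) = diag(1, 1) with the n-1 divisor
  emb <- rbind(base, sweep(base, 2, c(3, 0), `+`))
  labels <- rep(1:2, each = 5)
  d <- intercluster_distances(emb, labels)
  expect_equal(d[1, 2], 3, tolerance = 1e-3)
  expect_equal(diag(d), c(0, 0))
  expect_equal(d, t(d))
})

test_that("anisotropic covariance rescales the separation", {
  ## sample covariance exactly diag(4, 1): d^2 = 2^2 / 4 = 1
  base <- rbind(c(-2, 1), c(2, -1), c(-2, -1), c(2, 1), c(0, 0))
  emb <- rbind(base, sweep(base, 2, c(2, 0), `+`))
  labels <- rep(1:2, each = 5)
  d <- intercluster_distances(emb, labels)
  expect_equal(d[1, 2], 1, tolerance = 1e-3)
  expect_error(intercluster_distances(emb, c(rep(1, 9), 3)), "empty")
})

test_that("Prim's MST matches examples and the Pruefer brute-force oracle", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  expect_equal(minimum_spanning_tree(d), rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(nrow(minimum_spanning_tree(matrix(0, 1, 1))), 0)
  set.seed(3)
  for (i in 1:40) {
    k <- sample(3:6, 1)
    d <- random_symmetric_distance(k)
    edges <- minimum_spanning_tree(d)
    expect_equal(sum(d[edges]), min_spanning_weight_bruteforce(d),
                 tolerance = 1e-9)
  }
})

test_that("Prim's MST agrees with igraph", {
  skip_if_not_installed("igraph")
  set.seed(4)
  for (i in 1:10) {
    k <- sample(4:12, 1)
    d <- random_symmetric_distance(k)
    edges <- minimum_spanning_tree(d)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    w <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(sum(d[edges]), w, tolerance = 1e-9)
  }
})

test_that("cluster connectivity is MST degree over cluster count", {
  path <- rbind(c(1L, 2L), c(2L, 3L))
  expect_equal(cluster_connectivity(path, 3), c(1, 2, 1) / 3)
  star <- cbind(1L, 2:5)
  expect_equal(cluster_connectivity(star, 5), c(4, 1, 1, 1, 1) / 5)
  expect_equal(cluster_connectivity(rbind(c(1L, 2L)), 2), c(0.5, 0.5))
})

test_that("cell connectivity averages runs and ignores their order", {
  emb <- rbind(matrix(rnorm(20, 0), ncol = 2),
               matrix(rnorm(20, 6), ncol = 2),
               matrix(rnorm(20, c(0, 6)), ncol = 2))
  r1 <- list(k = 2L, labels = rep(c(1L, 2L), c(10, 20)))
  r2 <- list(k = 3L, labels = rep(c(1L, 2L, 3L), each = 10))
  g1 <- cluster_graph(emb, r1$labels)
  g2 <- cluster_graph(emb, r2$labels)
  single <- cell_connectivity(list(r1), list(g1))
  expect_equal(single, g1$connectivity[r1$labels])
  both <- cell_connectivity(list(r1, r2), list(g1, g2))
  swapped <- cell_connectivity(list(r2, r1), list(g2, g1))
  expect_equal(both, swapped)
  expect_equal(both, (g1$connectivity[r1$labels] +
                      g2$connectivity[r2$labels]) / 2)
  expect_error(cell_connectivity(list(r1), list(g2)), "disagree")
})

test_that("mean cluster connectivity equals 2(k-1)/k^2 for every run", {
  set.seed(6)
  emb <- matrix(rnorm(300), ncol = 2)
  for (k in c(2, 5, 9)) {
    run <- clara_run(emb, k, ensemble_config(), seed = k)
    g <- cluster_graph(emb, run$labels)
    expect_equal(mean(g$connectivity), 2 * (k - 1) / k^2, tolerance = 1e-12)
  }
})

test_that("VRC matches hand evaluation and handles degeneracy", {
  labels <- c(1L, 1L, 2L, 2L)
  expect_equal(vrc(labels, c(0, 1, 10, 11)), 200, tolerance = 1e-12)
  degenerate <- vrc(labels, c(3, 3, 8, 8))
  expect_true(is.infinite(degenerate))
  expect_true(isTRUE(attr(degenerate, "degenerate")))
  expect_error(vrc(rep(1L, 4), c(1, 2, 3, 4)), "at least 2")
})

test_that("VRC ranking selects the best run and validates pick", {
  conn <- c(0, 0.1, 0.9, 1, 0.5, 0.45)
  good <- list(k = 2L, labels = c(1L, 1L, 2L, 2L, 2L, 1L), seed = 1L,
               cost = 0)
  bad <- list(k = 2L, labels = c(1L, 2L, 1L, 2L, 1L, 2L), seed = 2L,
              cost = 0)
  sel <- rank_and_select(list(bad, good), conn)
  expect_identical(sel$selected, good)
  expect_equal(sel$rank$run[1], 2)
  one <- rank_and_select(list(good), conn)
  expect_identical(one$selected, good)
  expect_error(rank_and_select(list(bad, good), conn, pick = 5), "pick")
})

test_that("root selection honours the marker-enrichment filter", {
  labels <- rep(1:3, each = 4)
  run <- list(k = 3L, labels = labels)
  conn <- c(rep(0.5, 4), rep(0.3, 4), rep(0.8, 4))
  ## no markers: global argmax of mean connectivity
  expect_equal(select_root(run, conn), 3L)
  ## marker filter excludes the globally most-connected cluster
  markers <- c(rep(10, 4), rep(8, 4), rep(0, 4))
  expect_equal(select_root(run, conn, markers), 1L)
  ## both enriched -> higher connectivity wins
  markers2 <- c(rep(10, 4), rep(9, 4), rep(10, 4))
  expect_equal(select_root(run, conn, markers2), 3L)
})

test_that("lineage extraction follows root-to-leaf paths", {
  path <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  expect_equal(extract_lineages(path, 1), list(c(1L, 2L, 3L, 4L)))
  star <- cbind(1L, 2:4)
  expect_equal(extract_lineages(star, 1),
               list(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
  ## arbitrary tree vs depth-first-search oracle
  set.seed(8)
  for (i in 1:10) {
    k <- sample(4:9, 1)
    d <- random_symmetric_distance(k)
    edges <- minimum_spanning_tree(d)
    root <- sample(k, 1)
    lins <- extract_lineages(edges, root)
    adj <- lapply(seq_len(k), function(v) integer(0))
    for (e in seq_len(nrow(edges))) {
      adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
      adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
    }
    dfs_paths <- list()
    walk <- function(v, path) {
      nxt <- setdiff(adj[[v]], path)
      if (!length(nxt)) dfs_paths[[length(dfs_paths) + 1]] <<- c(path, v)
      for (w in nxt) walk(w, c(path, v))
    }
    walk(root, integer(0))
    dfs_paths <- dfs_paths[order(vapply(dfs_paths, function(p)
      p[length(p)], integer(1)))]
    dfs_paths <- lapply(dfs_paths, as.integer)
    expect_equal(lins, dfs_paths)
  }
})

test_that("pseudotime is arc length along the lineage curve", {
  ## centroids exactly at x = 0, 4, 8 on a line
  emb <- rbind(c(-1, 0), c(1, 0), c(3, 0), c(5, 0), c(7, 0), c(9, 0))
  run <- list(k = 3L, labels = c(1L, 1L, 2L, 2L, 3L, 3L))
  lineages <- list(c(1L, 2L, 3L))
  pt <- lineage_pseudotime(emb, run, lineages)
  ## cells project orthogonally; arc length measured from the root
  ## centroid, clamped to [0, total length]
  expect_equal(pt$pseudotime, c(0, 1, 3, 5, 7, 8))
  ## a cell exactly at the root centroid has pseudotime 0; one midway
  ## between centroids 4 apart (with an off-curve offset) lands at 2
  emb2 <- rbind(c(0, 0), c(0, 0), c(4, 0), c(4, 0), c(8, 0), c(8, 0),
                c(2, 1))
  run2 <- list(k = 3L, labels = c(1L, 1L, 2L, 2L, 3L, 3L, 2L))
  ## keep centroids exact by balancing the probe cell
  emb2 <- rbind(emb2, c(6, -1))
  run2$labels <- c(run2$labels, 2L)
  pt2 <- lineage_pseudotime(emb2, run2, lineages)
  expect_equal(pt2$pseudotime[1], 0)
  expect_equal(pt2$pseudotime[7], 2)
  expect_equal(pt2$pseudotime[8], 6)
})

test_that("cells in shared clusters split their weight across lineages", {
  emb <- rbind(c(0, 0), c(0, 0), c(4, 4), c(4, 4), c(4, -4), c(4, -4))
  run <- list(k = 3L, labels = c(1L, 1L, 2L, 2L, 3L, 3L))
  lineages <- list(c(1L, 2L), c(1L, 3L))
  pt <- lineage_pseudotime(emb, run, lineages)
  root_rows <- pt[pt$cluster == 1, ]
  expect_equal(nrow(root_rows), 4)  # 2 cells x 2 lineages
  expect_true(all(root_rows$weight == 0.5))
  leaf_rows <- pt[pt$cluster == 2, ]
  expect_true(all(leaf_rows$lineage == 1) && all(leaf_rows$weight == 1))
})

test_that("connectivity landscape interpolates linear fields exactly", {
  set.seed(10)
  emb <- matrix(runif(600, -2, 2), ncol = 2)
  ## constant scores -> constant grid
  land_c <- connectivity_landscape(emb, rep(0.4, nrow(emb)),
                                   grid_resolution = 20)
  expect_equal(range(land_c$z), c(0.4, 0.4), tolerance = 1e-12)
  ## scores equal to the x coordinate -> grid reproduces x inside the hull
  land_x <- connectivity_landscape(emb, emb[, 1], grid_resolution = 25)
  hull <- grDevices::chull(emb)
  inside <- sapply(seq_len(nrow(land_x$grid)), function(i)
    conntraj:::.point_in_hull(land_x$grid$x[i], land_x$grid$y[i],
                              emb[hull, 1], emb[hull, 2]))
  err <- abs(land_x$grid$z - land_x$grid$x)[inside]
  expect_lt(max(err), 1e-6)
})

test_that("landscape grid points that coincide with cells keep their score", {
  emb <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  scores <- c(0.1, 0.2, 0.3, 0.9)
  land2 <- connectivity_landscape(emb, scores, grid_resolution = 2,
                                  margin = 0)
  expect_equal(land2$z[1, 1], 0.1)
  expect_equal(land2$z[2, 2], 0.9)
  expect_warning(connectivity_landscape(cbind(1:5, 1:5), runif(5),
                                        grid_resolution = 5), "collinear")
})
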