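test_that("wcss matches closed forms and a brute-force double loop", {
  same <- matrix(1, 5, 3)
  expect_equal(wcss(same, c(1, 1, 2, 2, 2)), 0)
  expect_equal(wcss(matrix(c(0, 2), 2, 1), c(1, 1)), 2)

  set.seed(10)
  expr <- matrix(rnorm(100), 20, 5)
  labels <- sample(1:3, 20, replace = TRUE)
  brute <- 0
  for (j in unique(labels)) {
    mu <- colMeans(expr[labels == j, , drop = FALSE])
    for (i in which(labels == j)) brute <- brute + sum((expr[i, ] - mu)^2)
  }
  expect_equal(wcss(expr, labels), brute)

  # permutation invariance in spots and genes
  ps <- sample(20); pg <- sample(5)
  expect_equal(wcss(expr[ps, pg], labels[ps]), brute)
})

test_that("Ward clustering separates planted blobs; degenerate h works", {
  set.seed(11)
  blob <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  lab <- hierarchical_cluster(blob, 2)
  expect_equal(length(unique(lab[1:20])), 1L)
  expect_equal(length(unique(lab[21:40])), 1L)
  expect_true(lab[1] != lab[21])
  expect_equal(unique(hierarchical_cluster(blob, 1)), 1L)
  expect_equal(sort(hierarchical_cluster(blob, 40)), 1:40)
  expect_error(hierarchical_cluster(blob, 41), "h <=")
})

test_that("elbow rule recovers planted cluster count; curve non-increasing", {
  set.seed(12)
  blobs <- do.call(rbind, lapply(c(0, 8, 16), function(mu) {
    matrix(rnorm(60, mu, 0.5), 30, 2)
  }))
  res <- choose_h_elbow(blobs, h_range = 1:8)
  expect_equal(res$chosen_h, 3L)
  expect_true(all(diff(res$wcss_curve) <= 1e-8))

  flat <- matrix(1, 10, 3)
  expect_warning(rf <- choose_h_elbow(flat, h_range = 2:5), "flat")
  expect_equal(rf$chosen_h, 2L)
})

test_that("DBSCAN handles dense patches, distant noise, split patches", {
  # 3x3 patch minus its center: 8 spots, all mutually within eps=4
  patch <- as.matrix(expand.grid(1:3, 1:3))[-5, ]
  l1 <- dbscan_cluster(patch, eps = 4, min_pts = 8)
  expect_equal(unique(l1), 1L)

  far <- rbind(patch, c(100, 100))
  l2 <- dbscan_cluster(far, eps = 4, min_pts = 8)
  expect_equal(l2[9], 0L)          # unreachable -> noise
  expect_equal(unique(l2[1:8]), 1L)

  two <- rbind(lattice_coords(4)[1:10, ],
               lattice_coords(4)[1:10, ] + 50)
  l3 <- dbscan_cluster(two, eps = 4, min_pts = 8)
  expect_equal(length(setdiff(unique(l3), 0L)), 2L)
  expect_equal(length(unique(l3[1:10])), 1L)

  # fewer members than min_pts -> all noise
  expect_equal(dbscan_cluster(patch[1:5, ], eps = 4, min_pts = 8),
               rep(0L, 5))
})

test_that("DBSCAN agrees with an independent union-find oracle", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    coords <- cbind(sample(1:30, n, TRUE), sample(1:30, n, TRUE))
    coords <- coords[!duplicated(coords), , drop = FALSE]
    eps <- sample(2:4, 1); mp <- sample(3:8, 1)
    mine <- dbscan_cluster(coords, eps = eps, min_pts = mp)
    oracle <- brute_dbscan(coords, eps = eps, min_pts = mp)
    # identical core sets, identical core partitions, identical noise
    expect_identical(mine == 0L, oracle$labels == 0L)
    expect_true(same_partition(mine[oracle$core], oracle$labels[oracle$core]))
    # border points must sit within eps of a core point of their cluster
    border <- which(mine != 0L & !oracle$core)
    d <- as.matrix(dist(coords))
    for (b in border) {
      expect_true(any(oracle$core & mine == mine[b] & d[b, ] <= eps))
    }
  }
})

test_that("sub-cluster ids are globally unique across initial clusters", {
  coords <- rbind(lattice_coords(4), lattice_coords(4) + 100)
  init <- rep(1:2, each = 16)
  sub <- dbscan_subclusters(coords, init, eps = 4, min_pts = 8)
  expect_equal(sort(unique(sub$subcluster)), 1:2)
  expect_equal(unname(sub$parent), c(1L, 2L))
  expect_equal(unique(sub$subcluster[1:16]), 1L)
})

test_that("seed selection follows the size threshold and boundary rule", {
  # 10x10 lattice: 100 spots, one sub-cluster of 4 -> below 5% -> no seeds
  coords <- lattice_coords(10)
  sub <- integer(100)
  sub[1:4] <- 1L
  sub[5:40] <- 2L
  ss <- select_seeds(sub, coords, rng_seed = 7)
  expect_false(any(ss$seed_labels == 1L))

  # half of the eligible (non-boundary) members of a big sub-cluster
  eligible <- which(sub == 2L & !boundary_spots(coords))
  expect_equal(sum(ss$seed_labels == 2L), floor(0.5 * length(eligible)))
  expect_true(all(ss$seed_spots %in% eligible))

  # deterministic given the seed
  ss2 <- select_seeds(sub, coords, rng_seed = 7)
  expect_identical(ss$seed_spots, ss2$seed_spots)

  # all-boundary sub-cluster yields no seeds, then errors when alone
  # (on a 4x4 lattice only the 4 central spots have a full neighbor set)
  co4 <- lattice_coords(4)
  edge <- integer(16)
  edge[co4[, 1] == 1] <- 1L
  expect_true(all(boundary_spots(co4)[co4[, 1] == 1]))
  expect_error(suppressWarnings(select_seeds(edge, co4, rng_seed = 1)),
               "no seeds")
})

test_that("interior spots of a 10-spot sub-cluster yield 5 seeds", {
  # embed the sub-cluster in a lattice so its members are interior
  coords <- lattice_coords(12)
  interior <- which(!boundary_spots(coords))
  sub <- integer(nrow(coords))
  sub[interior[1:10]] <- 1L
  # total_n = 144; 10 >= 0.05*144 = 7.2 -> qualifies; floor(0.5*10) = 5
  ss <- select_seeds(sub, coords, rng_seed = 3)
  expect_equal(length(ss$seed_spots), 5L)
})

test_that("region growing labels every spot and fixes seeds", {
  coords <- lattice_coords(6)
  n <- nrow(coords)
  # identical expression, one seeded region -> everything joins it
  expr <- matrix(1, n, 4)
  seed_set <- structure(list(seed_spots = c(15L, 16L),
                             seed_labels = c(3L, 3L),
                             subcluster = integer(n)),
                        class = "seed_set")
  res <- srg(expr, coords, seed_set)
  expect_equal(unique(res$final_labels), 1L)
  expect_equal(res$n_clusters, 1L)
  expect_true(res$seed_fixed)

  # two expression blobs aligned with two spatial halves
  set.seed(14)
  left <- coords[, 1] <= 3
  expr2 <- matrix(rnorm(n * 5, 0, 0.1), n, 5)
  expr2[left, 1] <- expr2[left, 1] + 10
  seeds2 <- structure(list(seed_spots = c(which(left)[1:3],
                                          which(!left)[1:3]),
                           seed_labels = c(1L, 1L, 1L, 2L, 2L, 2L),
                           subcluster = integer(n)),
                      class = "seed_set")
  res2 <- srg(expr2, coords, seeds2)
  expect_equal(res2$n_clusters, 2L)
  expect_true(all(res2$final_labels > 0))
  expect_equal(length(unique(res2$final_labels[left])), 1L)
  expect_equal(length(unique(res2$final_labels[!left])), 1L)
  # seeds keep their (relabeled) regions: same partition restricted to seeds
  expect_equal(length(unique(res2$final_labels[seeds2$seed_spots[1:3]])), 1L)
  expect_true(res2$seed_fixed)
})

test_that("disconnected spots are assigned to the expression-nearest region", {
  coords <- rbind(lattice_coords(4), c(100, 100))
  expr <- matrix(0, 17, 3)
  expr[17, ] <- 5   # far spot, expression like nothing else
  seed_set <- structure(list(seed_spots = c(6L, 7L),
                             seed_labels = c(1L, 1L),
                             subcluster = integer(17)),
                        class = "seed_set")
  expect_warning(res <- srg(expr, coords, seed_set), "disconnected")
  expect_true(all(res$final_labels > 0))
})

test_that("pseudo-bulk aggregation matches group-by brute force", {
  expect_equal(unname(pseudo_bulk(rbind(c(2, 0), c(0, 2)), c(1, 1))),
               matrix(c(1, 1), 1, 2))
  prof <- matrix(3, 4, 2)
  expect_equal(unname(pseudo_bulk(prof, rep(1, 4))), matrix(3, 1, 2))

  set.seed(15)
  expr <- matrix(rpois(60, 4), 12, 5)
  labels <- sample(1:3, 12, replace = TRUE)
  pb <- pseudo_bulk(expr, labels)
  for (j in sort(unique(labels))) {
    expect_equal(pb[as.character(j), ],
                 colMeans(expr[labels == j, , drop = FALSE]),
                 ignore_attr = TRUE)
  }
  pbs <- pseudo_bulk(expr, labels, agg = "sum")
  expect_equal(unname(pbs["2", ]), unname(colSums(expr[labels == 2, ])))
})

test_that("clustering pipeline is reproducible given the same seed", {
  fx <- make_fixture(n_side = 8, n_genes = 60, n_cells_per_type = 20,
                     rng_seed = 5)
  cfg <- declust_config(h_range = 2:6, rng_seed = 5)
  a <- cluster_spots(fx$st, cfg)
  b <- cluster_spots(fx$st, cfg)
  expect_identical(a$final_labels, b$final_labels)
  expect_identical(a$seed_set$seed_spots, b$seed_set$seed_spots)
})
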