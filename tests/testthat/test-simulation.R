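test_that("spot simulation conserves cell counts and honors proportions", {
  sc <- tiny_sc(k = 3, n_per_type = 10, seed = 40)
  set.seed(40)
  sp <- simulate_spot(c(T1 = 1, T2 = 0, T3 = 0), sc, cells_per_spot = 10)
  expect_equal(unname(sp$counts), c(10L, 0L, 0L))
  expect_true(all(sc$cell_types[sp$cells] == "T1"))
  expect_equal(sum(sp$counts), 10L)
  expect_equal(sp$profile, colSums(sc$expr[sp$cells, , drop = FALSE]))

  for (i in 1:20) {
    expect_equal(sum(simulate_spot(c(0.5, 0.3, 0.2), sc, 10)$counts), 10L)
  }
  expect_error(simulate_spot(c(0.5, 0.2), sc, 10), "sum to 1")
})

test_that("empirical mean of counts matches proportions (LLN)", {
  sc <- tiny_sc(k = 3, n_per_type = 5, n_genes = 9, seed = 41)
  p <- c(0.5, 0.3, 0.2)
  set.seed(41)
  draws <- replicate(5000, simulate_spot(p, sc, 10)$counts / 10)
  se <- sqrt(p * (1 - p) / 10 / 5000)
  expect_true(all(abs(rowMeans(draws) - p) < 3 * se + 1e-12))
})

test_that("dataset simulation keeps coordinates and exact bookkeeping", {
  sc <- tiny_sc(k = 2, n_per_type = 8, n_genes = 12, seed = 42)
  co <- lattice_coords(3)
  S <- matrix(c(0.7, 0.3), nrow(co), 2, byrow = TRUE,
              dimnames = list(NULL, levels(sc$cell_types)))
  sim <- simulate_dataset(co, S, sc, cells_per_spot = 10, rng_seed = 1)
  expect_equal(unname(sim$st$coords), unname(co), ignore_attr = TRUE)
  # truth = counts / cells_per_spot exactly
  for (i in seq_len(nrow(co))) {
    counts <- table(factor(sc$cell_types[sim$cell_assignments[[i]]],
                           levels = levels(sc$cell_types)))
    expect_equal(unname(sim$truth[i, ]), as.numeric(counts) / 10)
  }
  expect_equal(unname(rowSums(sim$truth)), rep(1, nrow(co)))

  one <- simulate_dataset(co[1, , drop = FALSE], S[1, , drop = FALSE], sc)
  expect_equal(nrow(one$st$expr), 1L)

  r1 <- simulate_dataset(co, S, sc, rng_seed = 1)
  r2 <- simulate_dataset(co, S, sc, rng_seed = 2)
  expect_identical(r1$st$expr,
                   simulate_dataset(co, S, sc, rng_seed = 1)$st$expr)
  expect_false(identical(r1$st$expr, r2$st$expr))
})

test_that("ligand-receptor filter matches a brute-force threshold scan", {
  set.seed(43)
  expr <- matrix(round(runif(50 * 10, 0, 40), 3), 50, 10,
                 dimnames = list(NULL, paste0("g", 1:10)))
  sc <- sc_reference(expr, rep(c("A", "B"), 25))
  got <- lr_filter_cells(sc, "g1", "g2", 0.75)
  lg <- sc$expr[, "g1"]; rc <- sc$expr[, "g2"]
  brute <- unname(which(lg >= quantile(lg, 0.75) & rc >= quantile(rc, 0.75)))
  expect_identical(got, brute)

  # identical expression: quantile equals the common value, all pass
  flat <- sc_reference(matrix(3, 10, 2,
                              dimnames = list(NULL, c("L", "R"))),
                       rep(c("A", "B"), 5))
  expect_equal(lr_filter_cells(flat, "L", "R", 0.75), 1:10)

  # one cell uniquely high in both genes passes alone as q -> 1
  e <- matrix(1, 10, 2, dimnames = list(NULL, c("L", "R")))
  e[7, ] <- 100
  hi <- sc_reference(e, rep(c("A", "B"), 5))
  expect_equal(lr_filter_cells(hi, "L", "R", 0.999), 7L)

  # monotone in the quantile: higher cut -> subset
  q1 <- lr_filter_cells(sc, "g1", "g2", 0.25)
  q2 <- lr_filter_cells(sc, "g1", "g2", 0.6)
  expect_true(all(q2 %in% q1))
  expect_error(lr_filter_cells(sc, "nope", "g2"), "not found")
})

test_that("LR enrichment restricts pools only in the enriched cluster", {
  set.seed(44)
  k <- 3
  types <- c("CAF", "Plasmablast", "Other")
  expr <- matrix(rpois(60 * 40, 3), 60, 40,
                 dimnames = list(NULL, paste0("g", 1:40)))
  colnames(expr)[1:2] <- c("CXCL12", "CXCR4")
  sc <- sc_reference(expr, rep(types, each = 20))
  co <- lattice_coords(4)
  cl <- rep(1:2, each = 8)
  S_cluster <- matrix(1 / 3, 2, 3, dimnames = list(1:2, types))
  enr <- data.frame(cluster = 2, ligand = "CXCL12", receptor = "CXCR4",
                    type1 = "CAF", type2 = "Plasmablast", quantile = 0.75)
  sim <- simulate_lr_enriched(co, cl, S_cluster, sc, enr, rng_seed = 3)
  passing <- lr_filter_cells(sc, "CXCL12", "CXCR4", 0.75)
  for (i in which(cl == 2)) {
    cells <- sim$cell_assignments[[i]]
    pair <- cells[sc$cell_types[cells] %in% c("CAF", "Plasmablast")]
    expect_true(all(pair %in% passing))
  }
  # unenriched cluster samples freely from full pools (counts conserved)
  expect_equal(unname(rowSums(sim$truth)), rep(1, 16))

  # no enrichments reduces to the plain simulator given the same seed
  a <- simulate_lr_enriched(co, cl, S_cluster, sc,
                            enrichments = NULL, rng_seed = 5)
  b <- simulate_dataset(co, S_cluster[cl, ], sc, rng_seed = 5)
  expect_identical(a$st$expr, b$st$expr)
})

test_that("enriched clusters show elevated ligand expression", {
  set.seed(45)
  types <- c("CAF", "Plasmablast")
  expr <- matrix(rpois(40 * 30, 2), 40, 30,
                 dimnames = list(NULL, paste0("g", 1:30)))
  colnames(expr)[1:2] <- c("LG", "RC")
  # the same cells spike in both genes so co-expressors exist in each type
  spike <- rbinom(40, 1, 0.3)
  expr[, "LG"] <- rpois(40, 2) + spike * 30
  expr[, "RC"] <- rpois(40, 2) + spike * 30
  sc <- sc_reference(expr, rep(types, 20))
  co <- lattice_coords(6)
  cl <- rep(1:2, each = 18)
  S_cluster <- matrix(0.5, 2, 2, dimnames = list(1:2, types))
  enr <- data.frame(cluster = 2, ligand = "LG", receptor = "RC",
                    type1 = "CAF", type2 = "Plasmablast", quantile = 0.75)
  sim <- simulate_lr_enriched(co, cl, S_cluster, sc, enr, rng_seed = 7)
  expect_gt(mean(sim$st$expr[cl == 2, "LG"]),
            mean(sim$st$expr[cl == 1, "LG"]))
})

test_that("fixture generator plants recoverable structure, reproducibly", {
  fx <- make_fixture(n_side = 6, n_genes = 80, n_cells_per_type = 50,
                     rng_seed = 8)
  expect_equal(sort(unique(fx$domains)), 1:4)
  # quadrant domains are spatially contiguous: each occupies a rectangle
  for (d in 1:4) {
    xs <- fx$st$coords[fx$domains == d, 1]
    ys <- fx$st$coords[fx$domains == d, 2]
    expect_equal(length(unique(xs)) * length(unique(ys)), sum(fx$domains == d))
  }
  expect_identical(fx$st$expr,
                   make_fixture(n_side = 6, n_genes = 80,
                                n_cells_per_type = 50, rng_seed = 8)$st$expr)

  mt <- select_markers(fx$sc, t = 10)
  hits <- vapply(names(fx$planted_markers), function(ty) {
    sum(fx$planted_markers[[ty]] %in%
          mt$gene[mt$selected & mt$cell_type == ty])
  }, numeric(1))
  # overall planted-marker recovery (the joint criterion forfeits ~5% of
  # true markers to the T2 null rejection rate by construction)
  expect_gte(sum(hits) / (4 * 10), 0.9)
})
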