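test_that("sphere mesh honours the node-count contract and minimal closure", {
  g4 <- generate_sphere_mesh(4, radius = 100, seed = 7)
  expect_equal(sum(g4$hemisphere == "left"), 4)
  expect_equal(sum(g4$hemisphere == "right"), 4)
  # a closed triangulation of 4 points is the tetrahedron: 4 faces per sphere
  expect_equal(nrow(g4$triangles), 8)
  for (n in c(37, 120)) {
    g <- generate_sphere_mesh(n, radius = 50, seed = 1)
    expect_equal(nrow(g$vertices), 2 * n)
    # closed surface: every edge in exactly two triangles, F = 2V - 4
    for (h in c("left", "right")) {
      tri <- g$triangles[apply(matrix(g$hemisphere[g$triangles] == h, ncol = 3),
                               1, all), , drop = FALSE]
      e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
      key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      expect_true(all(table(key) == 2))
      expect_equal(nrow(tri), 2 * n - 4)
    }
  }
  expect_error(generate_sphere_mesh(3, 50, 1), "nodes_per_hemisphere")
})

test_that("mesh nodes are quasi-uniform (nearest-neighbour CV < 0.3)", {
  g <- generate_sphere_mesh(500, radius = 100, seed = 3)
  idx <- which(g$hemisphere == "left")
  # brute-force all-pairs Euclidean distances
  v <- g$vertices[idx, ]
  d <- as.matrix(dist(v))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.3)
})

test_that("generation is reproducible and seeds differ", {
  a <- generate_sphere_mesh(50, 50, seed = 5, n_subcortical = 3)
  b <- generate_sphere_mesh(50, 50, seed = 5, n_subcortical = 3)
  c <- generate_sphere_mesh(50, 50, seed = 6, n_subcortical = 3)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$vertices, c$vertices)))
})

test_that("parcellation counts, labelling, and contiguity", {
  g <- generate_sphere_mesh(200, 50, seed = 2, n_subcortical = 5)
  p2 <- generate_parcellation(g, 2, 5, seed = 1)
  expect_equal(nrow(p2$areas), 2 * 2 + 5)
  expect_equal(sum(p2$areas$is_callosal), 2)
  p <- generate_parcellation(g, 10, 5, seed = 1)
  expect_equal(nrow(p$areas), 25)
  expect_false(anyNA(p$area_id))
  # every functional cortical patch is a connected subgraph (BFS oracle)
  tri <- g$triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  gr <- igraph::graph_from_edgelist(e, directed = FALSE)
  for (a in p$areas$id[p$areas$kind == "cortical"]) {
    nodes <- which(p$area_id == a)
    sub <- igraph::induced_subgraph(gr, nodes)
    expect_true(igraph::is_connected(sub), label = paste("area", a))
  }
  # callosal patch sits on the medial face: its centroid leans toward x = 0
  for (h in c("left", "right")) {
    cal <- p$areas$id[p$areas$is_callosal & p$areas$hemisphere %in% h]
    ctr <- colMeans(g$vertices[p$area_id == cal, , drop = FALSE])
    hem <- colMeans(g$vertices[g$hemisphere == h, , drop = FALSE])
    expect_lt(abs(ctr[1]), abs(hem[1]) + 1e-9)
  }
  expect_error(generate_parcellation(g, 500, 5), "more areas than nodes")
})

test_that("homogeneous SC: normalization, isolation, kernel shape", {
  b <- tiny_bundle()
  hom <- build_homogeneous_sc(b$geometry, b$parc, sigma = 10)
  W <- hom$weights
  n_c <- nrow(b$geometry$vertices)
  cal <- which(b$parc$area_id %in% b$parc$areas$id[b$parc$areas$is_callosal])
  live <- setdiff(seq_len(n_c), cal)
  rs <- Matrix::rowSums(W)
  expect_lt(max(abs(rs[live] - 1)), 1e-12)
  expect_true(all(rs[cal] == 0))
  expect_true(all(Matrix::colSums(W)[cal] == 0))
  expect_true(all(W@x >= 0))
  # no interhemispheric links
  left <- which(b$geometry$hemisphere == "left")
  right <- which(b$geometry$hemisphere == "right")
  expect_equal(sum(W[left, right]) + sum(W[right, left]), 0)
  # subcortical rows and columns are zero
  subc <- (n_c + 1):nrow(W)
  expect_equal(sum(abs(W[subc, ])) + sum(abs(W[, subc])), 0)
  # within-row weight ratios follow the Gaussian kernel exactly
  d <- cortical_distances(b$geometry)
  i <- live[1]
  js <- setdiff(which(W[i, ] > 0), i)[1:5]
  expect_equal(as.numeric(W[i, js] / W[i, i]),
               exp(-d[i, js]^2 / (2 * 10^2)), tolerance = 1e-10)
  # sigma << edge length concentrates all mass on the node itself
  hom0 <- build_homogeneous_sc(b$geometry, b$parc, sigma = 0.05)
  expect_gt(min(Matrix::diag(hom0$weights)[live]), 1 - 1e-10)
  expect_error(build_homogeneous_sc(b$geometry, b$parc, sigma = 0), "sigma")
})

test_that("heterogeneous SC: density, normalization, delays", {
  g <- generate_sphere_mesh(150, 50, seed = 4, n_subcortical = 9)
  p <- generate_parcellation(g, 9, 9, seed = 4)   # 16 + 9 = 25 functional areas
  fun <- functional_areas(p)
  expect_equal(length(fun), 25)
  full <- generate_heterogeneous_sc(p, g, connection_density = 1, seed = 1)
  expect_equal(sum(full$weights[fun, fun] > 0), 25 * 24)
  expect_equal(sum(diag(full$weights)), 0)
  het <- generate_heterogeneous_sc(p, g, connection_density = 0.2, seed = 1)
  n_edges <- sum(het$weights > 0)
  # exact binomial 99% interval for Binom(25*24, 0.2)
  ci <- qbinom(c(0.005, 0.995), 25 * 24, 0.2)
  expect_gte(n_edges, ci[1])
  expect_lte(n_edges, ci[2])
  expect_equal(max(rowSums(het$weights)), 1, tolerance = 1e-12)
  # callosal areas carry no heterogeneous connections
  cal <- p$areas$id[p$areas$is_callosal]
  expect_equal(sum(het$weights[cal, ]) + sum(het$weights[, cal]), 0)
  # delay oracle: scalar loop over entries
  for (i in seq_len(nrow(het$weights)))
    for (j in seq_len(ncol(het$weights))) {
      expected <- if (het$weights[i, j] > 0)
        het$lengths[i, j] / (6 * 1000) else 0
      expect_identical(het$delays[i, j], expected)
    }
  expect_error(generate_heterogeneous_sc(p, g, connection_density = 0),
               "connection_density")
})

test_that("connectome files round-trip and are validated", {
  W <- matrix(c(0, 2, 3, 0), 2, 2)
  L <- matrix(c(0, 7, 7, 0), 2, 2)
  het <- heterogeneous_sc(W, L, speed = 6, normalize = FALSE)
  dir <- file.path(tempdir(), "conn_rt")
  write_connectome(het, dir, weights = W)
  back <- read_connectome(dir)
  # raw weights round-trip bit-exactly before normalization
  raw <- as.matrix(read.table(file.path(dir, "weights.txt")))
  dimnames(raw) <- NULL
  expect_equal(raw, W, ignore_attr = TRUE)
  expect_equal(max(rowSums(back$weights)), 1, tolerance = 1e-12)
  # a single nonzero row summing to 5 normalizes to 1
  W5 <- matrix(0, 3, 3); W5[2, c(1, 3)] <- c(2, 3)
  dir5 <- file.path(tempdir(), "conn5")
  write_connectome(heterogeneous_sc(W5, matrix(1, 3, 3) - diag(3),
                                    normalize = FALSE),
                   dir5, weights = W5)
  expect_equal(sum(read_connectome(dir5)$weights[2, ]), 1)
  # format errors
  bad <- file.path(tempdir(), "conn_bad"); dir.create(bad, showWarnings = FALSE)
  writeLines(c("1 2 3", "4 5"), file.path(bad, "weights.txt"))
  writeLines(c("0 1", "1 0"), file.path(bad, "tract_lengths.txt"))
  writeLines(c("a 0 0 0", "b 1 1 1"), file.path(bad, "centres.txt"))
  expect_error(read_connectome(bad), "ragged")
  writeLines(c("1 2 3", "4 5 6", "7 8 9"), file.path(bad, "weights.txt"))
  expect_error(read_connectome(bad), "dimensions differ")
  writeLines(c("0 -1", "1 0"), file.path(bad, "weights.txt"))
  expect_error(read_connectome(bad), "negative")
})

test_that("mesh TSV and OFF readers work", {
  g <- generate_sphere_mesh(30, 50, seed = 9, n_subcortical = 2)
  vp <- tempfile(fileext = ".tsv"); tp <- tempfile(fileext = ".tsv")
  sp <- tempfile(fileext = ".tsv")
  write_mesh(g, vp, tp, sp)
  back <- read_mesh(vp, tp, sp)
  expect_equal(back$vertices, g$vertices, ignore_attr = TRUE)
  expect_equal(back$triangles, g$triangles, ignore_attr = TRUE)
  expect_equal(back$subcortical, g$subcortical, ignore_attr = TRUE)
  off <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 4 6",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 1 2", "3 0 1 3", "3 0 2 3", "3 1 2 3"), off)
  tet <- read_mesh_off(off)
  expect_equal(nrow(tet$vertices), 4)
  expect_equal(nrow(tet$triangles), 4)
  expect_equal(min(tet$triangles), 1)
})
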