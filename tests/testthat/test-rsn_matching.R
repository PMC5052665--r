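test_that("coarse graining: hand arithmetic and mass conservation", {
  tb <- toy_brain(1, 1)
  v <- c(0.6, 0.8)
  w <- coarse_grain(v, tb$parc, "square")
  expect_equal(unname(w), c(0.36, 0.64))
  expect_equal(sum(w), 1)
  wa <- coarse_grain(v, tb$parc, "absolute")
  expect_equal(unname(wa), c(0.6 / 1.4, 0.8 / 1.4))
  # all mass in one area -> indicator vector
  expect_equal(unname(coarse_grain(c(1, 0), tb$parc, "square")), c(1, 0))
  # unit vector over one-node areas: squares sum to 1 without renormalization
  b <- tiny_bundle()
  nv <- length(node_areas(b$parc))
  u <- random_orthonormal(nv, 1, seed = 2)[, 1]
  cg <- coarse_grain(u, b$parc, "square")
  expect_equal(sum(cg), 1, tolerance = 1e-12)
  expect_true(all(cg >= 0))
  expect_error(coarse_grain(u, b$parc, "cubic"))
})

test_that("candidate patterns: combinatorics and normalization", {
  b <- tiny_bundle()
  nv <- length(node_areas(b$parc))
  V <- random_orthonormal(nv, 3, seed = 3)
  eig <- structure(list(vectors = V, fractions = c(0.6, 0.3, 0.1),
                        condition = list(site = 1, alpha = 0.5, sigma = 10)),
                   class = "eigenspace")
  cands <- candidate_patterns(eig, b$parc)
  expect_equal(names(cands),
               c("EV1", "EV2", "EV3", "EV1+2", "EV1+3", "EV2+3", "EV1+2+3"))
  for (w in cands) expect_equal(sum(w), 1, tolerance = 1e-12)
  eig$vectors <- V[, 1:2]
  expect_equal(names(candidate_patterns(eig, b$parc)),
               c("EV1", "EV2", "EV1+2"))
  eig$vectors <- cbind(V[, 1], V[, 1], V[, 1])
  cands_same <- candidate_patterns(eig, b$parc)
  for (w in cands_same) expect_equal(unname(w), unname(cands_same[[1]]))
})

test_that("Bhattacharyya coefficient closed forms and properties", {
  expect_equal(bhattacharyya_coefficient(c(0.2, 0.8), c(0.2, 0.8)), 1)
  expect_equal(bhattacharyya_coefficient(c(1, 0), c(0, 1)), 0)
  expect_equal(bhattacharyya_coefficient(c(0.5, 0.5), c(1, 0)), sqrt(0.5))
  set.seed(6)
  for (i in 1:20) {
    p <- rexp(10); p <- p / sum(p)
    q <- rexp(10); q <- q / sum(q)
    expect_equal(bhattacharyya_coefficient(p, q),
                 bhattacharyya_coefficient(q, p))
    expect_lt(bhattacharyya_coefficient(p, q), 1)   # BC = 1 iff p == q
    expect_equal(bhattacharyya_coefficient(p, p), 1, tolerance = 1e-12)
  }
  expect_error(bhattacharyya_coefficient(c(-0.1, 1.1), c(0.5, 0.5)),
               "negative")
})

test_that("permutation test formula and seed reproducibility", {
  b <- tiny_bundle()
  mask <- b$masks[[1]]
  # candidate identical to the mask: nothing can strictly exceed BC = 1
  mr <- permutation_test(mask$weights, mask, N = 99, seed = 1)
  expect_equal(mr$BC, 1)
  expect_equal(mr$n_exceed, 0L)
  expect_equal(mr$p, 1 / 100)
  mr2 <- permutation_test(mask$weights, mask, N = 999, seed = 3)
  expect_equal(mr2$p, 1 / 1000)
  set.seed(99)
  cand <- rexp(length(mask$weights)); cand <- cand / sum(cand)
  a <- permutation_test(cand, mask, N = 500, seed = 7)
  b2 <- permutation_test(cand, mask, N = 500, seed = 7)
  expect_identical(a$n_exceed, b2$n_exceed)
  expect_equal(a$p, (a$n_exceed + 1) / 501)
})

test_that("Holm correction: arithmetic, monotonicity, single p", {
  expect_equal(holm_correct(c(0.01, 0.04), m = 2), c(0.02, 0.04))
  expect_equal(holm_correct(0.03, m = 1), 0.03)
  expect_equal(holm_correct(c(0.2, 0.01), m = 4), c(0.6, 0.04))
  set.seed(8)
  p <- runif(10)
  adj <- holm_correct(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # agrees with the standard step-down implementation
  expect_equal(holm_correct(p), p.adjust(p, "holm"))
  expect_error(holm_correct(c(0.5, 1.2)), "p values")
  expect_error(holm_correct(c(0.5, 0.2), m = 1), "family size")
})

test_that("graph metrics: hand examples and an adjacency-loop oracle", {
  # mutual triangle, unit weights: clustering 1 everywhere
  W <- matrix(1, 3, 3); diag(W) <- 0
  gm <- graph_metrics(heterogeneous_sc(W, W * 60, normalize = FALSE))
  expect_equal(gm$clustering, rep(1, 3))
  expect_equal(gm$in_degree, rep(2, 3))
  expect_equal(gm$total_strength, rep(4, 3))
  # out-star: centre clustering 0
  W <- matrix(0, 4, 4); W[2:4, 1] <- 1
  gm2 <- graph_metrics(heterogeneous_sc(W, W * 60, normalize = FALSE))
  expect_equal(gm2$clustering[1], 0)
  expect_equal(gm2$out_degree, c(3, 0, 0, 0))
  # edges A->B, C->B: in-degree(B) = 2, out-degree(B) = 0
  W <- matrix(0, 3, 3); W[2, 1] <- 1; W[2, 3] <- 1
  gm3 <- graph_metrics(heterogeneous_sc(W, W * 60, normalize = FALSE))
  expect_equal(gm3$in_degree[2], 2)
  expect_equal(gm3$out_degree[2], 0)
  # oracle: scalar loops over the adjacency for degrees/strengths
  for (i in 1:10) {
    het <- random_het(10, 0.3, seed = 500 + i)
    W <- het$weights
    gm <- graph_metrics(het)
    for (a in 1:10) {
      expect_equal(gm$in_degree[a], sum(W[a, ] > 0))
      expect_equal(gm$out_degree[a], sum(W[, a] > 0))
      expect_equal(gm$in_strength[a], sum(W[a, ]))
      expect_equal(gm$out_strength[a], sum(W[, a]))
      expect_equal(gm$total_degree[a], sum(W[a, ] > 0) + sum(W[, a] > 0))
    }
    # clustering against igraph's Barrat-free binary version on the
    # symmetrized unweighted graph is not identical by design; check range
    expect_true(all(gm$clustering >= 0 & gm$clustering <= 1 + 1e-12))
  }
})

test_that("cortical versus subcortical distribution tests", {
  b <- tiny_bundle()
  fun <- functional_areas(b$parc)
  kind <- b$parc$areas$kind[match(fun, b$parc$areas$id)]
  w <- rep(1 / length(fun), length(fun))
  same <- cortical_subcortical_tests(w, b$parc)
  expect_gt(same$ks_p, 0.9)
  expect_false(same$ks_significant)
  # clearly separated supports with n >= 20 per group
  g <- generate_sphere_mesh(150, 50, seed = 31, n_subcortical = 20)
  p20 <- generate_parcellation(g, 11, 20, seed = 31)
  fun20 <- functional_areas(p20)
  kind20 <- p20$areas$kind[match(fun20, p20$areas$id)]
  w2 <- ifelse(kind20 == "cortical", 1, 100)
  w2 <- w2 / sum(w2)
  sep <- cortical_subcortical_tests(w2, p20)
  expect_lt(sep$ks_p, 0.01)
  expect_lt(sep$ranksum_p, 0.01)
  expect_true(sep$ks_significant && sep$ranksum_significant)
  # invariance under within-group permutation
  set.seed(1)
  w3 <- w2
  ci <- which(kind20 == "cortical")
  w3[ci] <- w3[sample(ci)]
  sep2 <- cortical_subcortical_tests(w3, p20)
  expect_equal(sep2$ks_p, sep$ks_p)
  expect_equal(sep2$ranksum_p, sep$ranksum_p)
})

test_that("optimal-parameter selection scans the significant table", {
  toy <- function(metric, alpha, sigma, rsn, BC, sig, site = 1L)
    data.frame(site = site, alpha = alpha, sigma = sigma, metric = metric,
               candidate = "EV1", rsn = rsn, BC = BC, p = 0.001,
               p_corrected = if (sig) 0.01 else 0.5, significant = sig,
               stringsAsFactors = FALSE)
  b <- tiny_bundle()
  tab <- rbind(
    toy("square", 0.6, 10, "visual", 0.9, TRUE),
    toy("square", 0.6, 10, "memory", 0.7, TRUE),
    toy("square", 0.2, 10, "visual", 0.95, TRUE),
    toy("absolute", 0.6, 10, "visual", 0.99, FALSE))   # not significant
  res <- select_optimal_parameters(tab, b$parc)
  expect_equal(res$combined$alpha, 0.6)        # (0.9+0.7)/8 > 0.95/8
  expect_equal(res$combined$metric, "square")
  expect_equal(res$combined$mean_BC, (0.9 + 0.7) / 8)
  # single significant entry
  one <- toy("square", 0.2, 15, "visual", 0.9, TRUE)
  expect_equal(select_optimal_parameters(one, b$parc)$combined$sigma, 15)
  # no significant matches -> NULL
  none <- toy("square", 0.2, 15, "visual", 0.9, FALSE)
  expect_null(select_optimal_parameters(none, b$parc)$combined)
  # grouping by site kind
  sub_site <- b$parc$areas$id[b$parc$areas$kind == "subcortical"][1]
  tab2 <- rbind(toy("square", 0.6, 10, "visual", 0.9, TRUE, site = 1L),
                toy("square", 1.0, 10, "visual", 0.8, TRUE, site = sub_site))
  res2 <- select_optimal_parameters(tab2, b$parc)
  expect_equal(res2$cortical$alpha, 0.6)
  expect_equal(res2$subcortical$alpha, 1.0)
})

test_that("stimulation map keeps the best significant row per site and RSN", {
  b <- tiny_bundle()
  row <- function(site, rsn, BC, cand, sig = TRUE)
    data.frame(site = site, alpha = 0.6, sigma = 10, metric = "square",
               candidate = cand, rsn = rsn, BC = BC, p = 1e-3,
               p_corrected = if (sig) 0.02 else 0.6, significant = sig,
               stringsAsFactors = FALSE)
  expect_equal(nrow(build_stimulation_map(row(1, "visual", 0.9, "EV1",
                                              sig = FALSE), b$parc)), 0)
  one <- build_stimulation_map(row(1, "visual", 0.9, "EV2"), b$parc)
  expect_equal(nrow(one), 1)
  expect_equal(one$BC, 0.9)
  expect_equal(one$eigenvector, "EV2")
  # BC tie between candidates: lowest candidate id wins
  tie <- rbind(row(1, "visual", 0.9, "EV3"), row(1, "visual", 0.9, "EV1"))
  expect_equal(build_stimulation_map(tie, b$parc)$eigenvector, "EV1")
})
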