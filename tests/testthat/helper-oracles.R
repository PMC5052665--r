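# Independent oracles and hand-built fixtures shared across test files.
# These deliberately re-derive quantities by the dumbest possible route
# (scalar loops, brute force) so they cannot share bugs with the package.

# Scalar-loop Heun reference for the delayed network: mirrors the model
# definition (instantaneous homogeneous term, delayed area-mean heterogeneous
# term, zero history) without any of the package's vectorized machinery.
reference_network <- function(homW, C, dsteps, node_area, stim_nodes,
                              stim_amp, stim_on, stim_off, alpha, eta,
                              gamma, epsilon, n_steps, dt) {
  N <- nrow(homW); A <- nrow(C)
  x1 <- numeric(N); x2 <- numeric(N)
  buf <- matrix(0, A, n_steps + 1)
  rec1 <- matrix(0, N, n_steps + 1); rec2 <- matrix(0, N, n_steps + 1)
  area_mean <- function(v) {
    out <- numeric(A)
    for (a in 1:A) {
      idx <- which(node_area == a)
      if (length(idx)) out[a] <- mean(v[idx])
    }
    out
  }
  drive_at <- function(v1, t_idx, pm) {
    d <- numeric(N)
    for (i in 1:N) {
      s <- 0
      for (j in 1:N) s <- s + homW[i, j] * v1[j]
      h <- 0
      a <- node_area[i]
      for (b in 1:A) if (C[a, b] != 0) {
        idx <- t_idx - dsteps[a, b]
        m <- if (dsteps[a, b] == 0 && !is.null(pm)) pm[b]
             else if (idx >= 0) buf[b, idx + 1] else 0
        h <- h + C[a, b] * m
      }
      d[i] <- (1 - alpha) * s + alpha * h
    }
    d
  }
  for (t in 0:(n_steps - 1)) {
    buf[, t + 1] <- area_mean(x1)
    s1 <- if (t >= stim_on && t < stim_off) stim_amp else 0
    s2 <- s1          # stimulus constant over the step interval
    dr <- drive_at(x1, t, NULL)
    dr[stim_nodes] <- dr[stim_nodes] + s1
    k11 <- eta * (x2 - gamma * x1 - x1^3) + eta * dr
    k12 <- -eta * epsilon * x1
    y1 <- x1 + dt * k11; y2 <- x2 + dt * k12
    dr2 <- drive_at(y1, t + 1, area_mean(y1))
    dr2[stim_nodes] <- dr2[stim_nodes] + s2
    k21 <- eta * (y2 - gamma * y1 - y1^3) + eta * dr2
    k22 <- -eta * epsilon * y1
    x1 <- x1 + dt / 2 * (k11 + k21)
    x2 <- x2 + dt / 2 * (k12 + k22)
    rec1[, t + 2] <- x1; rec2[, t + 2] <- x2
  }
  list(psi1 = rec1, psi2 = rec2)
}

# Toy brains built by hand (no generators): single-node "hemispheric" areas
# so area means equal node traces.  Asymmetric toys cannot satisfy the
# 2m + n area-count invariant of the exported constructor, so the object is
# assembled directly.
toy_parcellation <- function(area_id, areas, m, n_subcortical = 0L) {
  structure(list(area_id = as.integer(area_id), areas = areas,
                 m = as.integer(m), n_subcortical = as.integer(n_subcortical)),
            class = "parcellation")
}

toy_brain <- function(n_left = 1, n_right = 1) {
  n <- n_left + n_right
  vx <- cbind(seq_len(n), 0, 0)
  geometry <- brain_geometry(vx, matrix(integer(0), 0, 3),
                             c(rep("left", n_left), rep("right", n_right)),
                             NULL)
  areas <- data.frame(id = seq_len(n), name = paste0("A", seq_len(n)),
                      kind = "cortical",
                      hemisphere = c(rep("left", n_left),
                                     rep("right", n_right)),
                      is_callosal = FALSE, stringsAsFactors = FALSE)
  parc <- toy_parcellation(seq_len(n), areas, m = n_left)
  list(geometry = geometry, parc = parc)
}

zero_hom <- function(n, sigma = 10)
  homogeneous_sc(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                      x = numeric(0), dims = c(n, n)), sigma)

# delay-weighted single-source shortest paths via igraph (automaton oracle)
igraph_activation <- function(het, seed_area) {
  A <- nrow(het$weights)
  idx <- which(het$weights > 0, arr.ind = TRUE)   # [target, source]
  g <- igraph::make_empty_graph(A, directed = TRUE)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 2], idx[, 1]))
    igraph::E(g)$weight <- het$delays[idx]
  }
  as.numeric(igraph::distances(g, v = seed_area, mode = "out",
                               algorithm = "dijkstra"))
}

random_het <- function(A, density, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(A * A) < density, A, A) * stats::runif(A * A)
  diag(W) <- 0
  L <- matrix(stats::runif(A * A, 10, 150), A, A)
  L <- (L + t(L)) / 2
  heterogeneous_sc(W, L, speed = 6)
}

random_orthonormal <- function(n, k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
}

# cached small fixtures (built once per test run)
tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("tiny", seed = 42L)
    cache
  }
})
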