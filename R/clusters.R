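#' Subspace similarity of two response eigenspaces
#'
#' Mean of the singular values of the cross-product of the two orthonormal
#' bases, i.e. the mean principal-angle cosine.  Invariant to rotations
#' within each subspace; reduces to the absolute dot product for
#' one-dimensional spaces; 1 for identical subspaces, 0 for mutually
#' orthogonal ones.
#'
#' @param a,b [decompose_response()] eigenspaces (or plain orthonormal
#'   node x k matrices) over the same node set.
#' @return similarity in `[0, 1]`.
#' @export
eigenspace_similarity <- function(a, b) {
  Va <- if (inherits(a, "eigenspace")) a$vectors else as.matrix(a)
  Vb <- if (inherits(b, "eigenspace")) b$vectors else as.matrix(b)
  if (nrow(Va) != nrow(Vb))
    stop("eigenspaces span different node sets", call. = FALSE)
  s <- svd(crossprod(Va, Vb), nu = 0, nv = 0)$d
  mean(pmin(1, s))
}

#' Pairwise similarity matrix of a list of eigenspaces
#'
#' @param spaces list of eigenspaces.
#' @return symmetric matrix with unit diagonal.
#' @export
similarity_matrix <- function(spaces) {
  n <- length(spaces)
  S <- diag(1, n)
  if (n > 1)
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        S[i, j] <- S[j, i] <- eigenspace_similarity(spaces[[i]], spaces[[j]])
  S
}

# Pooled within-cluster dispersion (sum of squared distances to centroids).
within_dispersion <- function(X, labels) {
  sum(vapply(split(seq_len(nrow(X)), labels), function(idx) {
    Xi <- X[idx, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi), "-")^2)
  }, numeric(1)))
}

kmeans_labels <- function(X, k, nstart = 20) {
  n <- nrow(X)
  if (k == 1) return(rep(1L, n))
  if (k >= n) return(seq_len(n))   # every point its own cluster
  stats::kmeans(X, centers = k, nstart = nstart, iter.max = 50)$cluster
}

#' Cluster eigenspaces with k-means and the gap statistic
#'
#' The rows of the similarity matrix serve as feature vectors; k-means (20
#' restarts) partitions them for k = 1..k_max and the number of clusters is
#' chosen by the gap statistic with a uniform reference over the feature
#' bounding box: the smallest k with
#' `gap(k) >= gap(k+1) - s(k+1)` (ties toward smaller k).
#'
#' @param S square symmetric similarity matrix.
#' @param k_max largest cluster count considered (clipped with a warning when
#'   there are fewer distinct items).
#' @param B_reference reference draws for the gap statistic (default 50).
#' @param seed integer RNG seed.
#' @return list with `labels`, `k`, `gap` (per-k gap values) and `s`
#'   (reference spreads).
#' @export
cluster_eigenspaces <- function(S, k_max = 8L, B_reference = 50L, seed = 1L) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("similarity matrix must be square and symmetric", call. = FALSE)
  n <- nrow(S)
  n_distinct <- nrow(unique(round(S, 12)))
  if (k_max > n_distinct) {
    warning("k_max clipped to the number of distinct items")
    k_max <- n_distinct
  }
  set.seed(seed)
  ks <- seq_len(k_max)
  logW <- numeric(k_max)
  labels_k <- vector("list", k_max)
  for (k in ks) {
    labels_k[[k]] <- kmeans_labels(S, k)
    logW[k] <- log(max(within_dispersion(S, labels_k[[k]]), 1e-300))
  }
  lo <- apply(S, 2, min); hi <- apply(S, 2, max)
  ref <- matrix(0, B_reference, k_max)
  for (b in seq_len(B_reference)) {
    Xb <- sapply(seq_len(ncol(S)), function(j) stats::runif(n, lo[j], hi[j]))
    Xb <- matrix(Xb, nrow = n)
    for (k in ks)
      ref[b, k] <- log(max(within_dispersion(Xb, kmeans_labels(Xb, k)), 1e-300))
  }
  gap <- colMeans(ref) - logW
  s <- apply(ref, 2, stats::sd) * sqrt(1 + 1 / B_reference)
  k_hat <- k_max
  for (k in seq_len(k_max - 1)) {
    if (gap[k] >= gap[k + 1] - s[k + 1]) { k_hat <- k; break }
  }
  list(labels = labels_k[[k_hat]], k = k_hat, gap = gap, s = s)
}

#' Align eigenspaces within a cluster and average them
#'
#' The reference member is the one with the highest mean similarity to all
#' others; every member is rotated onto it by the orthogonal Procrustes
#' solution (SVD of the cross-product), the aligned bases are averaged
#' elementwise, and the mean is re-orthonormalized by its polar factor.
#'
#' @param members non-empty list of eigenspaces with equal node dimension.
#' @return An object of class `network_cluster`: `vectors` (node x k
#'   orthonormal), `reference` (index of the reference member), `n_members`.
#' @export
align_and_average <- function(members) {
  if (length(members) == 0) stop("empty cluster", call. = FALSE)
  get_V <- function(m) if (inherits(m, "eigenspace")) m$vectors else as.matrix(m)
  Vs <- lapply(members, get_V)
  n <- length(Vs)
  if (n == 1) {
    return(structure(list(vectors = Vs[[1]], reference = 1L, n_members = 1L),
                     class = "network_cluster"))
  }
  S <- similarity_matrix(Vs)
  ref <- which.max((rowSums(S) - 1) / (n - 1))
  R <- Vs[[ref]]
  k_ref <- ncol(R)
  aligned <- lapply(Vs, function(M) {
    sv <- svd(crossprod(M, R))
    M %*% (sv$u %*% t(sv$v))        # orthogonal Procrustes rotation onto R
  })
  avg <- Reduce(`+`, aligned) / n
  sv <- svd(avg)
  keep <- which(sv$d > 1e-8 * max(sv$d))
  V <- (sv$u[, keep, drop = FALSE]) %*% t(sv$v[, keep, drop = FALSE])
  V <- V[, seq_len(min(k_ref, ncol(V))), drop = FALSE]
  structure(list(vectors = canonicalize_signs(V), reference = ref,
                 n_members = n),
            class = "network_cluster")
}

#' Repertoire of dynamically responsive networks for one condition
#'
#' Clusters the per-site eigenspaces of one (alpha, sigma) condition, aligns
#' and averages each cluster, and counts (1) the distinct responsive networks
#' (the chosen k) and (2) the effective stimulation sites: sites whose
#' eigenspace has similarity at least `threshold` to its assigned cluster
#' mean.
#'
#' @param spaces list of eigenspaces, one per stimulation site.
#' @param threshold effective-site similarity threshold (default 0.8).
#' @param k_max,B_reference,seed passed to [cluster_eigenspaces()].
#' @return list with `n_networks`, `n_effective_sites`, `labels`, `clusters`
#'   (list of [align_and_average()] results) and `site_similarity`.
#' @export
repertoire_counts <- function(spaces, threshold = 0.8, k_max = 8L,
                              B_reference = 50L, seed = 1L) {
  S <- similarity_matrix(spaces)
  cl <- cluster_eigenspaces(S, k_max = k_max, B_reference = B_reference,
                            seed = seed)
  if (!is.null(names(spaces))) names(cl$labels) <- names(spaces)
  clusters <- lapply(seq_len(cl$k), function(k)
    align_and_average(spaces[cl$labels == k]))
  sim <- vapply(seq_along(spaces), function(i)
    eigenspace_similarity(spaces[[i]], clusters[[cl$labels[i]]]$vectors),
    numeric(1))
  list(n_networks = cl$k, n_effective_sites = sum(sim >= threshold),
       labels = cl$labels, clusters = clusters, site_similarity = sim)
}
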