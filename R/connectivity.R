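#' Short-range homogeneous structural connectivity
#'
#' Sparse node-by-node weight matrix in target-row convention
#' (`weights[i, j]` couples node j into node i).  Weights follow the
#' translation-invariant Gaussian kernel `g(d) = exp(-d^2 / (2 sigma^2))` on
#' intra-hemispheric cortical distances, truncated at `cutoff * sigma` and
#' renormalized so that the incoming weights of every connected node sum to 1
#' (discrete form of the unit-mass kernel normalization).  There are no
#' interhemispheric links, callosal-patch nodes are fully isolated, and
#' subcortical nodes carry no homogeneous connectivity.
#'
#' @param weights a `Matrix::dgCMatrix` over the full node set.
#' @param sigma spatial range in mm.
#' @return An object of class `homogeneous_sc`.
#' @export
homogeneous_sc <- function(weights, sigma) {
  stopifnot(inherits(weights, "sparseMatrix"), sigma > 0)
  structure(list(weights = weights, sigma = sigma), class = "homogeneous_sc")
}

#' @export
print.homogeneous_sc <- function(x, ...) {
  cat(sprintf("homogeneous_sc: %d nodes, %d nonzeros, sigma = %g mm\n",
              nrow(x$weights), Matrix::nnzero(x$weights), x$sigma))
  invisible(x)
}

#' Build the homogeneous SC from a geometry and parcellation
#'
#' @param geometry a [brain_geometry()].
#' @param parc a [parcellation()].
#' @param sigma Gaussian spatial range in mm (> 0).
#' @param cutoff kernel truncation radius in multiples of sigma (default 4,
#'   retaining > 99.99 percent of the kernel mass).
#' @return A [homogeneous_sc()] whose matrix spans the full node set
#'   (cortical then subcortical); subcortical and callosal rows/columns are
#'   zero, all other rows sum to 1.
#' @export
build_homogeneous_sc <- function(geometry, parc, sigma, cutoff = 4) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  nc <- nrow(geometry$vertices)
  ns <- nrow(geometry$subcortical)
  d <- cortical_distances(geometry)
  callosal_ids <- parc$areas$id[parc$areas$is_callosal]
  callosal_nodes <- which(parc$area_id %in% callosal_ids)
  keep <- is.finite(d) & d <= cutoff * sigma
  if (length(callosal_nodes)) {
    keep[callosal_nodes, ] <- FALSE
    keep[, callosal_nodes] <- FALSE
  }
  ij <- which(keep, arr.ind = TRUE)
  w <- exp(-d[ij]^2 / (2 * sigma^2))
  W <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = w,
                            dims = c(nc + ns, nc + ns))
  rs <- Matrix::rowSums(W)
  sc <- ifelse(rs > 0, 1 / rs, 0)
  W <- Matrix::Diagonal(x = sc) %*% W
  homogeneous_sc(methods::as(W, "CsparseMatrix"), sigma)
}

#' Long-range heterogeneous structural connectivity
#'
#' Directed area-by-area weights in target-row convention (`weights[i, j]` is
#' the connection j -> i), tract lengths in mm, a finite transmission speed in
#' m/s, and the derived delay matrix `delays = lengths / speed` in seconds
#' (zero where there is no connection).  Weights are normalized so the
#' maximum over target areas of the incoming weight sum equals 1.
#'
#' @param weights,lengths square numeric matrices (areas x areas).
#' @param speed transmission speed in m/s.
#' @param normalize normalize to unity maximum in-strength (default TRUE).
#' @return An object of class `heterogeneous_sc`.
#' @export
heterogeneous_sc <- function(weights, lengths, speed = 6, normalize = TRUE) {
  weights <- as.matrix(weights)
  lengths <- as.matrix(lengths)
  if (nrow(weights) != ncol(weights) || !all(dim(weights) == dim(lengths)))
    stop("weights and lengths must be square matrices of equal dimension",
         call. = FALSE)
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  if (any(lengths < 0)) stop("negative tract lengths", call. = FALSE)
  if (speed <= 0) stop("speed must be positive", call. = FALSE)
  diag(weights) <- 0
  if (normalize) weights <- normalize_heterogeneous(weights)
  delays <- lengths / (speed * 1000)        # mm / (m/s * 1000 mm/m) = s
  delays[weights == 0] <- 0
  structure(list(weights = weights, lengths = lengths, speed = speed,
                 delays = delays),
            class = "heterogeneous_sc")
}

#' @export
print.heterogeneous_sc <- function(x, ...) {
  cat(sprintf(
    "heterogeneous_sc: %d areas, %d directed connections, v = %g m/s, max delay = %.1f ms\n",
    nrow(x$weights), sum(x$weights > 0), x$speed, 1000 * max(x$delays)))
  invisible(x)
}

#' Normalize area weights to unity maximum in-strength
#'
#' Divides the whole matrix by the maximum over target areas of the total
#' incoming weight sum, so that no area receives more than unit drive and
#' activity cannot be amplified through the connectivity.
#'
#' @param weights square matrix, target-row convention.
#' @return rescaled matrix with `max(rowSums(.)) == 1` (unchanged if all zero).
#' @export
normalize_heterogeneous <- function(weights) {
  s <- max(rowSums(weights))
  if (s > 0) weights / s else weights
}

#' Generate a random heterogeneous SC over the areas of a parcellation
#'
#' Stand-in for an empirical tracer-based connectome: a directed random
#' weighted graph over the functional areas (callosal patches stay isolated)
#' with log-normal weights, tract lengths equal to Euclidean centroid
#' distances (optionally jittered), and delays derived from a finite
#' transmission speed.
#'
#' @param parc a [parcellation()].
#' @param geometry a [brain_geometry()] (for centroid distances).
#' @param connection_density probability of each directed area pair being
#'   connected, in (0, 1].
#' @param speed transmission speed in m/s.
#' @param seed integer RNG seed.
#' @param length_jitter_sd multiplicative log-normal jitter on tract lengths
#'   (0 = none; tracts are rarely straight lines).
#' @return A [heterogeneous_sc()], normalized.
#' @export
generate_heterogeneous_sc <- function(parc, geometry, connection_density = 0.3,
                                      speed = 6, seed = 1L,
                                      length_jitter_sd = 0) {
  if (connection_density <= 0 || connection_density > 1)
    stop("connection_density must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  A <- n_areas(parc)
  fun <- functional_areas(parc)
  W <- matrix(0, A, A)
  pairs <- expand.grid(i = fun, j = fun)
  pairs <- pairs[pairs$i != pairs$j, ]
  on <- stats::runif(nrow(pairs)) < connection_density
  w <- stats::rlnorm(sum(on), meanlog = 0, sdlog = 1)
  W[cbind(pairs$i[on], pairs$j[on])] <- w
  ctr <- area_centroids(geometry, parc)
  L <- as.matrix(stats::dist(ctr))
  if (length_jitter_sd > 0)
    L <- L * matrix(stats::rlnorm(A * A, 0, length_jitter_sd), A, A)
  heterogeneous_sc(W, L, speed = speed)
}

#' Read / write a connectome in the weights + tract-lengths + centres dialect
#'
#' A connectome is a directory (or zip archive) containing `weights.txt` and
#' `tract_lengths.txt` (whitespace-separated square numeric matrices of equal
#' dimension) and `centres.txt` (`label x y z` per row).  `read_connectome`
#' enforces the target-row orientation (row i = incoming connections of area
#' i) and returns a normalized [heterogeneous_sc()].
#'
#' @param path directory or `.zip` file.
#' @param speed transmission speed in m/s.
#' @return `read_connectome`: a [heterogeneous_sc()] with a `centres`
#'   attribute (data.frame `label`, `x`, `y`, `z`).
#' @export
read_connectome <- function(path, speed = 6) {
  dir <- path
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    dir <- tempfile("connectome")
    utils::unzip(path, exdir = dir)
  }
  f <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop("missing ", name, " in connectome", call. = FALSE)
    p
  }
  read_square <- function(p) {
    rows <- strsplit(trimws(readLines(f(p))), "\\s+")
    rows <- rows[vapply(rows, length, 1L) > 0]
    lens <- vapply(rows, length, 1L)
    if (length(unique(lens)) != 1)
      stop("ragged matrix in ", p, call. = FALSE)
    m <- do.call(rbind, lapply(rows, as.numeric))
    if (anyNA(m)) stop("non-numeric entry in ", p, call. = FALSE)
    if (nrow(m) != ncol(m)) stop(p, " is not square", call. = FALSE)
    m
  }
  W <- read_square("weights.txt")
  L <- read_square("tract_lengths.txt")
  if (!all(dim(W) == dim(L)))
    stop("weights and tract_lengths dimensions differ", call. = FALSE)
  if (any(W < 0)) stop("negative weights in connectome", call. = FALSE)
  cl <- strsplit(trimws(readLines(f("centres.txt"))), "\\s+")
  cl <- cl[vapply(cl, length, 1L) > 0]
  if (length(cl) != nrow(W))
    stop("centres row count does not match matrix dimension", call. = FALSE)
  centres <- data.frame(
    label = vapply(cl, `[`, "", 1),
    x = as.numeric(vapply(cl, `[`, "", 2)),
    y = as.numeric(vapply(cl, `[`, "", 3)),
    z = as.numeric(vapply(cl, `[`, "", 4)))
  het <- heterogeneous_sc(W, L, speed = speed)
  attr(het, "centres") <- centres
  het
}

#' @rdname read_connectome
#' @param het a [heterogeneous_sc()].
#' @param weights un-normalized weight matrix to write instead of the stored
#'   (normalized) one, if the round-trip should preserve raw values.
#' @param centres optional data.frame `label`, `x`, `y`, `z`.
#' @export
write_connectome <- function(het, path, weights = het$weights,
                             centres = attr(het, "centres")) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m, file)
    utils::write.table(m, file.path(path, file), sep = " ",
                       row.names = FALSE, col.names = FALSE)
  fmt(weights, "weights.txt")
  fmt(het$lengths, "tract_lengths.txt")
  if (is.null(centres)) {
    A <- nrow(het$weights)
    centres <- data.frame(label = paste0("area", seq_len(A)),
                          x = 0, y = 0, z = 0)
  }
  utils::write.table(centres, file.path(path, "centres.txt"), sep = " ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
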