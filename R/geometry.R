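#' Brain geometry: two triangulated hemispheric spheres plus subcortical points
#'
#' Container for the spatial substrate of the model: cortical vertices on two
#' closed 2-spheres (one per hemisphere), a closed triangulation of each
#' sphere, and point-like subcortical areas placed between the hemispheres.
#'
#' @param vertices numeric matrix (n x 3) of cortical node coordinates in mm.
#' @param triangles integer matrix (f x 3) of vertex indices (1-based).
#' @param hemisphere character vector, `"left"` or `"right"` per vertex.
#' @param subcortical numeric matrix (s x 3) of subcortical positions in mm
#'   (0-row matrix if none).
#' @param sphere optional list with `centres` (2 x 3 matrix, left/right) and
#'   `radius` (mm); present for synthetic meshes and enables great-circle
#'   distances.  Loaded meshes without it fall back to geodesic graph
#'   distances along mesh edges.
#' @return An object of class `brain_geometry`.
#' @export
brain_geometry <- function(vertices, triangles, hemisphere, subcortical,
                           sphere = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (length(hemisphere) != nrow(vertices))
    stop("hemisphere label required for every vertex", call. = FALSE)
  if (!all(hemisphere %in% c("left", "right")))
    stop("hemisphere labels must be 'left' or 'right'", call. = FALSE)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stop("triangle refers to an invalid vertex", call. = FALSE)
  # no triangle may straddle hemispheres
  tri_hemi <- matrix(hemisphere[triangles], ncol = 3)
  if (nrow(triangles) > 0 && any(tri_hemi[, 1] != tri_hemi[, 2] |
                                 tri_hemi[, 1] != tri_hemi[, 3]))
    stop("a triangle crosses hemispheres", call. = FALSE)
  if (is.null(subcortical)) subcortical <- matrix(numeric(0), 0, 3)
  subcortical <- as.matrix(subcortical)
  structure(list(vertices = vertices,
                 triangles = triangles,
                 hemisphere = hemisphere,
                 subcortical = subcortical,
                 sphere = sphere),
            class = "brain_geometry")
}

#' @export
print.brain_geometry <- function(x, ...) {
  cat(sprintf(
    "brain_geometry: %d cortical vertices (%d left / %d right), %d triangles, %d subcortical points\n",
    nrow(x$vertices), sum(x$hemisphere == "left"),
    sum(x$hemisphere == "right"), nrow(x$triangles), nrow(x$subcortical)))
  invisible(x)
}

# Quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

# Rotation matrix taking unit vector `from` onto unit vector `to` (Rodrigues).
rotation_onto <- function(from, to) {
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  if (abs(c_ + 1) < 1e-12) {   # antipodal: rotate pi about any orthogonal axis
    ax <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * from) * from
    ax <- ax / sqrt(sum(ax^2))
    return(2 * tcrossprod(ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Closed triangulation of points on the unit sphere via stereographic
# projection from a pole far from all data points + planar Delaunay; the
# residual hole around the pole is fan-filled.  Equivalent to the spherical
# Delaunay triangulation away from the pole cap.
sphere_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points to triangulate a sphere", call. = FALSE)
  cand <- fibonacci_sphere(max(500, 4 * n))
  # candidate pole with the largest angular clearance from the data
  dots <- cand %*% t(pts)
  pole <- cand[which.min(apply(dots, 1, max)), ]
  R <- rotation_onto(pole, c(0, 0, 1))
  q <- pts %*% t(R)
  X <- q[, 1] / (1 - q[, 3])
  Y <- q[, 2] / (1 - q[, 3])
  tm <- interp::tri.mesh(X, Y)
  tri <- as.matrix(interp::triangles(tm)[, 1:3])
  hull <- interp::convex.hull(tm)$i
  k <- length(hull)
  if (k >= 3) {
    fan <- cbind(hull[1], hull[2:(k - 1)], hull[3:k])
    tri <- rbind(tri, fan)
  }
  storage.mode(tri) <- "integer"
  tri
}

#' Generate two triangulated hemispheric sphere meshes
#'
#' Fills each hemispheric sphere quasi-uniformly with `nodes_per_hemisphere`
#' nodes (Fibonacci lattice with a seeded random rotation), triangulates each
#' closed sphere, and scatters subcortical point areas in the inter-hemispheric
#' gap.
#'
#' @param nodes_per_hemisphere number of cortical nodes per hemisphere (>= 4).
#' @param radius sphere radius in mm.
#' @param seed integer RNG seed (rotation + subcortical placement).
#' @param n_subcortical number of point-like subcortical areas.
#' @return A [brain_geometry()].
#' @export
generate_sphere_mesh <- function(nodes_per_hemisphere, radius = 50,
                                 seed = 1L, n_subcortical = 0L) {
  if (nodes_per_hemisphere < 4)
    stop("nodes_per_hemisphere must be >= 4", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  set.seed(seed)
  n <- nodes_per_hemisphere
  base <- fibonacci_sphere(n)
  # random rotation so repeated calls with different seeds decorrelate
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  unit <- base %*% R
  tri1 <- sphere_triangulate(unit)
  # hemispheres: spheres of radius r centred at x = -c and x = +c
  cx <- 1.05 * radius
  centres <- rbind(left = c(-cx, 0, 0), right = c(cx, 0, 0))
  vl <- sweep(unit * radius, 2, centres[1, ], "+")
  vr <- sweep(unit * radius, 2, centres[2, ], "+")
  vertices <- rbind(vl, vr)
  triangles <- rbind(tri1, tri1 + n)
  hemisphere <- rep(c("left", "right"), each = n)
  sub <- matrix(numeric(0), 0, 3)
  if (n_subcortical > 0) {
    # uniform in a midline ball (deep grey matter sits between the hemispheres)
    u <- matrix(stats::rnorm(3 * n_subcortical), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rr <- 0.3 * radius * stats::runif(n_subcortical)^(1 / 3)
    sub <- u * rr
  }
  brain_geometry(vertices, triangles, hemisphere, sub,
                 sphere = list(centres = centres, radius = radius))
}

#' Pairwise intra-hemispheric cortical distances
#'
#' Great-circle distance on the generating sphere for synthetic meshes;
#' geodesic graph distance along mesh edges for loaded meshes.  Distances
#' between hemispheres are `Inf` (the hemispheres are disjoint surfaces).
#'
#' @param geometry a [brain_geometry()].
#' @return dense numeric matrix (n x n) over cortical vertices, mm.
#' @export
cortical_distances <- function(geometry) {
  n <- nrow(geometry$vertices)
  d <- matrix(Inf, n, n)
  for (h in c("left", "right")) {
    idx <- which(geometry$hemisphere == h)
    if (!is.null(geometry$sphere)) {
      ctr <- geometry$sphere$centres[if (h == "left") 1 else 2, ]
      r <- geometry$sphere$radius
      u <- sweep(geometry$vertices[idx, , drop = FALSE], 2, ctr, "-") / r
      cosang <- pmin(1, pmax(-1, tcrossprod(u)))
      d[idx, idx] <- r * acos(cosang)
    } else {
      d[idx, idx] <- geodesic_distances(geometry, idx)
    }
  }
  diag(d) <- 0
  d
}

# Geodesic distances along mesh edges (used for meshes loaded from files,
# where the generating sphere is unknown).
geodesic_distances <- function(geometry, idx) {
  tri <- geometry$triangles
  keep <- matrix(tri %in% idx, ncol = 3)
  tri <- tri[rowSums(keep) == 3, , drop = FALSE]
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  w <- sqrt(rowSums((geometry$vertices[edges[, 1], , drop = FALSE] -
                     geometry$vertices[edges[, 2], , drop = FALSE])^2))
  remap <- match(edges, idx)
  g <- igraph::graph_from_edgelist(matrix(remap, ncol = 2), directed = FALSE)
  g <- igraph::simplify(igraph::set_edge_attr(g, "weight", value = w),
                        edge.attr.comb = "min")
  if (igraph::vcount(g) < length(idx))
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  igraph::distances(g)
}

# Undirected vertex adjacency list of the mesh (edge graph of the triangles).
mesh_adjacency <- function(geometry) {
  tri <- geometry$triangles
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  edges <- rbind(edges, edges[, 2:1])
  split(edges[, 2], factor(edges[, 1], levels = seq_len(nrow(geometry$vertices))))
}

#' Write / read a mesh as TSV vertex and triangle tables
#'
#' Vertex table columns: `x`, `y`, `z`, `hemisphere`; triangle table columns:
#' `v1`, `v2`, `v3` (1-based).  Subcortical positions go to a third optional
#' table with columns `x`, `y`, `z`.
#'
#' @param geometry a [brain_geometry()].
#' @param vertices_path,triangles_path,subcortical_path file paths.
#' @return `read_mesh` returns a [brain_geometry()] (without sphere metadata).
#' @export
write_mesh <- function(geometry, vertices_path, triangles_path,
                       subcortical_path = NULL) {
  vt <- data.frame(x = geometry$vertices[, 1], y = geometry$vertices[, 2],
                   z = geometry$vertices[, 3], hemisphere = geometry$hemisphere)
  utils::write.table(vt, vertices_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  tt <- data.frame(v1 = geometry$triangles[, 1], v2 = geometry$triangles[, 2],
                   v3 = geometry$triangles[, 3])
  utils::write.table(tt, triangles_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(subcortical_path)) {
    st <- data.frame(x = geometry$subcortical[, 1],
                     y = geometry$subcortical[, 2],
                     z = geometry$subcortical[, 3])
    utils::write.table(st, subcortical_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(geometry)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(vertices_path, triangles_path, subcortical_path = NULL) {
  vt <- utils::read.table(vertices_path, header = TRUE, sep = "\t")
  tt <- utils::read.table(triangles_path, header = TRUE, sep = "\t")
  sub <- NULL
  if (!is.null(subcortical_path)) {
    st <- utils::read.table(subcortical_path, header = TRUE, sep = "\t")
    sub <- as.matrix(st[, c("x", "y", "z")])
  }
  brain_geometry(as.matrix(vt[, c("x", "y", "z")]),
                 as.matrix(tt[, c("v1", "v2", "v3")]),
                 as.character(vt$hemisphere), sub)
}

#' Read a mesh in OFF format (single surface, assigned to one hemisphere)
#'
#' @param path OFF file.
#' @param hemisphere hemisphere label for all vertices.
#' @return A [brain_geometry()] without subcortical points.
#' @export
read_mesh_off <- function(path, hemisphere = "left") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file", call. = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  vx <- t(vapply(lines[3:(2 + nv)],
                 function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3]),
                 numeric(3)))
  fc <- t(vapply(lines[(3 + nv):(2 + nv + nf)],
                 function(s) as.integer(strsplit(trimws(s), "\\s+")[[1]][1:4]),
                 integer(4)))
  if (any(fc[, 1] != 3L)) stop("only triangular OFF faces supported", call. = FALSE)
  brain_geometry(vx, fc[, 2:4] + 1L, rep(hemisphere, nv), NULL)
}
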