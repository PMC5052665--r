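#' Parcellation of the cortical meshes into contiguous areas
#'
#' Each hemispheric sphere is divided into `m` contiguous patches grown over
#' the mesh adjacency from seed nodes; exactly one patch per hemisphere (on
#' the medial face, where the corpus callosum pierces the sphere) is flagged
#' callosal and is excluded from all connectivity.  Each subcortical point is
#' its own singleton area.  Area ids run left cortical (1..m), right cortical
#' (m+1..2m), subcortical (2m+1..2m+n); the callosal patch is the last area of
#' its hemisphere.
#'
#' @param area_id integer vector, area id per cortical node.
#' @param areas data.frame with columns `id`, `name`, `kind`
#'   (`"cortical"`/`"subcortical"`), `hemisphere` (`"left"`, `"right"`, `NA`),
#'   `is_callosal` (logical).
#' @param m cortical areas per hemisphere (including the callosal patch).
#' @param n_subcortical number of subcortical areas.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(area_id, areas, m, n_subcortical) {
  stopifnot(is.data.frame(areas),
            all(c("id", "name", "kind", "hemisphere", "is_callosal") %in%
                names(areas)))
  if (anyNA(area_id)) stop("every cortical node needs an area", call. = FALSE)
  if (nrow(areas) != 2 * m + n_subcortical)
    stop("area count must equal 2*m + n_subcortical", call. = FALSE)
  cort <- areas$id[areas$kind == "cortical" & !areas$is_callosal]
  sizes <- tabulate(area_id, nbins = nrow(areas))
  if (any(sizes[cort] < 1))
    stop("every non-callosal cortical area needs at least one node",
         call. = FALSE)
  structure(list(area_id = as.integer(area_id), areas = areas,
                 m = as.integer(m), n_subcortical = as.integer(n_subcortical)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "parcellation: %d areas (2 x %d cortical incl. callosal, %d subcortical), %d cortical nodes\n",
    nrow(x$areas), x$m, x$n_subcortical, length(x$area_id)))
  invisible(x)
}

#' @export
#' @rdname parcellation
#' @param parc a `parcellation`.
n_areas <- function(parc) nrow(parc$areas)

#' Functional (non-callosal) area ids
#' @param parc a [parcellation()].
#' @return integer vector of area ids.
#' @export
functional_areas <- function(parc) parc$areas$id[!parc$areas$is_callosal]

#' Area membership of every node (cortical nodes then subcortical singletons)
#'
#' @param parc a [parcellation()].
#' @return integer vector of length n_cortical + n_subcortical: the area id of
#'   each node in the full node set used by the simulator.
#' @export
node_areas <- function(parc) {
  sub_ids <- parc$areas$id[parc$areas$kind == "subcortical"]
  c(parc$area_id, sub_ids)
}

# Node index lists per area over the full node set.
area_members <- function(parc) {
  na <- node_areas(parc)
  split(seq_along(na), factor(na, levels = parc$areas$id))
}

#' Grow a parcellation on a synthetic brain geometry
#'
#' Patches are grown by multi-source breadth-first search over the mesh
#' adjacency from `areas_per_hemisphere` seed nodes per hemisphere, so every
#' patch is a connected subgraph of the mesh.  The callosal seed is the node
#' nearest the medial pole of each sphere; the remaining seeds are drawn at
#' random.
#'
#' @param geometry a [brain_geometry()].
#' @param areas_per_hemisphere areas per hemisphere incl. the callosal patch
#'   (>= 2).
#' @param n_subcortical number of subcortical areas; must match the number of
#'   subcortical points in `geometry`.
#' @param seed integer RNG seed.
#' @return A [parcellation()].
#' @export
generate_parcellation <- function(geometry, areas_per_hemisphere,
                                  n_subcortical = nrow(geometry$subcortical),
                                  seed = 1L) {
  m <- as.integer(areas_per_hemisphere)
  if (m < 2)
    stop("areas_per_hemisphere must be >= 2 (functional + callosal)",
         call. = FALSE)
  if (n_subcortical != nrow(geometry$subcortical))
    stop("n_subcortical must match the subcortical points in the geometry",
         call. = FALSE)
  nh <- table(geometry$hemisphere)
  if (any(m > nh)) stop("more areas than nodes in a hemisphere", call. = FALSE)
  set.seed(seed)
  adj <- mesh_adjacency(geometry)
  area_id <- rep(NA_integer_, nrow(geometry$vertices))
  for (h in c("left", "right")) {
    idx <- which(geometry$hemisphere == h)
    offset <- if (h == "left") 0L else m
    medial <- if (h == "left") c(1, 0, 0) else c(-1, 0, 0)
    ctr <- if (!is.null(geometry$sphere)) {
      geometry$sphere$centres[if (h == "left") 1 else 2, ]
    } else colMeans(geometry$vertices[idx, , drop = FALSE])
    u <- sweep(geometry$vertices[idx, , drop = FALSE], 2, ctr, "-")
    callosal_seed <- idx[which.max(u %*% medial)]
    others <- sample(setdiff(idx, callosal_seed), m - 1L)
    seeds <- c(others, callosal_seed)           # callosal is last area
    # multi-source BFS: graph Voronoi with deterministic queue order
    lab <- rep(NA_integer_, nrow(geometry$vertices))
    lab[seeds] <- seq_len(m)
    queue <- seeds
    while (length(queue) > 0) {
      nxt <- integer(0)
      for (v in queue) {
        nb <- adj[[v]]
        free <- nb[is.na(lab[nb])]
        if (length(free)) {
          lab[free] <- lab[v]
          nxt <- c(nxt, free)
        }
      }
      queue <- nxt
    }
    area_id[idx] <- lab[idx] + offset
  }
  hemi <- rep(c("left", "right"), each = m)
  nm <- c(paste0("L.", c(seq_len(m - 1), "CC")),
          paste0("R.", c(seq_len(m - 1), "CC")))
  areas <- data.frame(
    id = seq_len(2L * m + n_subcortical),
    name = c(nm, if (n_subcortical > 0) paste0("S.", seq_len(n_subcortical))),
    kind = c(rep("cortical", 2L * m), rep("subcortical", n_subcortical)),
    hemisphere = c(hemi, rep(NA_character_, n_subcortical)),
    is_callosal = c(rep(c(rep(FALSE, m - 1L), TRUE), 2), rep(FALSE, n_subcortical)),
    stringsAsFactors = FALSE)
  parcellation(area_id, areas, m, n_subcortical)
}

#' Area centroids over the full area set
#'
#' Cortical areas: mean coordinate of member vertices; subcortical areas:
#' their point position.
#'
#' @param geometry a [brain_geometry()].
#' @param parc a [parcellation()].
#' @return numeric matrix (n_areas x 3), mm.
#' @export
area_centroids <- function(geometry, parc) {
  A <- n_areas(parc)
  out <- matrix(NA_real_, A, 3)
  for (a in seq_len(2L * parc$m)) {
    nodes <- which(parc$area_id == a)
    out[a, ] <- colMeans(geometry$vertices[nodes, , drop = FALSE])
  }
  if (parc$n_subcortical > 0)
    out[(2L * parc$m + 1L):A, ] <- geometry$subcortical
  out
}
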