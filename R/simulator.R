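#' Simulation configuration
#'
#' @param alpha balance of the two connectivities in `[0, 1]`: 0 = purely
#'   homogeneous (short-range), 1 = purely heterogeneous (long-range
#'   delayed).
#' @param dt integration step in s (default 4e-5).
#' @param duration total simulated time in s.
#' @param record_stride keep every `record_stride`-th step (default 25, i.e.
#'   1 ms at the default dt).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(alpha, duration, dt = 4e-5, record_stride = 25L) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  structure(list(alpha = alpha, dt = dt, duration = duration,
                 record_stride = as.integer(record_stride)),
            class = "sim_config")
}

#' Simulate the full delayed network
#'
#' Integrates the coupled node flows with Heun's method: instantaneous
#' homogeneous coupling `(1-alpha) * sum_j homW[i,j] psi1_j(t)`, delayed
#' area-mean heterogeneous coupling
#' `alpha * sum_b c[a(i),b] <psi1>_b(t - tau[a(i),b])`, and a constant
#' stimulus applied simultaneously to all nodes of the target area.  Delays
#' are rounded to the nearest integer step; history before t = 0 is zero.
#'
#' @param geometry a [brain_geometry()].
#' @param parc a [parcellation()].
#' @param hom a [homogeneous_sc()].
#' @param het a [heterogeneous_sc()].
#' @param params a [node_params()].
#' @param stim a [stimulus_spec()] (or NULL for no stimulation).
#' @param cfg a [sim_config()].
#' @return An object of class `sim_result`: `psi1`, `psi2`
#'   (node x recorded-time matrices over cortical-then-subcortical nodes),
#'   `times`, `dt_recorded`, `stim`, `condition`.
#' @export
simulate_network <- function(geometry, parc, hom, het, params, stim, cfg) {
  na <- node_areas(parc)
  N <- length(na)
  if (nrow(hom$weights) != N)
    stop("homogeneous SC dimension does not match the node set", call. = FALSE)
  if (nrow(het$weights) != n_areas(parc))
    stop("heterogeneous SC dimension does not match the parcellation",
         call. = FALSE)
  n_steps <- as.integer(ceiling(cfg$duration / cfg$dt))
  dsteps <- matrix(as.integer(round(het$delays / cfg$dt)),
                   nrow(het$delays), ncol(het$delays))
  if (max(dsteps) >= n_steps)
    stop("duration shorter than the longest delay", call. = FALSE)
  if (is.null(stim)) {
    stim_nodes <- integer(0); amp <- 0; on <- 0L; off <- 0L
  } else {
    stim_nodes <- which(na == stim$target_area)
    if (!length(stim_nodes)) stop("empty stimulation target", call. = FALSE)
    amp <- stim$amplitude
    on <- as.integer(round(stim$onset / cfg$dt))
    off <- as.integer(round((stim$onset + stim$duration) / cfg$dt))
    if (off > n_steps) stop("duration must cover the stimulus", call. = FALSE)
  }
  out <- heun_network(hom$weights, het$weights, dsteps,
                      as.integer(na - 1L), as.integer(stim_nodes - 1L),
                      amp, on, off, cfg$alpha, params$eta, params$gamma,
                      params$epsilon, n_steps, cfg$dt, cfg$record_stride)
  dtr <- cfg$dt * cfg$record_stride
  structure(list(psi1 = out$psi1, psi2 = out$psi2,
                 times = seq(0, by = dtr, length.out = ncol(out$psi1)),
                 dt_recorded = dtr, stim = stim, params = params, cfg = cfg,
                 condition = list(site = if (is.null(stim)) NA_integer_
                                         else stim$target_area,
                                  alpha = cfg$alpha, sigma = hom$sigma)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "sim_result: %d nodes x %d samples (dt_rec = %g ms), site %s, alpha = %g, sigma = %g mm\n",
    nrow(x$psi1), ncol(x$psi1), 1000 * x$dt_recorded,
    as.character(x$condition$site), x$condition$alpha, x$condition$sigma))
  invisible(x)
}

#' Subtract the isolated-node stimulation response
#'
#' Removes the direct (network-independent) response from the nodes of the
#' stimulated area: the trajectory of an isolated node under the same
#' stimulus on the same time grid is subtracted from psi1 and psi2 of every
#' stimulated node.  What remains there is network-mediated re-entry only;
#' all other nodes are untouched.
#'
#' @param result a [sim_result()] from [simulate_network()].
#' @param parc the [parcellation()] used for the simulation.
#' @return a `sim_result` with the reference subtracted.
#' @export
subtract_isolated_response <- function(result, parc) {
  stim <- result$stim
  if (is.null(stim)) return(result)
  ref <- simulate_isolated_node(result$params, stim, dt = result$cfg$dt,
                                T = result$cfg$duration,
                                record_stride = result$cfg$record_stride)
  nt <- ncol(result$psi1)
  if (length(ref$psi1) < nt)
    stop("reference trajectory shorter than the simulation grid",
         call. = FALSE)
  nodes <- which(node_areas(parc) == stim$target_area)
  result$psi1[nodes, ] <- sweep(result$psi1[nodes, , drop = FALSE], 2,
                                ref$psi1[seq_len(nt)], "-")
  result$psi2[nodes, ] <- sweep(result$psi2[nodes, , drop = FALSE], 2,
                                ref$psi2[seq_len(nt)], "-")
  result
}

#' Area mean field of a simulation result
#'
#' Arithmetic mean of psi1 over the member nodes of each area at each
#' recorded time: the quantity transmitted by the heterogeneous SC.
#'
#' @param result a [sim_result()].
#' @param parc a [parcellation()].
#' @return numeric matrix (areas x recorded times).
#' @export
area_mean_field <- function(result, parc) {
  na <- node_areas(parc)
  A <- n_areas(parc)
  sizes <- tabulate(na, nbins = A)
  if (any(sizes[functional_areas(parc)] == 0))
    stop("empty functional area", call. = FALSE)
  M <- rowsum(result$psi1, group = na, reorder = TRUE)
  out <- matrix(0, A, ncol(result$psi1))
  out[sort(unique(na)), ] <- M / sizes[sort(unique(na))]
  rownames(out) <- NULL
  out
}
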