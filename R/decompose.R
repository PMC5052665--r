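#' Amplitude envelope of node time series
#'
#' Magnitude of the analytic signal (Hilbert-transform amplitude) of each
#' row, computed by zeroing the negative frequencies in the discrete Fourier
#' transform.
#'
#' @param timeseries numeric matrix (nodes x time), at least 8 samples.
#' @return matrix of the same shape with the instantaneous amplitude.
#' @export
envelope <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  n <- ncol(timeseries)
  if (n < 8) stop("time series too short for an envelope", call. = FALSE)
  F <- stats::mvfft(t(timeseries))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::mvfft(F * h, inverse = TRUE) / n
  t(Mod(analytic))
}

#' Principal spatial patterns of the evoked response
#'
#' PCA of the node-wise covariance of psi1 over an analysis window: the data
#' are mean-centered per node over time and decomposed by SVD (numerically
#' equivalent to the eigen-decomposition of the node covariance, stable when
#' nodes outnumber samples).  The smallest k <= 3 leading components whose
#' cumulative variance fraction first exceeds `threshold` are retained (all
#' 3 with a warning if the threshold is never reached).  Eigenvector signs
#' are canonicalized so the largest-magnitude element is positive.
#'
#' @param result a [sim_result()].
#' @param window numeric `c(start, length)` in s, within the recorded range.
#' @param threshold cumulative variance retention rule (default 0.99).
#' @param max_components maximum retained components (default 3).
#' @return An object of class `eigenspace`: `vectors` (node x k orthonormal),
#'   `fractions` (variance fractions of the retained components, descending),
#'   `all_fractions`, `condition`, `window`.
#' @export
decompose_response <- function(result, window, threshold = 0.99,
                               max_components = 3L) {
  start <- window[1]; len <- window[2]
  if (len <= 0) stop("empty analysis window", call. = FALSE)
  sel <- which(result$times >= start & result$times < start + len)
  if (length(sel) < 2)
    stop("analysis window outside the recorded range", call. = FALSE)
  X <- result$psi1[, sel, drop = FALSE]
  X <- X - rowMeans(X)
  sv <- svd(X, nu = max_components, nv = 0)
  ev <- sv$d^2
  total <- sum(ev)
  if (total <= 0) stop("window contains no variance", call. = FALSE)
  frac <- ev / total
  k_avail <- min(max_components, length(frac), ncol(sv$u))
  cum <- cumsum(frac[seq_len(k_avail)])
  k <- which(cum >= threshold)[1]
  if (is.na(k)) {
    k <- k_avail
    warning(sprintf("top %d components cover only %.2f%% of variance",
                    k_avail, 100 * cum[k_avail]))
  }
  V <- sv$u[, seq_len(k), drop = FALSE]
  V <- canonicalize_signs(V)
  structure(list(vectors = V,
                 fractions = frac[seq_len(k)],
                 all_fractions = frac,
                 condition = result$condition,
                 window = c(start = start, length = len)),
            class = "eigenspace")
}

# Flip each column so its largest-magnitude element is positive.
canonicalize_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.eigenspace <- function(x, ...) {
  cat(sprintf(
    "eigenspace: %d nodes x %d components, variance fractions %s (site %s, alpha %s, sigma %s)\n",
    nrow(x$vectors), ncol(x$vectors),
    paste(sprintf("%.3f", x$fractions), collapse = " "),
    as.character(x$condition$site), as.character(x$condition$alpha),
    as.character(x$condition$sigma)))
  invisible(x)
}
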