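#' Parameters of the two-variable node model
#'
#' Every network node carries a planar flow
#' \deqn{\dot\psi_1 = \eta(\psi_2 - \gamma\psi_1 - \psi_1^3) + drive, \quad
#'       \dot\psi_2 = -\eta\varepsilon\psi_1,}
#' a damped oscillator whose origin is a stable focus sitting below a
#' supercritical Andronov-Hopf bifurcation.  At the defaults (gamma = 1.21,
#' epsilon = 12.3083, eta = 76.74 1/s) the small-oscillation frequency is
#' about 42 Hz and the node operates near criticality: constant positive
#' self-input of weight gamma would put it exactly on the bifurcation.
#' Coupling and input act on the first variable only (coupling vectors
#' (eta, 0)).
#'
#' @param gamma dimensionless damping/bifurcation parameter (> 0 for a stable
#'   focus).
#' @param epsilon dimensionless stiffness; `epsilon > gamma^2/4` gives the
#'   oscillatory regime.
#' @param eta characteristic rate in 1/s (> 0).
#' @return An object of class `node_params`.
#' @export
node_params <- function(gamma = 1.21, epsilon = 12.3083, eta = 76.74) {
  if (eta <= 0) stop("eta must be positive", call. = FALSE)
  if (epsilon <= gamma^2 / 4)
    warning("epsilon <= gamma^2/4: node is not in the oscillatory regime")
  structure(list(gamma = gamma, epsilon = epsilon, eta = eta),
            class = "node_params")
}

#' Stimulus protocol for one brain area
#'
#' All nodes of the target area receive a constant signed drive of the given
#' amplitude for `duration` seconds (default: one characteristic time 1/eta),
#' which evokes a damped oscillation.  Use
#' [calibrate_stimulus_amplitude()] to pick the amplitude that gives an
#' isolated node a peak response of exactly one.
#'
#' @param target_area area id to stimulate.
#' @param amplitude drive magnitude (applied to psi1 scaled by eta).
#' @param onset stimulus onset in s.
#' @param duration stimulus duration in s; default 1/eta at the default rate.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(target_area, amplitude, onset = 0,
                          duration = 1 / 76.74) {
  if (!is.finite(amplitude)) stop("amplitude must be finite", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  structure(list(target_area = as.integer(target_area), amplitude = amplitude,
                 onset = onset, duration = duration),
            class = "stimulus_spec")
}

#' Evaluate the node flow
#'
#' @param state numeric length-2 vector `(psi1, psi2)`.
#' @param params a [node_params()].
#' @param drive already-signed scalar input added to the first component.
#' @return numeric length-2 vector of time derivatives.
#' @export
node_flow <- function(state, params, drive = 0) {
  c(params$eta * (state[2] - params$gamma * state[1] - state[1]^3) + drive,
    -params$eta * params$epsilon * state[1])
}

#' Eigenfrequency and decay rate of the linearized node
#'
#' The Jacobian at the origin has eigenvalues
#' `eta * (-gamma/2 +- sqrt(gamma^2/4 - epsilon))`: decay rate `eta*gamma/2`
#' and, in the oscillatory regime, frequency
#' `eta * sqrt(epsilon - gamma^2/4) / (2*pi)`.
#'
#' @param params a [node_params()].
#' @return list with `frequency` (Hz; 0 if overdamped) and `decay_rate` (1/s).
#' @export
node_eigenfrequency <- function(params) {
  disc <- params$epsilon - params$gamma^2 / 4
  freq <- if (disc > 0) params$eta * sqrt(disc) / (2 * pi) else 0
  list(frequency = freq, decay_rate = params$eta * params$gamma / 2)
}

#' Critical instantaneous self-coupling weight
#'
#' A constant instantaneous self-input of weight `w` on psi1 (scaled by eta,
#' like all coupling) shifts the effective damping to `gamma - w`; the
#' linearized real part crosses zero at `w = gamma`.  Because both
#' connectivities are normalized to unity maximum in-strength, the total
#' coupling weight into any node is at most 1 < gamma = 1.21, so every node
#' in the network stays strictly subcritical.
#'
#' @param params a [node_params()].
#' @return the critical weight (equal to gamma).
#' @export
critical_coupling <- function(params) params$gamma

#' Simulate an isolated node under the stimulation protocol
#'
#' Heun integration of the single-node flow with a constant drive of
#' amplitude `stim$amplitude` (times eta) over
#' `[stim$onset, stim$onset + stim$duration)`.
#'
#' @param params a [node_params()].
#' @param stim a [stimulus_spec()].
#' @param dt time step in s; must resolve the oscillation
#'   (`dt < 1/(10 * frequency)`).
#' @param T total simulated time in s.
#' @param self_weight optional instantaneous self-coupling weight (for
#'   probing the criticality threshold); default 0.
#' @param record_stride keep every `record_stride`-th sample.
#' @return list with `times`, `psi1`, `psi2` (recorded samples) and `peak`
#'   (max |psi1| over the full-resolution trajectory).
#' @export
simulate_isolated_node <- function(params, stim, dt = 4e-5, T = 0.5,
                                   self_weight = 0, record_stride = 1L) {
  f <- node_eigenfrequency(params)$frequency
  if (f > 0 && dt >= 1 / (10 * f))
    stop("dt too large to resolve the node oscillation", call. = FALSE)
  n_steps <- ceiling(T / dt)
  on <- round(stim$onset / dt)
  off <- round((stim$onset + stim$duration) / dt)
  out <- heun_isolated(params$eta, params$gamma, params$epsilon,
                       params$eta * stim$amplitude, as.integer(on),
                       as.integer(off), as.integer(n_steps), dt,
                       self_weight, as.integer(record_stride))
  if (!all(is.finite(out$psi1)))
    stop("integration diverged (unstable dt or supercritical coupling)",
         call. = FALSE)
  out$times <- seq(0, by = dt * record_stride, length.out = length(out$psi1))
  out
}

#' Calibrate the stimulus amplitude to a unit peak response
#'
#' Bisection on the amplitude of a constant drive of duration 1/eta so that
#' the isolated node's peak |psi1| equals 1 within `tol`.  The peak response
#' is monotone increasing in the amplitude, so the bracket is found by
#' doubling.
#'
#' @param params a [node_params()].
#' @param dt integration step in s.
#' @param tol tolerance on the peak (default 1e-3).
#' @return the calibrated amplitude (scalar).
#' @export
calibrate_stimulus_amplitude <- function(params, dt = 4e-5, tol = 1e-3) {
  T <- 0.15 + 1 / params$eta
  peak_of <- function(a) {
    stim <- stimulus_spec(1L, a, onset = 0, duration = 1 / params$eta)
    simulate_isolated_node(params, stim, dt = dt, T = T)$peak
  }
  lo <- 0; hi <- 1
  while (peak_of(hi) < 1) {
    lo <- hi; hi <- 2 * hi
    if (hi > 1e6) stop("calibration bracket not found", call. = FALSE)
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    p <- peak_of(mid)
    if (abs(p - 1) < tol) return(mid)
    if (p < 1) lo <- mid else hi <- mid
  }
  stop("calibration did not converge", call. = FALSE)
}
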