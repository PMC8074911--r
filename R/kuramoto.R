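#' Simulation configuration for the networked Kuramoto model
#'
#' @param omega Winding number (intrinsic rate of phase advance, radians per
#'   unit time); a scalar broadcast to all oscillators or a vector. The coffee
#'   study system uses identical `omega = 0.01`.
#' @param K Coupling coefficient on the per-neighbour scale: the phase
#'   velocity is `omega + K * sum_j gamma_ij sin(theta_j - theta_i)`.
#' @param sign Sign convention of the coupling term. `"attractive"` (default)
#'   uses `sin(theta_j - theta_i)`, under which in-phase synchrony is stable;
#'   `"literal"` flips the sign, which makes an in-phase pair repulsive and is
#'   kept only for reference.
#' @param t_end Simulation horizon (default 20, the harvest time used for all
#'   group classification).
#' @param dt Fixed integrator and output step (default 0.01).
#' @param seed Integer seed for random initial phases; `NULL` leaves the
#'   global RNG alone.
#' @param init Initial phase distribution: `"uniform"` on `[0, 2*pi)` or the
#'   degenerate `"zero"` (all phases 0; a testing hook).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(omega = 0.01, K = 1, sign = c("attractive", "literal"),
                       t_end = 20, dt = 0.01, seed = NULL,
                       init = c("uniform", "zero")) {
  sign <- match.arg(sign)
  init <- match.arg(init)
  stopifnot(K >= 0, t_end > 0, dt > 0, all(is.finite(omega)))
  structure(list(omega = omega, K = K, sign = sign, t_end = t_end, dt = dt,
                 seed = seed, init = init),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> K = ", x$K, ", omega = ",
      paste(utils::head(unique(x$omega), 3), collapse = ","),
      ", sign = ", x$sign, ", t_end = ", x$t_end, ", dt = ", x$dt,
      ", seed = ", x$seed %||% "NULL", "\n", sep = "")
  invisible(x)
}

#' Draw initial phases
#'
#' @param n Number of oscillators.
#' @param config A [sim_config]; its `seed` and `init` fields control the
#'   draw. Identical seeds give identical phases.
#' @return Numeric vector of `n` phases in `[0, 2*pi)`.
#' @export
init_phases <- function(n, config = sim_config()) {
  stopifnot(n >= 1)
  if (config$init == "zero") return(rep(0, n))
  draw <- function() stats::runif(n, 0, 2 * pi)
  if (is.null(config$seed)) draw() else withr::with_seed(config$seed, draw())
}

#' Instantaneous phase velocities
#'
#' Evaluates the right-hand side of the adjacency-disaggregated Kuramoto
#' model, `dtheta_i/dt = omega_i + K * sum_j gamma_ij sin(theta_j - theta_i)`
#' (attractive convention; `sign = "literal"` flips the sine's argument).
#'
#' @param theta Numeric vector of phases (radians), one per oscillator.
#' @param net An [oscillator_network].
#' @param config A [sim_config].
#' @return Numeric vector of phase velocities.
#' @export
phase_velocity <- function(theta, net, config = sim_config()) {
  stopifnot(inherits(net, "oscillator_network"))
  if (length(theta) != net$n) {
    stop("phase vector length (", length(theta),
         ") does not match network size (", net$n, ")", call. = FALSE)
  }
  omega <- rep_len(config$omega, net$n)
  s <- sin(theta); cth <- cos(theta)
  # sum_j g_ij sin(theta_j - theta_i) = cos(theta_i) (G s)_i - sin(theta_i) (G c)_i
  coupling <- cth * as.vector(net$gamma %*% s) - s * as.vector(net$gamma %*% cth)
  if (config$sign == "literal") coupling <- -coupling
  omega + config$K * coupling
}

#' Integrate the networked Kuramoto model
#'
#' Fixed-step 4th-order Runge-Kutta from `t = 0` to `t_end`, sampled on the
#' `dt` grid. Integration runs on unwrapped phases; the stored trajectory is
#' reduced modulo `2*pi` into `[0, 2*pi)`. Deterministic given the network,
#' configuration and initial state.
#'
#' @param net An [oscillator_network].
#' @param config A [sim_config].
#' @param initial Optional numeric vector of initial phases; when omitted,
#'   [init_phases()] is used.
#' @return An object of class `kuramoto_trajectory`: a list with `times`,
#'   `phases` (time-by-oscillator matrix, columns named by oscillator id),
#'   `config` and `network`.
#' @examples
#' fx <- coffee_fixture()
#' traj <- integrate_kuramoto(fx$network, sim_config(K = 0.8, seed = 1))
#' order_parameter(final_phases(traj))
#' @export
integrate_kuramoto <- function(net, config = sim_config(), initial = NULL) {
  stopifnot(inherits(net, "oscillator_network"))
  if (is.null(initial)) initial <- init_phases(net$n, config)
  if (length(initial) != net$n) {
    stop("initial state length does not match network size", call. = FALSE)
  }
  n_steps <- round(config$t_end / config$dt)
  if (abs(n_steps * config$dt - config$t_end) > 1e-9) {
    n_steps <- ceiling(config$t_end / config$dt)
  }
  phases <- kuramoto_rk4_cpp(net$gamma, rep_len(config$omega, net$n),
                             as.numeric(initial), config$K, config$dt,
                             as.integer(n_steps),
                             config$sign == "literal", 1L)
  if (any(!is.finite(phases))) {
    bad <- which(!apply(is.finite(phases), 1, all))[1]
    stop("non-finite phase during integration at t = ",
         (bad - 1) * config$dt, call. = FALSE)
  }
  phases <- phases %% (2 * pi)
  colnames(phases) <- net$labels
  structure(list(times = seq(0, by = config$dt, length.out = n_steps + 1),
                 phases = phases, config = config, network = net),
            class = "kuramoto_trajectory")
}

#' @export
print.kuramoto_trajectory <- function(x, ...) {
  cat("<kuramoto_trajectory> ", ncol(x$phases), " oscillators, t in [0, ",
      max(x$times), "], K = ", x$config$K, "\n", sep = "")
  invisible(x)
}

# Final phases only, without storing the trajectory: the workhorse for
# replicate persistence analysis.
simulate_final_phases <- function(net, config, initial = NULL) {
  if (is.null(initial)) initial <- init_phases(net$n, config)
  n_steps <- round(config$t_end / config$dt)
  phases <- kuramoto_rk4_cpp(net$gamma, rep_len(config$omega, net$n),
                             as.numeric(initial), config$K, config$dt,
                             as.integer(n_steps),
                             config$sign == "literal", as.integer(n_steps))
  out <- phases[nrow(phases), ] %% (2 * pi)
  names(out) <- net$labels
  out
}

#' Final phases of a trajectory
#'
#' @param traj A `kuramoto_trajectory`.
#' @return Named numeric vector of phases at `t_end`.
#' @export
final_phases <- function(traj) {
  stopifnot(inherits(traj, "kuramoto_trajectory"))
  traj$phases[nrow(traj$phases), ]
}

#' Phases at a given trajectory time
#'
#' @param traj A `kuramoto_trajectory`.
#' @param time A time on the output grid (matched to the nearest sample
#'   within half a step).
#' @return Named numeric vector of phases.
#' @export
phases_at <- function(traj, time) {
  stopifnot(inherits(traj, "kuramoto_trajectory"))
  i <- which.min(abs(traj$times - time))
  if (abs(traj$times[i] - time) > traj$config$dt / 2 + 1e-12) {
    stop("time ", time, " outside the sampled trajectory grid", call. = FALSE)
  }
  traj$phases[i, ]
}

#' Kuramoto order parameter
#'
#' The magnitude of the mean unit vector, `|z| = |mean(exp(1i * theta))|`:
#' 1 for full coherence, near 0 for incoherent phases.
#'
#' @param theta Numeric vector of phases (radians).
#' @return A number in `[0, 1]`.
#' @examples
#' order_parameter(rep(1.3, 10))              # 1
#' order_parameter(2 * pi * (0:9) / 10)       # 0 (roots of unity)
#' @export
order_parameter <- function(theta) {
  if (length(theta) == 0) stop("order parameter of an empty state", call. = FALSE)
  Mod(mean(exp(1i * theta)))
}

#' Order parameter over a whole trajectory
#'
#' @param traj A `kuramoto_trajectory`.
#' @return A tibble with columns `time` and `r`.
#' @export
order_parameter_ts <- function(traj) {
  stopifnot(inherits(traj, "kuramoto_trajectory"))
  tibble::tibble(time = traj$times,
                 r = apply(traj$phases, 1, order_parameter))
}

# Deterministic replicate seed derivation. Keeps every derived seed inside
# 32-bit integer range so set.seed() accepts it, and pairs replicates across
# networks (same master seed, sweep index and replicate -> same initial
# phases).
derive_seed <- function(master, k_index, r) {
  m <- 2147483629
  as.integer((as.numeric(master) %% m * 48271 +
                as.numeric(k_index) * 1299709 +
                as.numeric(r) * 104729) %% m)
}
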