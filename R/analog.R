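# Behavioral simulation of the op-amp Hopfield neuron circuit.
#
# Each neuron is a summing amplifier: resistive connections from the other
# neurons' outputs inject current at its input node (KCL balance), a bias
# source adds a constant term, and the amplifier applies a saturating
# transfer function between input node voltage and output. The textbook
# dynamical model of that circuit is the continuous-Hopfield RC relaxation
#   tau * du_i/dt = -u_i + sum_j G_ij v_j + bias_i + noise(t)
#   v_i = rails * tanh(gain * u_i)
# with G the signed, normalized conductance matrix realizing the Hebbian
# weights (negative weights route through the inverting input). At high
# amplifier gain the stable states of this system coincide with the fixed
# points of the ideal digital network.

#' Configuration of the analog neuron circuit
#'
#' @param gain amplifier gain (slope of the tanh transfer function,
#'   dimensionless). High gain (>= 10) approximates the digital threshold.
#' @param tau RC relaxation time constant of the summing node, seconds.
#' @param dt explicit-Euler integration step, seconds; default `tau/100`.
#' @param duration simulated time, seconds; default `8 * tau` (long enough
#'   for the node voltages to settle at high gain).
#' @param noise_sd standard deviation of white Gaussian voltage noise added
#'   at the summing node, in units of the output rails.
#' @param rails output saturation level (supply rails), volts; outputs live
#'   in (-rails, rails).
#' @param bias per-neuron constant bias source voltage (recycled scalar ok).
#' @return an object of class `circuit_config`.
#' @export
circuit_config <- function(gain = 10, tau = 1, dt = tau / 100,
                           duration = 8 * tau, noise_sd = 0, rails = 1,
                           bias = 0) {
  stopifnot(gain > 0, tau > 0, dt > 0, duration >= dt, noise_sd >= 0,
            rails > 0)
  structure(list(gain = gain, tau = tau, dt = dt, duration = duration,
                 noise_sd = noise_sd, rails = rails, bias = bias),
            class = "circuit_config")
}

#' Map Hebbian weights to normalized circuit conductances
#'
#' Conductance magnitudes are proportional to |W| and normalized so the
#' largest is 1 (the paper's circuit fixes no absolute resistor scale); the
#' sign of each connection selects the inverting or non-inverting path, so
#' `sign(G) == sign(W)` entrywise. Zero weights are open circuits.
#'
#' @param W a `hopfield` fit or symmetric zero-diagonal weight matrix.
#' @param config a [circuit_config()] (carried along for the simulator).
#' @return a `circuit_params`: list with `G` (normalized signed conductance
#'   matrix), `scale` (the magnitude divided out), `config`.
#' @export
map_weights_to_circuit <- function(W, config = circuit_config()) {
  W <- as_weights(W)
  scale <- max(abs(W))
  G <- if (scale > 0) W / scale else W
  structure(list(G = G, scale = scale, config = config),
            class = "circuit_params")
}

#' Threshold an analog output vector to a bipolar readout
#'
#' High voltage reads as +1, low as -1; an exactly-zero node keeps the
#' corresponding entry of the initial state (the same tie rule as the
#' digital dynamics).
#'
#' @param v real-valued output voltages.
#' @param init bipolar state supplying the value at exact zeros.
#' @return bipolar vector.
#' @export
threshold_readout <- function(v, init) {
  assert_bipolar(init, "init")
  stopifnot(length(v) == length(init))
  sign_threshold(v, init)
}

#' Integrate the analog neuron circuit
#'
#' Fixed-step explicit Euler integration of the RC relaxation from a bipolar
#' initial state scaled to the rails. Divergence (any node exceeding 1e6
#' times the rails) is reported, never silent.
#'
#' @param params a `circuit_params` from [map_weights_to_circuit()] (or a
#'   `hopfield` fit / weight matrix, mapped automatically).
#' @param config a [circuit_config()]; defaults to the one stored in
#'   `params`.
#' @param init bipolar initial state.
#' @param seed seed for the noise process.
#' @param keep_trajectory if `TRUE`, return the full output-voltage
#'   trajectory (time x neurons).
#' @return an `analog_recall`: list with `state` (bipolar readout of the
#'   final outputs), `v` (final continuous outputs), `u` (final node
#'   voltages), `diverged`, `steps`, `config`, and optionally `trajectory`.
#' @export
simulate_circuit <- function(params, config = NULL, init, seed = NULL,
                             keep_trajectory = FALSE) {
  if (!inherits(params, "circuit_params")) {
    params <- map_weights_to_circuit(params,
                                     if (is.null(config)) circuit_config() else config)
  }
  if (is.null(config)) config <- params$config
  assert_bipolar(init, "init")
  G <- params$G
  n <- nrow(G)
  stopifnot(length(init) == n)
  bias <- rep_len(config$bias, n)
  nsteps <- floor(config$duration / config$dt)
  limit <- 1e6 * config$rails
  ## start on the rails: u chosen so v = rails*tanh(gain*u) is essentially init
  u <- init
  v <- config$rails * tanh(config$gain * u)
  traj <- if (keep_trajectory) matrix(NA_real_, nrow = nsteps + 1L, ncol = n)
  if (keep_trajectory) traj[1L, ] <- v
  diverged <- FALSE
  with_seed(seed, {
    for (s in seq_len(nsteps)) {
      drive <- as.vector(G %*% v) + bias
      if (config$noise_sd > 0) {
        drive <- drive + stats::rnorm(n, sd = config$noise_sd)
      }
      u <- u + (config$dt / config$tau) * (-u + drive)
      if (any(abs(u) > limit)) { diverged <- TRUE; break }
      v <- config$rails * tanh(config$gain * u)
      if (keep_trajectory) traj[s + 1L, ] <- v
    }
  })
  if (diverged) warning("analog simulation diverged: node voltage exceeded 1e6 x rails")
  structure(list(state = threshold_readout(v, init), v = v, u = u,
                 diverged = diverged, steps = nsteps, config = config,
                 trajectory = if (keep_trajectory) traj),
            class = "analog_recall")
}

#' @export
print.analog_recall <- function(x, ...) {
  cat(sprintf("<analog_recall> %d steps of dt=%g (gain %g, noise sd %g)%s\n",
              x$steps, x$config$dt, x$config$gain, x$config$noise_sd,
              if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Lyapunov energy of the continuous circuit
#'
#' The continuous-Hopfield energy
#' `E = -1/2 v'Gv - bias'v + (1/gain) * sum_i rails * int_0^{v_i/rails} atanh(s) ds`,
#' non-increasing along zero-noise trajectories of the relaxation.
#'
#' @param G signed conductance matrix.
#' @param v continuous output vector (|v| < rails).
#' @param config a [circuit_config()].
#' @return scalar energy.
#' @export
circuit_energy <- function(G, v, config = circuit_config()) {
  x <- v / config$rails
  stopifnot(all(abs(x) <= 1))
  ## int_0^x atanh(s) ds = [(1+x)log(1+x) + (1-x)log(1-x)] / 2,
  ## written in the form that stays finite as |x| -> 1 (limit log 2)
  xlx <- function(z) ifelse(z <= 0, 0, z * log(z))
  leak <- (config$rails^2 / config$gain) *
    sum((xlx(1 + x) + xlx(1 - x)) / 2)
  bias <- rep_len(config$bias, length(v))
  -0.5 * sum(v * (G %*% v)) - sum(bias * v) + leak
}

#' Simulate recall through the analog circuit backend
#'
#' The `simulate` method for a `hopfield` fit runs the behavioral circuit
#' model from `nsim` seeded random bipolar initial states (or from a given
#' probe) and returns the thresholded readouts.
#'
#' @param object a `hopfield` fit.
#' @param nsim number of random initial states (ignored when `init` given).
#' @param seed master seed; per-run seeds are derived from it.
#' @param init optional probe (bipolar vector or [template()]).
#' @param config a [circuit_config()].
#' @param ... unused.
#' @return matrix of bipolar readouts, one run per row, with attribute
#'   `diverged` (logical per run).
#' @export
simulate.hopfield <- function(object, nsim = 1, seed = NULL, init = NULL,
                              config = circuit_config(), ...) {
  params <- map_weights_to_circuit(object, config)
  inits <- if (!is.null(init)) {
    as_pattern_matrix(init)
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), nsim * object$n, replace = TRUE),
                           nrow = nsim))
  }
  base_seed <- if (is.null(seed)) 0L else as.integer(seed)
  runs <- lapply(seq_len(nrow(inits)), function(k) {
    simulate_circuit(params, config, inits[k, ], seed = base_seed + k)
  })
  out <- do.call(rbind, lapply(runs, `[[`, "state"))
  attr(out, "diverged") <- vapply(runs, `[[`, logical(1), "diverged")
  out
}
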