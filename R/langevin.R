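#' Langevin dynamics parameters
#'
#' @param temperature Target temperature in K.
#' @param friction Langevin damping coefficient in ps^-1 (0 gives NVE
#'   velocity-Verlet dynamics).
#' @param timestep Integration time step in ps.
#' @param seed Integer seed; fixed seed gives bit-reproducible trajectories.
#' @return A list of class `"langevin_params"`.
#' @export
langevin_params <- function(temperature = 300, friction = 5,
                            timestep = 0.002, seed = 1) {
  if (timestep <= 0) stop("timestep must be positive")
  if (friction < 0) stop("friction must be non-negative")
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, seed = as.integer(seed)),
            class = "langevin_params")
}

#' Run (optionally biased) Langevin dynamics
#'
#' BAOAB-discretized Langevin integrator. Initial velocities are drawn from
#' the Maxwell-Boltzmann distribution at `params$temperature` (using
#' `params$seed`) unless `v0` is supplied. A `bias` callback
#' `function(t, coords)` returning an N x 3 force matrix (kcal/mol/A) is
#' added to the potential forces each step; the steering and metadynamics
#' front-ends use dedicated compiled bias paths instead.
#'
#' @param potential A potential object (see [potentials] or
#'   [build_toy_pocket()]).
#' @param start Initial [configuration()].
#' @param params [langevin_params()].
#' @param n_steps Number of integration steps (>= 1).
#' @param bias Optional R bias-force callback.
#' @param record_stride Store every `record_stride`-th frame.
#' @param v0 Optional N x 3 initial velocity matrix (A/ps).
#' @return A [trajectory()] with per-frame `potential_energy` and
#'   `kinetic_energy` (kcal/mol) attached as fields.
#' @export
run_langevin <- function(potential, start, params, n_steps, bias = NULL,
                         record_stride = 1, v0 = NULL) {
  stopifnot(inherits(params, "langevin_params"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  res <- .langevin_run_cpp(potential$spec, start$coords, start$masses,
                           params$temperature, params$friction,
                           params$timestep, as.integer(n_steps),
                           params$seed, as.integer(record_stride), bias, v0)
  traj <- traj_from_flat(res$coords, start, res$times)
  traj$potential_energy <- res$potential_energy
  traj$kinetic_energy <- res$kinetic_energy
  traj
}
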