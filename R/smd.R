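#' Steered dynamics configuration
#'
#' Constant-velocity steering along the distance between the centres of
#' mass of two disjoint atom selections: a harmonic guide
#' `U(t) = k/2 (xi - xi0 - v t)^2` drags the reaction coordinate `xi` from
#' its initial value over `target_extension` Angstrom.
#'
#' @param group_a Pulled selection (indices or group name).
#' @param group_b Anchor selection.
#' @param force_constant Guide spring k in kcal mol^-1 A^-2 (default 20).
#' @param speed Pulling speed in A/ps (default 0.005).
#' @param target_extension Total extension in Angstrom.
#' @return A list of class `"smd_config"`.
#' @export
smd_config <- function(group_a, group_b, force_constant = 20, speed = 0.005,
                       target_extension = 7.5) {
  if (force_constant <= 0) stop("force_constant must be positive")
  if (speed <= 0) stop("speed must be positive")
  structure(list(group_a = group_a, group_b = group_b,
                 force_constant = force_constant, speed = speed,
                 target_extension = target_extension),
            class = "smd_config")
}

#' Duration of a constant-velocity pulling schedule
#'
#' @param config An [smd_config()].
#' @return `target_extension / speed` in ps.
#' @export
#' @examples
#' schedule_duration(smd_config(1, 2, speed = 0.005, target_extension = 7.5))
schedule_duration <- function(config) {
  stopifnot(inherits(config, "smd_config"))
  if (config$speed == 0) stop("speed must be non-zero")
  config$target_extension / config$speed
}

#' Run one steered (constant-velocity) realisation
#'
#' The applied force `F(t) = k (xi0 + v t - xi)` and accumulated work
#' `W(t) = int F v dt` (trapezoid rule on the integration grid) are recorded
#' along the pull. Initial velocities are a fresh Maxwell-Boltzmann draw per
#' run seed, so independent realisations differ only by their seed.
#'
#' @param potential,start,params As for [run_langevin()].
#' @param config An [smd_config()]; selections are resolved on `start`.
#' @param run_id Identifier stored on the record.
#' @param record_stride Stride (in steps) for the recorded series.
#' @param traj_stride If > 0, also keep every `traj_stride`-th frame.
#' @param equilibrate Time (ps) spent equilibrating under the static
#'   restraint before the centre starts moving. The work bound holds
#'   against equilibrium initial conditions, so production protocols
#'   should equilibrate; 0 starts pulling immediately.
#' @return A `pull_record`: data frame with columns `time`, `xi`,
#'   `restraint_center`, `force`, `work`, plus attributes `run_id` and (if
#'   requested) `trajectory`.
#' @export
run_smd <- function(potential, start, params, config, run_id = 1L,
                    record_stride = 10, traj_stride = 0, equilibrate = 5) {
  stopifnot(inherits(config, "smd_config"))
  ga <- resolve_selection(start, config$group_a)
  gb <- resolve_selection(start, config$group_b)
  if (!length(ga) || !length(gb)) stop("SMD groups must be non-empty")
  if (length(intersect(ga, gb))) stop("SMD groups must be disjoint")
  n_steps <- max(1L, as.integer(round(
    schedule_duration(config) / params$timestep)))
  equil_steps <- max(0L, as.integer(round(equilibrate / params$timestep)))
  res <- .smd_run_cpp(potential$spec, start$coords, start$masses,
                      params$temperature, params$friction, params$timestep,
                      n_steps, params$seed, as.integer(record_stride),
                      as.integer(traj_stride), ga, gb,
                      config$force_constant, config$speed, equil_steps)
  rec <- data.frame(time = res$times, xi = res$xi,
                    restraint_center = res$restraint_center,
                    force = res$force, work = res$work)
  class(rec) <- c("pull_record", class(rec))
  attr(rec, "run_id") <- run_id
  attr(rec, "xi0") <- res$xi0
  if (traj_stride > 0)
    attr(rec, "trajectory") <- traj_from_flat(res$coords, start, res$t_traj)
  rec
}

#' Final nonequilibrium work of a pull
#' @param record A `pull_record`.
#' @return Work in kcal/mol.
#' @export
final_work <- function(record) tail(record$work, 1)

#' Select the best steering run
#'
#' Returns the record with the lowest final work; ties are broken by the
#' lower total variation of the force profile, then by run id.
#'
#' @param records List of `pull_record`s sharing one schedule.
#' @return The selected `pull_record`.
#' @export
select_lowest_work <- function(records) {
  if (!length(records)) stop("no pull records supplied")
  works <- vapply(records, final_work, numeric(1))
  tv <- vapply(records, function(r) sum(abs(diff(r$force))), numeric(1))
  ids <- vapply(records, function(r) as.numeric(attr(r, "run_id")), numeric(1))
  ord <- order(works, tv, ids)
  records[[ord[1]]]
}

#' Write / read a pull record as tab-separated text
#' @param record A `pull_record`.
#' @param path File path.
#' @return `path` (write) or a `pull_record` (read).
#' @export
write_pull_record <- function(record, path) {
  write.table(as.data.frame(record), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pull_record
#' @export
read_pull_record <- function(path) {
  rec <- read.table(path, header = TRUE, sep = "\t")
  class(rec) <- c("pull_record", class(rec))
  rec
}
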