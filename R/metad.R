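#' Run metadynamics on the path collective variables (S, Z)
#'
#' Langevin dynamics with a history-dependent bias: every `config$stride`
#' ps a Gaussian hill is deposited at the current (S, Z) and its force
#' (chain rule through the analytic S/Z gradients, acting on the displace
#' selection) is added to the dynamics. For efficiency the engine
#' accumulates hill gradients on a fine (S, Z) grid (spacing sigma/10,
#' bilinear lookup); the exact bias and its analytic gradient are always
#' available from the returned hill log via [bias_value()] and
#' [bias_gradient()].
#'
#' The default stopping rule is the recrossing event: the run ends when S,
#' having reached `end_region`, returns to `start_region` (with
#' `max_steps` as a safety cap). With `deposition_rate = 0` no hills are
#' deposited and the run reduces to plain Langevin dynamics recording
#' (S, Z) — useful for brute-force reference sampling.
#'
#' @param potential,start,params As for [run_langevin()].
#' @param fs A [frameset()] defining S and Z.
#' @param config A [metad_config()].
#' @param max_steps Safety cap on integration steps.
#' @param stop_on_recross Stop at the first recrossing?
#' @param start_region,end_region S-intervals `c(lo, hi)` for the stopping
#'   rule; defaults to the first/last fifth of `[1, P]`.
#' @param grid_z_max Upper Z bound of the internal bias grid.
#' @param record_stride Stride (steps) for the recorded (S, Z) series.
#' @param traj_stride If > 0, keep every so-many-th frame.
#' @return List of class `"metad_run"`: `hills` ([hill_log()]), `series`
#'   (data frame time/s/z), `trajectory` (or NULL), `recross_time` (ps or
#'   NA), `steps_done`.
#' @export
run_metadynamics <- function(potential, start, params, fs, config,
                             max_steps = 5e6, stop_on_recross = TRUE,
                             start_region = NULL, end_region = NULL,
                             grid_z_max = NULL, record_stride = 100,
                             traj_stride = 0) {
  stopifnot(inherits(config, "metad_config"), inherits(fs, "frameset"))
  P <- length(fs$frames)
  if (is.null(start_region)) start_region <- c(1 - 1, 1 + (P - 1) / 5)
  if (is.null(end_region)) end_region <- c(P - (P - 1) / 5, P + 1)
  if (stop_on_recross && start_region[2] >= end_region[1])
    stop("start and end regions must be disjoint")
  if (is.null(grid_z_max))
    grid_z_max <- max(20 * config$sigma_z, 4 * mean(fs$adjacent_msd)) + 10
  hill_stride <- max(1L, as.integer(round(config$stride / params$timestep)))

  res <- .metad_run_cpp(potential$spec, start$coords, start$masses,
                        params$temperature, params$friction, params$timestep,
                        params$seed, fs_cpp(fs), config$height, hill_stride,
                        config$sigma_s, config$sigma_z,
                        0, P + 1.5, -1, grid_z_max,
                        as.integer(max_steps), as.integer(record_stride),
                        as.integer(traj_stride), isTRUE(stop_on_recross),
                        start_region[1], start_region[2],
                        end_region[1], end_region[2])
  hills <- if (length(res$hill_time))
    hill_log(res$hill_time, res$hill_s, res$hill_z, config$height,
             config$sigma_s, config$sigma_z)
  else
    hill_log(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0),
             numeric(0))
  out <- list(hills = hills,
              series = data.frame(time = res$times, s = res$s, z = res$z),
              trajectory = if (traj_stride > 0)
                traj_from_flat(res$coords, start, res$t_traj) else NULL,
              recross_time = if (res$recross_time < 0) NA_real_
                             else res$recross_time,
              steps_done = res$steps_done, config = config)
  class(out) <- "metad_run"
  out
}

#' @export
print.metad_run <- function(x, ...) {
  cat(sprintf("<metad_run> %d hills, %d steps, recrossing at %s ps\n",
              nrow(x$hills), x$steps_done,
              if (is.na(x$recross_time)) "-" else format(x$recross_time)))
  invisible(x)
}

#' Detect the first recrossing event in an S time series
#'
#' Returns the first time at which the series, having first reached
#' `end_region` after leaving `start_region`, returns to `start_region`;
#' `NA` if that never happens.
#'
#' @param s_series Numeric S values.
#' @param times Times (ps) aligned with `s_series`; defaults to indices.
#' @param start_region,end_region Disjoint S-intervals `c(lo, hi)`.
#' @return Event time (ps) or `NA`.
#' @export
detect_recrossing <- function(s_series, start_region, end_region,
                              times = seq_along(s_series) - 1) {
  if (max(start_region[1], end_region[1]) <=
      min(start_region[2], end_region[2]))
    stop("start and end regions must be disjoint")
  in_start <- s_series >= start_region[1] & s_series <= start_region[2]
  in_end <- s_series >= end_region[1] & s_series <= end_region[2]
  first_end <- which(in_end)[1]
  if (is.na(first_end)) return(NA_real_)
  back <- which(in_start & seq_along(s_series) > first_end)[1]
  if (is.na(back)) return(NA_real_)
  times[back]
}
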