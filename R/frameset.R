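#' Construct a frameset (ordered reference configurations defining a path)
#'
#' @param frames List of P >= 2 [configuration()]s sharing one topology.
#' @param align_selection Atom indices (or group name, resolved on the first
#'   frame) for the least-squares fit; `NULL` for no alignment.
#' @param displace_selection Atoms over which the MSD metric is measured.
#' @param lambda Smoothness parameter in A^-2; if `NULL`, calibrated with
#'   [calibrate_lambda()].
#' @return An object of class `"frameset"` with fields `frames`, `align`,
#'   `displace`, `lambda` and `adjacent_msd` (P-1 values, A^2).
#' @export
frameset <- function(frames, align_selection, displace_selection,
                     lambda = NULL) {
  if (length(frames) < 2) stop("a frameset needs at least 2 frames")
  f1 <- frames[[1]]
  al <- if (is.null(align_selection)) integer(0)
        else resolve_selection(f1, align_selection)
  di <- resolve_selection(f1, displace_selection)
  if (!length(di)) stop("displace_selection must be non-empty")
  adj <- vapply(seq_len(length(frames) - 1), function(i)
    .msd_cpp(frames[[i]]$coords, frames[[i + 1]]$coords,
             as.integer(al), as.integer(di)), numeric(1))
  if (any(adj <= 0))
    stop("adjacent frames must be distinct (zero MSD found)")
  fs <- structure(list(frames = frames, align = as.integer(al),
                       displace = as.integer(di), lambda = lambda,
                       adjacent_msd = adj),
                  class = "frameset")
  if (is.null(lambda)) fs$lambda <- calibrate_lambda(fs)
  if (fs$lambda <= 0) stop("lambda must be positive")
  fs
}

#' @export
print.frameset <- function(x, ...) {
  cat(sprintf(
    "<frameset> P = %d frames, lambda = %.4g 1/A^2, mean adjacent MSD = %.4g A^2\n",
    length(x$frames), x$lambda, mean(x$adjacent_msd)))
  invisible(x)
}

# compiled-side representation
fs_cpp <- function(fs) {
  list(frames_flat = unlist(lapply(fs$frames, function(f) as.vector(t(f$coords))),
                            use.names = FALSE),
       n_atoms = n_atoms(fs$frames[[1]]), P = length(fs$frames),
       align = fs$align, displace = fs$displace, lambda = fs$lambda)
}

#' Calibrate the path smoothness parameter lambda
#'
#' Uses the rule `lambda = ln(10) / mean(adjacent MSD)`, so a configuration
#' one inter-frame spacing away from a frame contributes weight 0.1 to the
#' path sums. For the spacing reported for a typical protein-ligand
#' frameset (1.1 A RMSD, i.e. 1.21 A^2 MSD) this gives lambda = 1.90 A^-2.
#'
#' @param fs A [frameset()] with `adjacent_msd` populated.
#' @return lambda in A^-2.
#' @export
calibrate_lambda <- function(fs) {
  m <- mean(fs$adjacent_msd)
  if (!is.finite(m) || m <= 0) stop("zero mean inter-frame spacing")
  log(10) / m
}

#' Extract an evenly spaced frameset from a trajectory
#'
#' Selects `P` frames (the first and last always included) whose adjacent
#' MSD spacings are as even as possible: a dynamic programme over a
#' candidate frame grid (at most `max_candidates`) minimizes
#' `sum (msd_adjacent - target)^2`, with the target spacing taken from the
#' cumulative RMSD arc length divided by P-1.
#'
#' @param traj A [trajectory()].
#' @param P Number of frames to extract (2..n_frames).
#' @param align_selection,displace_selection As in [frameset()], resolved on
#'   the first frame.
#' @param lambda Optional; default calibrated from the result.
#' @param max_candidates Cap on the candidate grid size.
#' @return A [frameset()].
#' @export
extract_frameset <- function(traj, P, align_selection, displace_selection,
                             lambda = NULL, max_candidates = 500) {
  nf <- n_frames(traj)
  if (P < 2 || P > nf) stop("P must be between 2 and the trajectory length")
  f1 <- traj$frames[[1]]
  al <- if (is.null(align_selection)) integer(0)
        else resolve_selection(f1, align_selection)
  di <- resolve_selection(f1, displace_selection)

  cand <- unique(round(seq(1, nf, length.out = min(nf, max_candidates))))
  flat <- traj_flat(traj)
  D <- .msd_matrix_cpp(flat, n_atoms(traj), as.integer(cand),
                       as.integer(al), as.integer(di))
  if (max(D[1, ]) < 1e-12)
    stop("trajectory has no net displacement: cannot define a path")
  # Even spacing via DP with an iteratively refined target: anchor on the
  # net end-to-end spacing (noise-free lower bound), then refine the target
  # to the achieved mean adjacent spacing until it is self-consistent.
  target <- D[1, ncol(D)] / (P - 1)^2
  sel <- .frameset_dp_cpp(D, as.integer(P), target)
  for (it in 1:4) {
    adj <- D[cbind(sel[-P], sel[-1])]
    new_target <- mean(adj)
    if (abs(new_target - target) < 1e-3 * target) break
    target <- new_target
    sel <- .frameset_dp_cpp(D, as.integer(P), target)
  }
  idx <- cand[sel]
  frameset(traj$frames[idx],
           if (length(al)) al else NULL, di, lambda = lambda)
}

#' Write / read a frameset as multi-frame XYZ plus a YAML sidecar
#'
#' The frames go to `<prefix>.xyz`; selections, lambda and the adjacent MSD
#' spacings go to `<prefix>.yaml`.
#'
#' @param fs A [frameset()].
#' @param prefix Output path prefix.
#' @return `prefix` (write); a [frameset()] (read).
#' @export
write_frameset <- function(fs, prefix) {
  write_xyz(trajectory(fs$frames, seq_along(fs$frames) - 1),
            paste0(prefix, ".xyz"))
  yaml::write_yaml(list(align = fs$align, displace = fs$displace,
                        lambda = fs$lambda, adjacent_msd = fs$adjacent_msd),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_frameset
#' @export
read_frameset <- function(prefix) {
  traj <- read_xyz(paste0(prefix, ".xyz"))
  side <- yaml::read_yaml(paste0(prefix, ".yaml"))
  if (is.null(side$lambda) || is.null(side$displace))
    stop(sprintf("corrupt frameset sidecar '%s.yaml': missing lambda/displace",
                 prefix))
  frameset(traj$frames,
           if (length(side$align)) as.integer(side$align) else NULL,
           as.integer(side$displace), lambda = side$lambda)
}
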