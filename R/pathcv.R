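#' Evaluate the path collective variables S and Z
#'
#' With `D_i` the MSD between `config` and frame `i` of the frameset
#' (i = 1..P, after superposition over the alignment selection),
#' \deqn{S = \frac{\sum_i i\, e^{-\lambda D_i}}{\sum_i e^{-\lambda D_i}},
#'   \qquad Z = -\frac{1}{\lambda} \ln \sum_i e^{-\lambda D_i}.}
#' S measures progression along the path (1..P), Z the distance from it
#' (A^2). Sums are evaluated in log-sum-exp form so extreme `lambda * D`
#' never underflows. Gradients with respect to the displace-selection
#' coordinates are analytic; the optimal rotation/translation is held fixed
#' per evaluation, which is exact as long as the align and displace
#' selections are disjoint (the supported layout).
#'
#' @param config A [configuration()] matching the frameset topology.
#' @param fs A [frameset()].
#' @param gradients Compute `ds_dx`/`dz_dx`?
#' @return A list of class `"pathcv_value"`: `s`, `z`, and (optionally)
#'   `ds_dx`, `dz_dx` as N x 3 matrices that are zero outside the displace
#'   selection.
#' @export
#' @examples
#' # a 2-frame path for a single atom moving along x
#' mk <- function(x) configuration(matrix(c(x, 0, 0), 1, 3))
#' fs <- frameset(list(mk(0), mk(1)), NULL, 1, lambda = 2)
#' evaluate_path_cv(mk(0.5), fs)$s # 1.5 by symmetry
evaluate_path_cv <- function(config, fs, gradients = TRUE) {
  stopifnot(inherits(fs, "frameset"))
  if (n_atoms(config) != n_atoms(fs$frames[[1]]))
    stop("configuration does not match frameset topology")
  res <- .pathcv_eval_cpp(fs_cpp(fs), config$coords, isTRUE(gradients))
  out <- list(s = res$s, z = res$z)
  if (isTRUE(gradients)) {
    n <- n_atoms(config)
    ds <- matrix(0, n, 3)
    dz <- matrix(0, n, 3)
    ds[fs$displace, ] <- res$ds_dx
    dz[fs$displace, ] <- res$dz_dx
    out$ds_dx <- ds
    out$dz_dx <- dz
  }
  class(out) <- "pathcv_value"
  out
}

#' @export
print.pathcv_value <- function(x, ...) {
  cat(sprintf("<pathcv> S = %.4f, Z = %.4f A^2\n", x$s, x$z))
  invisible(x)
}

#' S and Z along a whole trajectory
#'
#' @param traj A [trajectory()].
#' @param fs A [frameset()].
#' @return Data frame with columns `time`, `s`, `z`.
#' @export
pathcv_series <- function(traj, fs) {
  res <- .pathcv_series_cpp(fs_cpp(fs), traj_flat(traj), n_frames(traj))
  data.frame(time = traj$times, s = res$s, z = res$z)
}
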