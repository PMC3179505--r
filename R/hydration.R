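#' Rational switching-function parameters for coordination counts
#'
#' @param r0 Characteristic radius in Angstrom (default 3.5).
#' @param n,m Even positive exponents with m > n (defaults 6 and 16).
#' @return A list of class `"switching_params"`.
#' @export
switching_params <- function(r0 = 3.5, n = 6, m = 16) {
  if (r0 <= 0) stop("r0 must be positive")
  if (n %% 2 != 0 || m %% 2 != 0 || n <= 0 || m <= n)
    stop("n and m must be even positive integers with m > n")
  structure(list(r0 = r0, n = as.integer(n), m = as.integer(m)),
            class = "switching_params")
}

#' Smooth coordination count around a point
#'
#' `sum_i (1 - (r_i/r0)^n) / (1 - (r_i/r0)^m)` over water positions, with
#' the removable singularity at `r = r0` evaluated as its limit `n/m`.
#' Each water contributes ~1 well inside `r0` and ~0 well outside.
#'
#' @param point A 3-vector (or k x 3 matrix of points).
#' @param waters W x 3 matrix of water-oxygen positions.
#' @param params A [switching_params()].
#' @return Coordination number(s), dimensionless.
#' @export
#' @examples
#' coordination_count(c(0, 0, 0), matrix(c(3.5, 0, 0), 1), switching_params())
#' # = 6/16 = 0.375 at r = r0
coordination_count <- function(point, waters, params = switching_params()) {
  if (is.null(dim(point))) point <- matrix(point, 1, 3)
  waters <- as.matrix(waters)
  if (!nrow(waters)) return(rep(0, nrow(point)))
  out <- .coordination_cpp(point, waters, params$r0, params$n, params$m)
  if (length(out) == 1) out[[1]] else out
}

#' Segment axis through a pocket
#'
#' A straight segment between two anchor points, divided into `n_slices`
#' slices giving `n_slices + 1` evenly spaced probe points (fractions 0,
#' 1/n, ..., 1 of the axis).
#'
#' @param from,to 3-vectors (Angstrom), e.g. centroids of stable anchor
#'   selections at the pocket bottom and mouth.
#' @param n_slices Number of slices (default 10, giving 11 points).
#' @return A list of class `"segment_axis"` with `points`
#'   ((n_slices+1) x 3) and `fractions`.
#' @export
segment_axis <- function(from, to, n_slices = 10) {
  if (n_slices < 1) stop("n_slices must be >= 1")
  fr <- seq(0, 1, length.out = n_slices + 1)
  pts <- outer(1 - fr, from) + outer(fr, to)
  structure(list(points = pts, fractions = fr, from = from, to = to,
                 n_slices = as.integer(n_slices)),
            class = "segment_axis")
}

#' Water-coordination map along a pocket axis as a function of S
#'
#' For every trajectory frame the coordination count of the `water_O` group
#' is evaluated at each axis point; frames are pooled into S-bins of width
#' `s_bin` (Z is marginalized) and averaged per (point, bin).
#'
#' @param traj A [trajectory()] whose frames carry a `water_O` group.
#' @param s_series S value per frame (same length as the trajectory).
#' @param axis A [segment_axis()].
#' @param params A [switching_params()].
#' @param s_bin S bin width (default 0.5).
#' @return Matrix (axis point x S bin) of mean water counts, with axis
#'   fractions as row names and bin centres as column names; class
#'   `"hydration_map"`.
#' @export
hydration_map <- function(traj, s_series, axis, params = switching_params(),
                          s_bin = 0.5) {
  if (length(s_series) != n_frames(traj))
    stop("s_series must align with the trajectory frames")
  wat <- traj$frames[[1]]$groups$water_O
  if (is.null(wat)) stop("trajectory has no water_O group")
  npt <- nrow(axis$points)
  bin <- floor(s_series / s_bin)
  bins <- sort(unique(bin))
  acc <- matrix(0, npt, length(bins), dimnames = list(
    sprintf("%.1f", axis$fractions), sprintf("%.2f", (bins + 0.5) * s_bin)))
  cnt <- numeric(length(bins))
  bidx <- match(bin, bins)
  for (f in seq_len(n_frames(traj))) {
    co <- if (length(wat))
      coordination_count(axis$points,
                         traj$frames[[f]]$coords[wat, , drop = FALSE], params)
    else rep(0, npt)
    acc[, bidx[f]] <- acc[, bidx[f]] + co
    cnt[bidx[f]] <- cnt[bidx[f]] + 1
  }
  out <- sweep(acc, 2, pmax(cnt, 1), "/")
  class(out) <- c("hydration_map", class(out))
  out
}
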