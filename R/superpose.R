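#' Optimal rigid-body superposition (Kearsley quaternion method)
#'
#' Finds the rotation and translation minimizing the RMSD between the
#' alignment atoms of `mobile` and `reference`. The returned transform maps
#' mobile coordinates into the reference frame as
#' `x' = (x - cm_mobile) %*% t(rotation) + cm_reference`
#' (rows are atoms). The minimized RMSD comes directly from the smallest
#' eigenvalue of the 4x4 Kearsley matrix.
#'
#' @param mobile,reference [configuration()]s with matching topology.
#' @param align_selection Atom indices or group name; at least 3
#'   non-collinear atoms.
#' @return List with `rotation` (3x3), `cm_mobile`, `cm_reference`, `rmsd`
#'   (Angstrom) and `apply(coords)` transforming arbitrary coordinates.
#' @export
superpose <- function(mobile, reference, align_selection) {
  sel <- resolve_selection(mobile, align_selection)
  if (length(sel) < 3) stop("need at least 3 alignment atoms")
  a <- mobile$coords[sel, , drop = FALSE]
  b <- reference$coords[sel, , drop = FALSE]
  if (collinear(a) || collinear(b))
    stop("alignment atoms are (nearly) collinear: degenerate fit")
  fit <- .kearsley_cpp(a, b)
  fit$apply <- function(coords)
    sweep(coords, 2, fit$cm_mobile) %*% t(fit$rotation) +
      matrix(fit$cm_reference, nrow(coords), 3, byrow = TRUE)
  fit
}

collinear <- function(m, tol = 1e-8) {
  if (nrow(m) < 3) return(TRUE)
  c0 <- sweep(m, 2, colMeans(m))
  sv <- svd(c0, nu = 0, nv = 0)$d
  sv[2] < tol * max(sv[1], 1)
}

#' MSD metric between two configurations
#'
#' Mean squared deviation (Angstrom^2) over `displace_selection` after
#' least-squares superposition over `align_selection`. This is the distance
#' entering the path collective variables. With an empty alignment
#' selection no fit is performed (raw displacement MSD), which is the
#' natural choice for abstract low-dimensional systems.
#'
#' @param a,b [configuration()]s with matching topology.
#' @param align_selection Alignment atoms (indices, group name, or `NULL`
#'   for no superposition).
#' @param displace_selection Atoms over which the deviation is measured.
#' @return MSD in Angstrom^2.
#' @export
msd_distance <- function(a, b, align_selection, displace_selection) {
  al <- if (is.null(align_selection)) integer(0)
        else resolve_selection(a, align_selection)
  di <- resolve_selection(a, displace_selection)
  if (!length(di)) stop("displace_selection must be non-empty")
  if (length(al) > 0 && length(al) < 3)
    stop("alignment needs at least 3 atoms (or NULL for none)")
  .msd_cpp(a$coords, b$coords, as.integer(al), as.integer(di))
}
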