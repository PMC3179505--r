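#' Atomic configuration
#'
#' The universal substrate of all collective variables and monitors: an
#' ordered set of atoms with Cartesian coordinates in Angstrom, per-atom
#' element symbols and names, and named index groups (selections).
#'
#' @param coords Numeric N x 3 matrix of coordinates (Angstrom).
#' @param elements Character vector of element symbols (recycled if length 1).
#' @param names Character vector of atom labels (recycled if length 1).
#' @param groups Named list of integer atom index vectors (1-based).
#' @param masses Optional per-atom masses in amu (default 12 for every atom).
#' @return An object of class `"configuration"`.
#' @export
#' @examples
#' conf <- configuration(matrix(rnorm(9), 3, 3), elements = "C")
#' n_atoms(conf)
configuration <- function(coords, elements = "C", names = elements,
                          groups = list(), masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 1) stop("a configuration needs at least one atom")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  elements <- rep_len(as.character(elements), n)
  names <- rep_len(as.character(names), n)
  if (is.null(masses)) masses <- rep(12, n) else masses <- rep_len(masses, n)
  for (g in base::names(groups)) {
    idx <- groups[[g]]
    if (length(idx) && (any(idx < 1) || any(idx > n)))
      stop(sprintf("group '%s' has indices outside 1..%d", g, n))
    groups[[g]] <- as.integer(idx)
  }
  structure(list(coords = unname(coords), elements = elements, names = names,
                 groups = groups, masses = masses),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> %d atoms, %d groups (%s)\n", n_atoms(x),
              length(x$groups), paste(names(x$groups), collapse = ", ")))
  invisible(x)
}

#' Number of atoms in a configuration or trajectory
#' @param x A `configuration` or `trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) UseMethod("n_atoms")

#' @export
n_atoms.configuration <- function(x) nrow(x$coords)

#' @export
n_atoms.trajectory <- function(x) nrow(x$frames[[1]]$coords)

#' Resolve an atom selection on a configuration
#'
#' A selection is either an integer index vector or the name of a group
#' stored on the configuration.
#'
#' @param conf A `configuration`.
#' @param sel Integer indices or a group name.
#' @return Integer atom indices (1-based).
#' @export
resolve_selection <- function(conf, sel) {
  if (is.character(sel) && length(sel) == 1) {
    if (is.null(conf$groups[[sel]]))
      stop(sprintf("no group named '%s' on this configuration", sel))
    return(conf$groups[[sel]])
  }
  sel <- as.integer(sel)
  if (length(sel) && (any(sel < 1) || any(sel > n_atoms(conf))))
    stop("selection indices out of range")
  sel
}

#' Trajectory: ordered configurations sharing one topology
#'
#' @param frames List of `configuration` objects with identical atom counts
#'   and labels.
#' @param times Numeric vector of times in ps, strictly increasing. Defaults
#'   to `0, 1, 2, ...` when absent.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(frames, times = NULL) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  n <- nrow(frames[[1]]$coords)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$coords) != n)
      stop(sprintf("frame %d has %d atoms, expected %d", i,
                   nrow(frames[[i]]$coords), n))
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames))
    stop("times and frames differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(frames = frames, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %g..%g ps\n",
              n_frames(x), n_atoms(x), x$times[1], tail(x$times, 1)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

# flat coordinate vector (frame-major) for the compiled back-ends
traj_flat <- function(traj) {
  unlist(lapply(traj$frames, function(f) as.vector(t(f$coords))),
         use.names = FALSE)
}

# rebuild a trajectory from flat coords + a template configuration
traj_from_flat <- function(flat, template, times) {
  n <- n_atoms(template)
  nf <- length(flat) / (3 * n)
  frames <- lapply(seq_len(nf), function(i) {
    m <- matrix(flat[((i - 1) * 3 * n + 1):(i * 3 * n)], ncol = 3, byrow = TRUE)
    out <- template
    out$coords <- m
    out
  })
  trajectory(frames, times)
}
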