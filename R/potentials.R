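#' @rdname potentials
#' @export
potential_energy <- function(potential, conf) {
  .pot_energy_cpp(potential$spec, conf$coords)
}

#' @rdname potentials
#' @export
potential_gradient <- function(potential, conf) {
  .pot_gradient_cpp(potential$spec, conf$coords)
}

new_potential <- function(spec, dim, analytic_free_energy = NULL) {
  p <- list(spec = spec, dim = dim,
            analytic_free_energy = analytic_free_energy)
  p$energy <- function(conf) .pot_energy_cpp(spec, conf$coords)
  p$gradient <- function(conf) .pot_gradient_cpp(spec, conf$coords)
  class(p) <- "potential"
  p
}

#' @export
print.potential <- function(x, ...) {
  cat(sprintf("<potential> type '%s', %d atom(s)\n", x$spec$type,
              x$spec$n_atoms))
  invisible(x)
}

#' Analytic toy potentials
#'
#' `double_well_1d()` builds the symmetric quartic double well
#' \deqn{V(x) = b \, ((2x/a)^2 - 1)^2}
#' with minima `V = 0` at `x = +/- a/2` and `V(0) = b` (the barrier), acting
#' on the x coordinate of one atom. Being one-dimensional, its analytic free
#' energy along x is V itself. `harmonic_potential()` is an isotropic
#' harmonic well (`V = k/2 sum |x - x0|^2`), `linear_potential()` a constant
#' slope along x; both serve as closed-form references for the sampler and
#' the steering module.
#'
#' `potential_energy()`/`potential_gradient()` evaluate any potential on a
#' [configuration()]; gradients are analytic.
#'
#' @param barrier Barrier height b in kcal/mol (> 0).
#' @param separation Distance a between the two minima in Angstrom (> 0).
#' @param atom Index of the atom the 1D potential acts on.
#' @param n_atoms Number of atoms in configurations this potential accepts.
#' @param k Harmonic force constant, kcal mol^-1 A^-2.
#' @param x0 Equilibrium coordinates, N x 3 (defaults to the origin).
#' @param slope Slope g in kcal mol^-1 A^-1.
#' @param k_perp Transverse confinement (kcal mol^-1 A^-2) tying the y and
#'   z coordinates of the 1D atom to zero — the embedding of a 1D model in
#'   3D space.
#' @param atoms Optional atom subset a harmonic restraint acts on (rows of
#'   `x0` then correspond to these atoms).
#' @param potential A potential object.
#' @param conf A [configuration()].
#' @return A `potential` object with fields `energy(conf)`, `gradient(conf)`
#'   (kcal/mol and kcal/mol/A) and, where available,
#'   `analytic_free_energy(x)`.
#' @name potentials
#' @export
#' @examples
#' dw <- double_well_1d(5, 2)
#' dw$energy(configuration(matrix(c(0, 0, 0), 1, 3))) # = 5
double_well_1d <- function(barrier, separation, atom = 1, n_atoms = 1,
                           k_perp = 100) {
  if (barrier <= 0 || separation <= 0)
    stop("barrier and separation must be positive")
  spec <- list(type = "double_well_1d", n_atoms = as.integer(n_atoms),
               barrier = barrier, separation = separation,
               atom = as.integer(atom), k_perp = k_perp)
  new_potential(spec, dim = 1,
                analytic_free_energy = function(x)
                  barrier * ((2 * x / separation)^2 - 1)^2)
}

#' @rdname potentials
#' @export
harmonic_potential <- function(k, n_atoms = 1, x0 = NULL, atoms = NULL) {
  if (k <= 0) stop("k must be positive")
  na <- if (is.null(atoms)) n_atoms else length(atoms)
  if (is.null(x0)) x0 <- matrix(0, na, 3)
  spec <- list(type = "harmonic", n_atoms = as.integer(n_atoms), k = k,
               x0 = as.vector(t(x0)))
  if (!is.null(atoms)) spec$atoms <- as.integer(atoms)
  new_potential(spec, dim = 3 * na,
                analytic_free_energy = function(x) 0.5 * k * x^2)
}

#' @rdname potentials
#' @export
linear_potential <- function(slope, atom = 1, n_atoms = 1, k_perp = 100) {
  spec <- list(type = "linear_1d", n_atoms = as.integer(n_atoms),
               slope = slope, atom = as.integer(atom), k_perp = k_perp)
  new_potential(spec, dim = 1,
                analytic_free_energy = function(x) slope * x)
}

#' @rdname potentials
#' @param ... For `composite_potential()`: potential objects sharing one
#'   atom count whose energies are summed.
#' @export
composite_potential <- function(...) {
  parts <- list(...)
  if (!length(parts)) stop("need at least one component")
  n <- parts[[1]]$spec$n_atoms
  for (p in parts)
    if (p$spec$n_atoms != n) stop("components disagree on atom count")
  spec <- list(type = "composite", n_atoms = as.integer(n),
               components = lapply(parts, function(p) p$spec))
  new_potential(spec, dim = 3 * n)
}
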