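#' Specification of the funnel-pocket toy system
#'
#' Desk-scale stand-in for a deep binding cleft: a quasi-rigid ligand of
#' `ligand_atoms` beads sits in an axial binding well of depth
#' `pocket_depth` that decays to bulk over `channel_length` along the pocket
#' axis (z); purely repulsive solvent beads occupy the bulk and can exchange
#' with the pocket across a gate at the pocket mouth. `backdoor = TRUE`
#' lowers that gate, emulating a secondary channel that lets solvent reach
#' the pocket bottom regardless of whether the ligand blocks the mouth. A
#' restrained reference cage of beads around the pocket bottom and mouth
#' provides the alignment frame for path collective variables.
#'
#' @param pocket_depth Well depth in kcal/mol (> 0).
#' @param channel_length Distance in Angstrom over which the well decays to
#'   bulk.
#' @param n_solvent Number of solvent beads.
#' @param backdoor Logical; low solvent gate (TRUE) or high (FALSE).
#' @param ligand_atoms Number of ligand beads (>= 3 so superposition is
#'   well-posed).
#' @param seed Integer seed for the initial solvent placement.
#' @return A list of class `"toy_pocket_spec"`.
#' @export
toy_pocket_spec <- function(pocket_depth = 6, channel_length = 8,
                            n_solvent = 12, backdoor = TRUE,
                            ligand_atoms = 4, seed = 1) {
  if (pocket_depth <= 0) stop("pocket_depth must be positive")
  if (ligand_atoms < 3) stop("ligand_atoms must be >= 3")
  if (channel_length <= 0) stop("channel_length must be positive")
  structure(list(pocket_depth = pocket_depth,
                 channel_length = channel_length,
                 n_solvent = as.integer(n_solvent),
                 backdoor = isTRUE(backdoor),
                 ligand_atoms = as.integer(ligand_atoms),
                 seed = as.integer(seed)),
            class = "toy_pocket_spec")
}

#' Build the funnel-pocket toy system
#'
#' Returns the many-particle potential and an initial bound configuration
#' with groups `ligand_heavy`, `pocket_ref` (plus `pocket_bottom_ref`,
#' `pocket_mouth_ref`) and `water_O` populated. The construction is
#' deterministic for a given `spec$seed`.
#'
#' Geometry: the pocket sits at the origin with its axis along +z. The
#' ligand is a ring of beads (radius 0.6 A) held quasi-rigid by stiff
#' harmonic bonds (200 kcal/mol/A^2) whose centre of mass feels the binding
#' well, a radial tube wall (radius 1.2 A) and axial caps; solvent beads
#' (WCA, sigma 2.8 A) are confined to a funnel — a cylinder of radius 6 A
#' in the bulk narrowing to 2 A below the pocket mouth — and pass a
#' Gaussian gate bump at the mouth (z = 2.5 A) of height 0.5 (backdoor) or
#' 4 kcal/mol (no backdoor). The pocket interior attracts solvent weakly
#' (1.5 kcal/mol, a polar cavity), so the pocket hydrates when empty while
#' a bound ligand sterically dries it. Reference beads are restrained
#' to sites by 50 kcal/mol/A^2 springs and do not interact otherwise.
#'
#' @param spec A [toy_pocket_spec()].
#' @return List with elements `potential` and `configuration`.
#' @export
#' @examples
#' sys <- build_toy_pocket(toy_pocket_spec(n_solvent = 0))
#' sys$potential$energy(sys$configuration) # ~ -pocket_depth
build_toy_pocket <- function(spec) {
  stopifnot(inherits(spec, "toy_pocket_spec"))
  nl <- spec$ligand_atoms
  ns <- spec$n_solvent
  L <- spec$channel_length

  # ligand ring in the xy plane, COM at the origin
  ang <- 2 * pi * (seq_len(nl) - 1) / nl
  lig_xyz <- cbind(0.6 * cos(ang), 0.6 * sin(ang), 0)
  lig_xyz <- sweep(lig_xyz, 2, colMeans(lig_xyz))

  # reference cage: 3 beads around the pocket bottom, 4 around the mouth
  bot <- cbind(2.5 * cos(2 * pi * (0:2) / 3), 2.5 * sin(2 * pi * (0:2) / 3), -1.5)
  mou <- cbind(3.5 * cos(pi / 4 + 2 * pi * (0:3) / 4),
               3.5 * sin(pi / 4 + 2 * pi * (0:3) / 4), 2.5)
  ref_sites <- rbind(bot, mou)

  gate_z <- 2.5
  z_hi_solv <- L + 6
  rho_solv <- 6

  # deterministic solvent placement in the bulk, bounded retries
  solv_xyz <- matrix(numeric(0), 0, 3)
  if (ns > 0) {
    rs <- local_rng(spec$seed, {
      placed <- matrix(NA_real_, ns, 3)
      got <- 0
      for (try in seq_len(5000 + 400 * ns)) {
        if (got == ns) break
        rho <- sqrt(stats::runif(1)) * (rho_solv - 0.5)
        th <- stats::runif(1, 0, 2 * pi)
        cand <- c(rho * cos(th), rho * sin(th),
                  stats::runif(1, gate_z + 1.5, z_hi_solv - 0.5))
        ok <- TRUE
        if (got > 0) {
          d2 <- colSums((t(placed[seq_len(got), , drop = FALSE]) - cand)^2)
          if (min(d2) < 2.6^2) ok <- FALSE
        }
        if (ok && min(colSums((t(lig_xyz) - cand)^2)) < 2.9^2) ok <- FALSE
        if (ok) {
          got <- got + 1
          placed[got, ] <- cand
        }
      }
      if (got < ns)
        stop("solvent placement failed after bounded retries; lower n_solvent")
      placed
    })
    solv_xyz <- rs
  }

  coords <- rbind(lig_xyz, ref_sites, solv_xyz)
  n <- nrow(coords)
  lig_idx <- seq_len(nl)
  ref_idx <- nl + seq_len(nrow(ref_sites))
  solv_idx <- if (ns > 0) nl + nrow(ref_sites) + seq_len(ns) else integer(0)

  conf <- configuration(
    coords,
    elements = c(rep("C", nl), rep("X", nrow(ref_sites)), rep("O", ns)),
    names = c(sprintf("L%d", seq_len(nl)), sprintf("R%d", seq_len(nrow(ref_sites))),
              if (ns > 0) sprintf("W%d", seq_len(ns))),
    groups = list(ligand_heavy = lig_idx,
                  pocket_ref = ref_idx,
                  pocket_bottom_ref = nl + 1:3,
                  pocket_mouth_ref = nl + 4:7,
                  water_O = solv_idx))

  bonds <- t(utils::combn(lig_idx, 2))
  bond_r0 <- sqrt(rowSums((lig_xyz[bonds[, 1], , drop = FALSE] -
                             lig_xyz[bonds[, 2], , drop = FALSE])^2))

  pspec <- list(type = "toy_pocket", n_atoms = as.integer(n),
                depth = spec$pocket_depth,
                z_half = L / 3, delta = L / 12,
                ligand = as.integer(lig_idx), solvent = as.integer(solv_idx),
                ref = as.integer(ref_idx),
                bond_i = as.integer(bonds[, 1]), bond_j = as.integer(bonds[, 2]),
                bond_r0 = bond_r0, k_int = 200,
                ref_sites = as.vector(t(ref_sites)), k_ref = 50,
                sigma_wca = 2.8, eps_wca = 0.2,
                rho_lig = 1.2, z_lo_lig = -0.5, z_hi_lig = L + 2,
                rho_solv = rho_solv, rho_pocket = 2,
                z_lo_solv = -2, z_hi_solv = z_hi_solv,
                k_wall = 10,
                gate_height = if (spec$backdoor) 0.5 else 4,
                gate_z = gate_z, gate_w = 0.6,
                eps_solv_pocket = 1.5)

  list(potential = new_potential(pspec, dim = 3 * n), configuration = conf,
       spec = spec)
}

# evaluate `expr` under a temporary, seeded RNG state
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
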