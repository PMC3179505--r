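#' Distance monitor
#'
#' Per-frame Euclidean distance between two selections, either between
#' single atoms (`mode = "atom"`, selections of length 1) or between
#' selection centroids (`mode = "centroid"`). The two modes coincide for
#' singleton selections.
#'
#' @param traj A [trajectory()].
#' @param sel_a,sel_b Atom selections (indices or group names).
#' @param mode `"atom"` or `"centroid"`.
#' @return Data frame with columns `frame`, `time`, `value` (Angstrom).
#' @export
monitor_distance <- function(traj, sel_a, sel_b, mode = c("centroid", "atom")) {
  mode <- match.arg(mode)
  f1 <- traj$frames[[1]]
  a <- resolve_selection(f1, sel_a)
  b <- resolve_selection(f1, sel_b)
  if (!length(a) || !length(b)) stop("selections must be non-empty")
  if (mode == "atom" && (length(a) != 1 || length(b) != 1))
    stop("atom mode requires singleton selections")
  val <- vapply(traj$frames, function(f) {
    ca <- colMeans(f$coords[a, , drop = FALSE])
    cb <- colMeans(f$coords[b, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  data.frame(frame = seq_along(val), time = traj$times, value = val)
}

#' Dihedral-angle monitor
#'
#' Signed dihedral defined by four atoms via the standard atan2
#' construction, in degrees in (-180, 180].
#'
#' @param traj A [trajectory()].
#' @param atoms Integer vector of 4 distinct atom indices.
#' @return Data frame with columns `frame`, `time`, `value` (degrees).
#' @export
monitor_dihedral <- function(traj, atoms) {
  if (length(atoms) != 4 || anyDuplicated(atoms))
    stop("need 4 distinct atoms")
  val <- vapply(traj$frames, function(f) {
    p <- f$coords[atoms, , drop = FALSE]
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
      stop("collinear atoms: dihedral undefined")
    x <- sum(n1 * n2)
    y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
    ang <- atan2(y, x) * 180 / pi
    if (ang <= -180) ang + 360 else ang
  }, numeric(1))
  data.frame(frame = seq_along(val), time = traj$times, value = val)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' RMSD time series and per-atom RMSF
#'
#' Every frame is superposed onto the first frame over `align_selection`;
#' the RMSD is then measured over `measure_selection` per frame, and the
#' RMSF as each atom's root-mean-square deviation from its time-mean
#' position after alignment.
#'
#' @param traj A [trajectory()].
#' @param align_selection Alignment atoms (>= 3, non-collinear).
#' @param measure_selection Atoms entering RMSD/RMSF (default: the
#'   alignment atoms).
#' @return List with `rmsd` (data frame frame/time/value, Angstrom) and
#'   `rmsf` (named vector, Angstrom, one per measured atom).
#' @export
rmsd_rmsf <- function(traj, align_selection, measure_selection = align_selection) {
  f1 <- traj$frames[[1]]
  al <- resolve_selection(f1, align_selection)
  me <- resolve_selection(f1, measure_selection)
  if (length(al) < 3) stop("need at least 3 alignment atoms")
  nf <- n_frames(traj)
  aligned <- array(NA_real_, c(length(me), 3, nf))
  rmsd <- numeric(nf)
  for (f in seq_len(nf)) {
    fit <- superpose(traj$frames[[f]], f1, al)
    cc <- fit$apply(traj$frames[[f]]$coords[me, , drop = FALSE])
    aligned[, , f] <- cc
    rmsd[f] <- sqrt(mean(rowSums((cc - f1$coords[me, , drop = FALSE])^2)))
  }
  mean_pos <- apply(aligned, c(1, 2), mean)
  rmsf <- sqrt(vapply(seq_along(me), function(i)
    mean(colSums((aligned[i, , ] - mean_pos[i, ])^2)), numeric(1)))
  list(rmsd = data.frame(frame = seq_len(nf), time = traj$times,
                         value = rmsd),
       rmsf = setNames(rmsf, f1$names[me]))
}

#' Catalytic-competence predicate
#'
#' A pose is catalytically competent when (a) the hydride-transfer distance
#' (donor carbon to acceptor carbon) is within `hydride_cutoff` and (b, c)
#' the two hydrogen-bond distances from the substrate keto oxygen to the
#' catalytic tyrosine and serine oxygens are within `hbond_cutoff`.
#'
#' @param frame A [configuration()].
#' @param roles Named list/vector of atom indices: `hydride_donor`,
#'   `hydride_acceptor`, `keto_o`, `tyr_o`, `ser_o`.
#' @param hydride_cutoff Hydride distance cutoff in Angstrom (default 4.5).
#' @param hbond_cutoff Hydrogen-bond cutoff in Angstrom (default 3.5).
#' @return Logical; per-criterion distances in `attr(, "distances")`.
#' @export
is_catalytically_competent <- function(frame, roles, hydride_cutoff = 4.5,
                                       hbond_cutoff = 3.5) {
  need <- c("hydride_donor", "hydride_acceptor", "keto_o", "tyr_o", "ser_o")
  missing <- setdiff(need, names(roles))
  if (length(missing))
    stop("missing role atoms: ", paste(missing, collapse = ", "))
  d <- function(i, j) sqrt(sum((frame$coords[roles[[i]], ] -
                                  frame$coords[roles[[j]], ])^2))
  dist <- c(hydride = d("hydride_donor", "hydride_acceptor"),
            hbond_tyr = d("keto_o", "tyr_o"),
            hbond_ser = d("keto_o", "ser_o"))
  ok <- dist[["hydride"]] <= hydride_cutoff &&
    dist[["hbond_tyr"]] <= hbond_cutoff &&
    dist[["hbond_ser"]] <= hbond_cutoff
  structure(ok, distances = dist)
}
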