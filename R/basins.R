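#' Locate free-energy basins on a surface
#'
#' Local minima are found on the grid (8-neighbourhood) and every cell is
#' assigned to a basin by steepest descent. Basins whose depth relative to
#' their lowest spill point (the saddle to a neighbouring basin) is below
#' `min_depth` are merged into that neighbour, so sub-isoline wrinkles do
#' not count as separate states. Basins are labelled `A`, `B`, ... in order
#' of increasing minimum free energy.
#'
#' @param fes An `"fes"` object.
#' @param min_depth Minimum basin depth in kcal/mol (default 1, one
#'   isoline).
#' @param max_value Ignore cells above this free energy (default: all).
#' @return A data frame of class `"basin_set"`: `label`, `s`, `z` (minimum
#'   location), `min_value`, `depth` relative to the global minimum; the
#'   basin map (matrix of labels) is in `attr(, "map")`.
#' @export
find_basins <- function(fes, min_depth = 1, max_value = Inf) {
  v <- fes$values
  ns <- nrow(v); nz <- ncol(v)
  if (diff(range(v[is.finite(v)])) < 1e-12)
    return(empty_basins(fes))
  # steepest-descent assignment
  nb_off <- expand.grid(di = -1:1, dj = -1:1)
  nb_off <- nb_off[!(nb_off$di == 0 & nb_off$dj == 0), ]
  down <- matrix(0L, ns, nz) # linear index of steepest lower neighbour, 0 = min
  for (i in seq_len(ns)) {
    for (j in seq_len(nz)) {
      if (!is.finite(v[i, j]) || v[i, j] > max_value) { down[i, j] <- -1L; next }
      best <- 0; bi <- 0L
      for (k in seq_len(nrow(nb_off))) {
        ii <- i + nb_off$di[k]; jj <- j + nb_off$dj[k]
        if (ii < 1 || ii > ns || jj < 1 || jj > nz) next
        if (!is.finite(v[ii, jj])) next
        drop <- v[i, j] - v[ii, jj]
        if (drop > best) { best <- drop; bi <- ii + (jj - 1L) * ns }
      }
      down[i, j] <- bi
    }
  }
  # path compression to basin roots
  basin <- matrix(0L, ns, nz)
  roots <- integer(0)
  for (lin in seq_len(ns * nz)) {
    if (down[lin] < 0L) { basin[lin] <- NA_integer_; next }
    chain <- lin
    cur <- lin
    while (down[cur] > 0L && basin[cur] == 0L) {
      cur <- down[cur]
      chain <- c(chain, cur)
    }
    root_id <- if (basin[cur] > 0L) basin[cur] else {
      roots <- c(roots, cur)
      length(roots)
    }
    basin[chain] <- root_id
  }
  # merge shallow basins into their spill neighbours
  repeat {
    info <- basin_spills(v, basin, roots)
    shallow <- which(info$depth < min_depth & is.finite(info$depth))
    if (!length(shallow)) break
    worst <- shallow[which.min(info$depth[shallow])]
    tgt <- info$spill_to[worst]
    basin[basin == worst] <- tgt
    roots[worst] <- NA_integer_
    live <- which(!is.na(roots))
    relab <- match(seq_along(roots), live)
    basin[] <- relab[basin]
    roots <- roots[live]
  }
  mins <- vapply(roots, function(r) v[r], numeric(1))
  ord <- order(mins)
  relab <- match(seq_along(roots), ord)
  basin[] <- relab[basin]
  roots <- roots[ord]
  mins <- mins[ord]
  si <- ((roots - 1L) %% ns) + 1L
  zi <- ((roots - 1L) %/% ns) + 1L
  out <- data.frame(label = LETTERS[seq_along(roots)],
                    s = fes$s[si], z = fes$z[zi],
                    min_value = mins, depth = mins - min(mins))
  class(out) <- c("basin_set", class(out))
  attr(out, "map") <- basin
  attr(out, "fes") <- fes
  out
}

empty_basins <- function(fes) {
  out <- data.frame(label = character(0), s = numeric(0), z = numeric(0),
                    min_value = numeric(0), depth = numeric(0))
  class(out) <- c("basin_set", class(out))
  attr(out, "fes") <- fes
  out
}

# depth of each basin below its lowest boundary (spill) point and the basin
# it would spill into
basin_spills <- function(v, basin, roots) {
  nbasin <- length(roots)
  ns <- nrow(v); nz <- ncol(v)
  spill <- rep(Inf, nbasin)
  spill_to <- rep(NA_integer_, nbasin)
  for (i in seq_len(ns)) {
    for (j in seq_len(nz)) {
      b <- basin[i, j]
      if (is.na(b)) next
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > ns || jj < 1 || jj > nz) next
        b2 <- basin[ii, jj]
        if (is.na(b2) || b2 == b) next
        lev <- max(v[i, j], v[ii, jj])
        if (lev < spill[b]) { spill[b] <- lev; spill_to[b] <- b2 }
      }
    }
  }
  mins <- vapply(roots, function(r) if (is.na(r)) NA_real_ else v[r], numeric(1))
  list(depth = spill - mins, spill_to = spill_to)
}

#' Free-energy difference between two basins
#'
#' Minimum-to-minimum difference `F(b) - F(a)`; positive when basin `a` is
#' the deeper one. For a bound-state basin `a` and an unbound basin `b`
#' this is the binding free energy read off the surface.
#'
#' @param basins A `"basin_set"` from [find_basins()].
#' @param a,b Basin labels.
#' @return Free-energy difference in kcal/mol.
#' @export
basin_delta_g <- function(basins, a, b) {
  ia <- match(a, basins$label); ib <- match(b, basins$label)
  if (is.na(ia) || is.na(ib)) stop("unknown basin label")
  basins$min_value[ib] - basins$min_value[ia]
}

#' Barrier height between two basins (lowest saddle)
#'
#' The minimax path value between the two minima — the lowest free energy
#' at which the basins connect — minus the value at the minimum of basin
#' `a`. Computed by a Dijkstra-type search where a path's cost is the
#' maximum cell value along it (8-neighbourhood).
#'
#' @param basins A `"basin_set"` (with its FES attached).
#' @param a,b Basin labels.
#' @return Barrier in kcal/mol relative to basin `a`'s minimum.
#' @export
barrier_height <- function(basins, a, b) {
  if (identical(a, b)) return(0)
  fes <- attr(basins, "fes")
  ia <- match(a, basins$label); ib <- match(b, basins$label)
  if (is.na(ia) || is.na(ib)) stop("unknown basin label")
  v <- fes$values
  from <- c(which.min(abs(fes$s - basins$s[ia])),
            which.min(abs(fes$z - basins$z[ia])))
  to <- c(which.min(abs(fes$s - basins$s[ib])),
          which.min(abs(fes$z - basins$z[ib])))
  mm <- minimax_level(v, from, to)
  if (!is.finite(mm)) stop("basins are not connected on the grid")
  mm - basins$min_value[ia]
}

# lowest level at which `from` and `to` connect: Dijkstra with max-edge cost
minimax_level <- function(v, from, to) {
  ns <- nrow(v); nz <- ncol(v)
  start <- from[1] + (from[2] - 1L) * ns
  goal <- to[1] + (to[2] - 1L) * ns
  best <- matrix(Inf, ns, nz)
  best[start] <- max(v[start], -Inf)
  # simple priority queue on vectors (grids are small)
  frontier <- c(start)
  fcost <- c(best[start])
  visited <- matrix(FALSE, ns, nz)
  while (length(frontier)) {
    k <- which.min(fcost)
    cur <- frontier[k]; cost <- fcost[k]
    frontier <- frontier[-k]; fcost <- fcost[-k]
    if (visited[cur]) next
    visited[cur] <- TRUE
    if (cur == goal) return(cost)
    i <- ((cur - 1L) %% ns) + 1L
    j <- ((cur - 1L) %/% ns) + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > ns || jj < 1 || jj > nz) next
      nxt <- ii + (jj - 1L) * ns
      if (visited[nxt] || !is.finite(v[nxt])) next
      c2 <- max(cost, v[nxt])
      if (c2 < best[nxt]) {
        best[nxt] <- c2
        frontier <- c(frontier, nxt)
        fcost <- c(fcost, c2)
      }
    }
  }
  Inf
}
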