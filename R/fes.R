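#' Reconstruct the free-energy surface from a hill log
#'
#' In standard (non-well-tempered) metadynamics the accumulated bias
#' mirrors the negative free energy, so `F(s, z) = -V(s, z, t)` shifted so
#' its minimum is zero. The sum over hills is exact (no grid
#' approximation). An empty log gives a flat zero surface.
#'
#' @param hills A [hill_log()].
#' @param t Use hills deposited before `t` ps (default all).
#' @param grid List with `s` and `z` axis vectors; by default a regular
#'   grid covering all hill centres +/- 4 sigma at spacing sigma/2.
#' @return An object of class `"fes"`: fields `s`, `z` (axes) and `values`
#'   (length(s) x length(z) matrix, kcal/mol, min 0).
#' @export
reconstruct_fes <- function(hills, t = Inf, grid = NULL) {
  if (is.null(grid)) {
    if (nrow(hills)) {
      ss <- hills$sigma_s[1]; sz <- hills$sigma_z[1]
      grid <- list(s = seq(min(hills$s) - 4 * ss, max(hills$s) + 4 * ss,
                           by = ss / 2),
                   z = seq(min(hills$z) - 4 * sz, max(hills$z) + 4 * sz,
                           by = sz / 2))
    } else {
      grid <- list(s = seq(0, 1, length.out = 11),
                   z = seq(0, 1, length.out = 11))
    }
  }
  ns <- length(grid$s); nz <- length(grid$z)
  V <- matrix(0, ns, nz)
  if (nrow(hills)) {
    k <- hills$time < t
    if (any(k)) {
      h <- hills[k, ]
      # separable Gaussian factors; fast path when widths are constant
      if (length(unique(h$sigma_s)) == 1 && length(unique(h$sigma_z)) == 1) {
        es <- exp(-outer(grid$s, h$s, "-")^2 / (2 * h$sigma_s[1]^2))
        ez <- exp(-outer(grid$z, h$z, "-")^2 / (2 * h$sigma_z[1]^2))
        V <- es %*% (h$height * t(ez))
      } else {
        for (i in seq_len(nrow(h))) {
          es <- exp(-(grid$s - h$s[i])^2 / (2 * h$sigma_s[i]^2))
          ez <- exp(-(grid$z - h$z[i])^2 / (2 * h$sigma_z[i]^2))
          V <- V + h$height[i] * outer(es, ez)
        }
      }
    }
  }
  f <- -V
  f <- f - min(f)
  structure(list(s = grid$s, z = grid$z, values = f), class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  cat(sprintf("<fes> %d x %d grid, S in [%.3g, %.3g], Z in [%.3g, %.3g], max %.3g kcal/mol\n",
              length(x$s), length(x$z), min(x$s), max(x$s), min(x$z),
              max(x$z), max(x$values)))
  invisible(x)
}

#' Average several FES snapshots
#'
#' Standard variance reduction for metadynamics estimates: reconstruct the
#' surface at several late checkpoints and average the (min-shifted)
#' snapshots on a common grid.
#'
#' @param hills A [hill_log()].
#' @param times Checkpoint times (ps).
#' @param grid As in [reconstruct_fes()]; default covers the full log.
#' @return An `"fes"` object.
#' @export
reconstruct_fes_averaged <- function(hills, times, grid = NULL) {
  if (is.null(grid)) {
    full <- reconstruct_fes(hills)
    grid <- list(s = full$s, z = full$z)
  }
  snaps <- lapply(times, function(t) reconstruct_fes(hills, t, grid)$values)
  avg <- Reduce(`+`, snaps) / length(snaps)
  avg <- avg - min(avg)
  structure(list(s = grid$s, z = grid$z, values = avg), class = "fes")
}

#' Write an FES as gridded TSV (columns s, z, free_energy)
#' @param fes An `"fes"` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fes_table <- function(fes, path) {
  df <- data.frame(s = rep(fes$s, times = length(fes$z)),
                   z = rep(fes$z, each = length(fes$s)),
                   free_energy = as.vector(fes$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Contour plot of an FES with 1 kcal/mol isolines
#' @param x An `"fes"` object.
#' @param isoline Isoline separation in kcal/mol.
#' @param ... Passed to [graphics::contour()].
#' @export
plot.fes <- function(x, isoline = 1, ...) {
  graphics::contour(x$s, x$z, x$values,
                    levels = seq(0, max(x$values), by = isoline),
                    xlab = "S", ylab = expression(Z ~ (ring(A)^2)), ...)
  invisible(x)
}

#' Minimum free energy inside an (S, Z) window
#'
#' @param fes An `"fes"` object.
#' @param s_range,z_range Inclusive ranges; `NULL` means no restriction.
#' @return Minimum free energy (kcal/mol) in the window.
#' @export
fes_window_min <- function(fes, s_range = NULL, z_range = NULL) {
  si <- if (is.null(s_range)) seq_along(fes$s)
        else which(fes$s >= s_range[1] & fes$s <= s_range[2])
  zi <- if (is.null(z_range)) seq_along(fes$z)
        else which(fes$z >= z_range[1] & fes$z <= z_range[2])
  if (!length(si) || !length(zi)) stop("empty FES window")
  min(fes$values[si, zi])
}

#' Boltzmann-weighted free energy of an (S, Z) window
#'
#' `F_win = -kT ln sum_cells exp(-F_cell / kT)` over the window — the free
#' energy of the whole region rather than of its single lowest cell. For
#' comparing two estimates of the same surface (e.g. metadynamics vs a
#' histogram reference) this statistic is far less sensitive to
#' cell-level noise than the window minimum: sparse-count minima are
#' biased low, whereas the Boltzmann sum pools the full window weight.
#' Unvisited (`Inf`) cells contribute zero weight.
#'
#' @param fes An `"fes"` object.
#' @param s_range,z_range Inclusive ranges; `NULL` means no restriction.
#' @param temperature Temperature in K.
#' @return Window free energy in kcal/mol (same zero as the surface).
#' @export
fes_window_free_energy <- function(fes, s_range = NULL, z_range = NULL,
                                   temperature = 300) {
  si <- if (is.null(s_range)) seq_along(fes$s)
        else which(fes$s >= s_range[1] & fes$s <= s_range[2])
  zi <- if (is.null(z_range)) seq_along(fes$z)
        else which(fes$z >= z_range[1] & fes$z <= z_range[2])
  if (!length(si) || !length(zi)) stop("empty FES window")
  kT <- thermal_energy(temperature)
  w <- exp(-fes$values[si, zi] / kT)
  tot <- sum(w[is.finite(w)])
  if (tot <= 0) stop("window carries no Boltzmann weight")
  -kT * log(tot)
}

#' Brute-force FES from unbiased sampling
#'
#' Histogram estimate `F = -kT ln p(s, z)` on the same kind of grid as
#' [reconstruct_fes()], the independent reference for validating
#' metadynamics reconstructions on toy systems.
#'
#' @param s,z Sampled S and Z series from unbiased dynamics.
#' @param temperature Temperature in K.
#' @param grid List with `s`, `z` axis vectors (cell centres).
#' @return An `"fes"` object; unvisited cells are `Inf`.
#' @export
histogram_fes <- function(s, z, temperature, grid) {
  ds <- diff(grid$s[1:2]); dz <- diff(grid$z[1:2])
  si <- round((s - grid$s[1]) / ds) + 1
  zi <- round((z - grid$z[1]) / dz) + 1
  ok <- si >= 1 & si <= length(grid$s) & zi >= 1 & zi <= length(grid$z)
  counts <- matrix(0, length(grid$s), length(grid$z))
  tab <- table(factor(si[ok], levels = seq_along(grid$s)),
               factor(zi[ok], levels = seq_along(grid$z)))
  counts <- counts + as.matrix(tab)
  f <- -thermal_energy(temperature) * log(counts)
  f <- f - min(f[is.finite(f)])
  structure(list(s = grid$s, z = grid$z, values = f), class = "fes")
}
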