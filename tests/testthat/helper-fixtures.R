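# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately written with different algorithms than the package
# (grid searches, naive sums, union-find, quadrature) so each check is a true
# dual-route comparison.

conf1 <- function(x, y = 0, z = 0) configuration(matrix(c(x, y, z), 1, 3))

random_configuration <- function(n, groups = list(), sd = 1) {
  configuration(matrix(rnorm(3 * n, sd = sd), n, 3), groups = groups)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# Brute-force minimum RMSD by coarse-to-fine search over Euler angles,
# refined down to 0.2 degrees. Independent of the Kearsley eigenproblem.
rmsd_grid_oracle <- function(mobile, ref) {
  cm <- sweep(mobile, 2, colMeans(mobile))
  cr <- sweep(ref, 2, colMeans(ref))
  rmsd_of <- function(a, b, c) {
    sqrt(mean(rowSums((cm %*% t(euler_rot(a, b, c)) - cr)^2)))
  }
  best <- c(0, 0, 0)
  best_val <- Inf
  step <- 20 * pi / 180
  grid <- expand.grid(a = seq(0, 2 * pi, by = step),
                      b = seq(0, pi, by = step),
                      c = seq(0, 2 * pi, by = step))
  for (i in seq_len(nrow(grid))) {
    v <- rmsd_of(grid$a[i], grid$b[i], grid$c[i])
    if (v < best_val) { best_val <- v; best <- unlist(grid[i, ]) }
  }
  while (step > 0.2 * pi / 180) {
    step <- step / 4
    for (da in c(-2:2) * step) for (db in c(-2:2) * step)
      for (dc in c(-2:2) * step) {
        v <- rmsd_of(best[1] + da, best[2] + db, best[3] + dc)
        if (v < best_val) {
          best_val <- v
          best <- best + c(da, db, dc)
          # keep centre of refinement updated
        }
      }
  }
  best_val
}

# Naive direct-summation path CV (no log-sum-exp), msd via independent
# SVD-based (Kabsch) superposition.
kabsch_align <- function(mobile, ref) {
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  H <- t(sweep(mobile, 2, cm)) %*% sweep(ref, 2, cr)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  U <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(apply = function(x) sweep(x, 2, cm) %*% t(U) +
         matrix(cr, nrow(x), 3, byrow = TRUE))
}

msd_oracle <- function(a, b, align, disp) {
  if (length(align) >= 3) {
    fit <- kabsch_align(a[align, , drop = FALSE], b[align, , drop = FALSE])
    ap <- fit$apply(a[disp, , drop = FALSE])
  } else {
    ap <- a[disp, , drop = FALSE]
  }
  mean(rowSums((ap - b[disp, , drop = FALSE])^2))
}

pathcv_oracle <- function(config, fs) {
  P <- length(fs$frames)
  D <- vapply(fs$frames, function(fr)
    msd_oracle(config$coords, fr$coords, fs$align, fs$displace), numeric(1))
  w <- exp(-fs$lambda * D)
  list(s = sum(seq_len(P) * w) / sum(w), z = -log(sum(w)) / fs$lambda)
}

# Minimax (lowest connecting level) by threshold sweep + flood fill:
# independent of the Dijkstra implementation.
minimax_oracle <- function(v, from, to) {
  ns <- nrow(v); nz <- ncol(v)
  levels <- sort(unique(as.vector(v)))
  connected_at <- function(lev) {
    ok <- v <= lev
    if (!ok[from[1], from[2]] || !ok[to[1], to[2]]) return(FALSE)
    seen <- matrix(FALSE, ns, nz)
    queue <- list(from)
    seen[from[1], from[2]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (all(cur == to)) return(TRUE)
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii < 1 || ii > ns || jj < 1 || jj > nz) next
        if (seen[ii, jj] || !ok[ii, jj]) next
        seen[ii, jj] <- TRUE
        queue <- c(queue, list(c(ii, jj)))
      }
    }
    FALSE
  }
  for (lev in levels) if (connected_at(lev)) return(lev)
  Inf
}

# Union-find connected components over a thresholded distance matrix.
unionfind_clusters <- function(D, cutoff) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && D[i, j] <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Independent dihedral implementation: bio3d's torsion calculator.
dihedral_oracle <- function(p) {
  bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
}

# Boltzmann well populations / free energies by numerical quadrature for
# 1D potentials.
quad_free_energy <- function(vfun, lo, hi, temperature = 300) {
  kT <- pathmeta::thermal_energy(temperature)
  z <- integrate(function(x) exp(-vfun(x) / kT), lo, hi,
                 rel.tol = 1e-10)$value
  -kT * log(z)
}

# small deterministic double-well frameset along x shared by metadynamics
# tests: frames at -1.4, -1.2, ..., 1.4 (P = 15)
dw_frameset <- function() {
  frameset(lapply(seq(-1.4, 1.4, by = 0.2), conf1), NULL, 1)
}

# map the dw frameset S coordinate back to x
dw_s_to_x <- function(s) -1.4 + (s - 1) * 0.2

expect_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}
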