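test_that("coordination count limits: r = 0, r = r0, far field", {
  sp <- switching_params(3.5, 6, 16)
  expect_equal(coordination_count(c(0, 0, 0), matrix(c(0, 0, 0), 1, 3), sp),
               1)
  expect_equal(coordination_count(c(0, 0, 0), matrix(c(3.5, 0, 0), 1, 3),
                                  sp), 6 / 16, tolerance = 1e-6)
  expect_lt(coordination_count(c(0, 0, 0), matrix(c(30, 0, 0), 1, 3), sp),
            1e-5)
  expect_error(switching_params(3.5, 5, 16), "even")
  expect_error(switching_params(3.5, 16, 6), "m > n")
})

test_that("coordination matches the perturbed direct formula near r0", {
  set.seed(51)
  sp <- switching_params(3.5, 6, 16)
  waters <- matrix(rnorm(150, sd = 3), 50, 3)
  # put some waters exactly on the singular shell
  waters[1:5, ] <- waters[1:5, ] / sqrt(rowSums(waters[1:5, ]^2)) * 3.5
  direct <- function(p, w, eps) {
    r <- sqrt(colSums((t(w) - p)^2)) + eps
    u <- r / sp$r0
    sum((1 - u^sp$n) / (1 - u^sp$m))
  }
  got <- coordination_count(c(0, 0, 0), waters, sp)
  expect_equal(got, direct(c(0, 0, 0), waters, 1e-9), tolerance = 1e-6)
})

test_that("coordination is continuous and strictly decreasing across r0", {
  sp <- switching_params(3.5, 6, 16)
  r <- seq(0.5, 7, by = 0.005)
  vals <- vapply(r, function(ri)
    coordination_count(c(0, 0, 0), matrix(c(ri, 0, 0), 1, 3), sp),
    numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(max(abs(diff(vals))), 0.02) # no jump at the removable singularity
})

test_that("segment axis divides into the requested points", {
  ax <- segment_axis(c(0, 0, 0), c(0, 0, 5), n_slices = 10)
  expect_equal(nrow(ax$points), 11)
  expect_equal(ax$fractions, seq(0, 1, by = 0.1))
  expect_equal(ax$points[6, ], c(0, 0, 2.5))
  d <- sqrt(rowSums(diff(ax$points)^2))
  expect_true(all(abs(d - 0.5) < 1e-12)) # evenly spaced
})

test_that("hydration map: zero waters give a zero grid; bins average counts", {
  sp <- switching_params()
  conf <- configuration(matrix(rnorm(9), 3, 3),
                        groups = list(water_O = integer(0)))
  traj <- trajectory(list(conf, conf, conf))
  ax <- segment_axis(c(0, 0, 0), c(0, 0, 3), 10)
  hm <- hydration_map(traj, c(0.2, 0.3, 0.9), ax, sp, s_bin = 0.5)
  expect_true(all(hm == 0))
  expect_equal(dim(hm), c(11, 2)) # bins [0, 0.5) and [0.5, 1)
})

test_that("uniform bulk water matches the switching-integral expectation", {
  set.seed(52)
  sp <- switching_params(3.5, 6, 16)
  # uniform density in a big box around a short axis
  L <- 24; rho <- 1200 / L^3
  frames <- lapply(1:40, function(i) {
    configuration(matrix(runif(3600, -L / 2, L / 2), 1200, 3),
                  groups = list(water_O = 1:1200))
  })
  traj <- trajectory(frames)
  ax <- segment_axis(c(-1, 0, 0), c(1, 0, 0), 4)
  hm <- hydration_map(traj, rep(0.2, 40), ax, sp, s_bin = 0.5)
  # analytic: rho * int switching over space (radial quadrature)
  integrand <- function(r) {
    u <- r / sp$r0
    sw <- ifelse(abs(u - 1) < 1e-12, sp$n / sp$m,
                 (1 - u^sp$n) / (1 - u^sp$m))
    4 * pi * r^2 * sw
  }
  expected <- rho * integrate(integrand, 0, L / 2)$value
  expect_true(all(abs(hm - expected) / expected < 0.1))
})

test_that("pocket bottom is wetter with the ligand removed", {
  spec <- toy_pocket_spec(pocket_depth = 6, channel_length = 6,
                          n_solvent = 12, backdoor = TRUE)
  sys <- build_toy_pocket(spec)
  lig <- sys$configuration$groups$ligand_heavy
  p <- langevin_params(friction = 2, seed = 61)
  bound <- run_langevin(sys$potential, sys$configuration, p, 4e5,
                        record_stride = 200)
  # "removed": ligand held in the bulk section by an axial wall so it
  # cannot re-enter during the run
  gone <- sys$configuration
  gone$coords[lig, 3] <- gone$coords[lig, 3] + 7
  pot_u <- sys$potential
  pot_u$spec$z_lo_lig <- 6
  unbound <- run_langevin(pot_u, gone, p, 4e5, record_stride = 200)
  ax <- segment_axis(c(0, 0, -1.5), c(0, 0, 4), 10)
  sp <- switching_params()
  mean_bottom <- function(traj) {
    hm <- hydration_map(traj, rep(0.2, n_frames(traj)), ax, sp)
    hm[1, 1]
  }
  expect_gt(mean_bottom(unbound), mean_bottom(bound))
})

test_that("monitor_distance handles atoms, centroids and coincidence", {
  conf <- configuration(rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1),
                              c(-1, -1, -1)))
  traj <- trajectory(list(conf, conf))
  expect_equal(monitor_distance(traj, 1, 2, mode = "atom")$value, c(5, 5))
  expect_equal(monitor_distance(traj, 1, 2, mode = "centroid")$value,
               monitor_distance(traj, 1, 2, mode = "atom")$value)
  # centroid of atoms 3 and 4 is the origin -> coincides with atom 1
  expect_equal(monitor_distance(traj, 1, 3:4)$value, c(0, 0))
  expect_error(monitor_distance(traj, integer(0), 1), "non-empty")
})

test_that("dihedral monitor: cis 0, trans 180, and matches the oracle", {
  cis <- configuration(rbind(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0),
                             c(-1, 1, 0)))
  trans <- configuration(rbind(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0),
                               c(-1, -1, 0)))
  expect_equal(monitor_dihedral(trajectory(list(cis)), 1:4)$value, 0)
  expect_equal(abs(monitor_dihedral(trajectory(list(trans)), 1:4)$value),
               180)
  set.seed(53)
  for (rep in 1:6) {
    p <- matrix(rnorm(12), 4, 3)
    got <- monitor_dihedral(trajectory(list(configuration(p))), 1:4)$value
    expect_equal(got, as.numeric(dihedral_oracle(p)), tolerance = 1e-6)
  }
  line <- configuration(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)))
  expect_error(monitor_dihedral(trajectory(list(line)), 1:4), "collinear")
})

test_that("RMSD/RMSF: static and rigidly rotating trajectories give zero", {
  set.seed(54)
  base <- random_configuration(8)
  still <- trajectory(list(base, base, base))
  r <- rmsd_rmsf(still, 1:8)
  expect_equal(max(r$rmsd$value), 0, tolerance = 1e-7)
  expect_equal(max(r$rmsf), 0, tolerance = 1e-7)
  rotating <- trajectory(lapply(seq(0, 1, by = 0.2), function(th) {
    f <- base
    f$coords <- base$coords %*% t(rot_z(th)) + th
    f
  }))
  r2 <- rmsd_rmsf(rotating, 1:8)
  expect_equal(max(r2$rmsd$value), 0, tolerance = 1e-6)
})

test_that("RMSF of a sinusoidally oscillating atom is amplitude/sqrt(2)", {
  set.seed(55)
  cage <- random_configuration(6, sd = 3)
  a <- 0.8
  nf <- 10000
  frames <- lapply(seq_len(nf), function(i) {
    f <- cage
    f$coords <- rbind(cage$coords,
                      c(1 + a * sin(2 * pi * i / 97), 0, 0))
    f
  })
  traj <- trajectory(frames)
  r <- rmsd_rmsf(traj, 1:6, measure_selection = 7)
  expect_close(r$rmsf[[1]], a / sqrt(2), 0.02 * a)
})

test_that("catalytic competence is the conjunction of distance criteria", {
  mk_frame <- function(d_hyd, d_tyr, d_ser) {
    configuration(rbind(c(0, 0, 0),          # hydride donor (C4)
                        c(d_hyd, 0, 0),      # hydride acceptor (C11)
                        c(0, 5, 0),          # keto O
                        c(d_tyr, 5, 0),      # tyr O
                        c(0, 5 + d_ser, 0))) # ser O
  }
  roles <- list(hydride_donor = 1, hydride_acceptor = 2, keto_o = 3,
                tyr_o = 4, ser_o = 5)
  expect_true(is_catalytically_competent(mk_frame(4.0, 3.0, 3.2), roles))
  expect_false(is_catalytically_competent(mk_frame(4.0, 3.0, 3.8), roles))
  expect_false(is_catalytically_competent(mk_frame(4.6, 3.0, 3.2), roles))
  expect_error(is_catalytically_competent(mk_frame(4, 3, 3),
                                          roles[1:4]), "missing role")
  # sweep: predicate equals the conjunction of monitor_distance thresholds
  set.seed(56)
  for (rep in 1:20) {
    d <- runif(3, 2.5, 5.5)
    fr <- mk_frame(d[1], d[2], d[3])
    traj <- trajectory(list(fr))
    want <- monitor_distance(traj, 1, 2)$value <= 4.5 &&
      monitor_distance(traj, 3, 4)$value <= 3.5 &&
      monitor_distance(traj, 3, 5)$value <= 3.5
    expect_equal(as.logical(is_catalytically_competent(fr, roles)), want)
  }
})

test_that("single-linkage clustering equals union-find on the RMSD graph", {
  set.seed(57)
  base <- random_configuration(6, sd = 2)
  jitter_conf <- function(center, sd) {
    f <- base
    f$coords <- center + matrix(rnorm(18, sd = sd), 6, 3)
    f
  }
  tight1 <- lapply(1:4, function(i) jitter_conf(base$coords, 0.05))
  tight2 <- lapply(1:3, function(i) jitter_conf(base$coords + 5, 0.05))
  configs <- c(tight1, tight2)
  labels <- cluster_single_linkage(configs, NULL, 1:6, cutoff = 0.7)
  expect_equal(length(unique(labels)), 2)
  expect_equal(labels[1:4], rep(1L, 4)) # larger cluster labelled 1
  expect_equal(labels[5:7], rep(2L, 3))
  # identical configurations collapse to one cluster
  expect_equal(unique(cluster_single_linkage(rep(list(base), 5), NULL, 1:6,
                                             0.7)), 1L)
  # random set vs union-find oracle
  configs2 <- lapply(1:8, function(i) jitter_conf(base$coords, runif(1, 0, 1)))
  lab2 <- cluster_single_linkage(configs2, NULL, 1:6, cutoff = 0.9)
  D <- attr(lab2, "rmsd")
  oracle <- unionfind_clusters(D, 0.9)
  # same partition (labels may differ)
  expect_equal(length(unique(lab2)), length(unique(oracle)))
  for (k in unique(oracle))
    expect_equal(length(unique(lab2[oracle == k])), 1L)
})
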