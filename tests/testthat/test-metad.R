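test_that("bias_value has the constructed centre value and Gaussian tails", {
  h <- hill_log(0, s = 5, z = 1, height = 0.05, sigma_s = 0.15,
                sigma_z = 0.20)
  expect_equal(bias_value(5, 1, h), 0.05)
  expect_lt(bias_value(5 + 6 * 0.15, 1, h), 1e-7 * 0.05)
  expect_equal(bias_value(5, 1, h, t = 0), 0) # hills deposited at time >= t
  empty <- hill_log(numeric(0), numeric(0), numeric(0), numeric(0),
                    numeric(0), numeric(0))
  expect_equal(bias_value(1, 1, empty), 0)
})

test_that("bias_value equals a naive double-loop sum on random hill logs", {
  set.seed(21)
  h <- hill_log(sort(runif(100, 0, 50)), s = runif(100, 0, 10),
                z = runif(100, 0, 3), height = runif(100, 0.01, 0.2),
                sigma_s = 0.15, sigma_z = 0.2)
  pts <- cbind(runif(5, 0, 10), runif(5, 0, 3))
  for (i in seq_len(nrow(pts))) {
    naive <- 0
    for (k in seq_len(nrow(h)))
      naive <- naive + h$height[k] *
        exp(-(pts[i, 1] - h$s[k])^2 / (2 * h$sigma_s[k]^2)) *
        exp(-(pts[i, 2] - h$z[k])^2 / (2 * h$sigma_z[k]^2))
    expect_equal(bias_value(pts[i, 1], pts[i, 2], h), naive,
                 tolerance = 1e-12)
  }
})

test_that("analytic bias gradient matches finite differences", {
  set.seed(22)
  h <- hill_log(sort(runif(60, 0, 30)), s = runif(60, 0, 8),
                z = runif(60, 0, 2), height = 0.1, sigma_s = 0.15,
                sigma_z = 0.2)
  worst <- 0
  for (i in 1:20) {
    s0 <- runif(1, 0.5, 7.5); z0 <- runif(1, 0.2, 1.8)
    g <- bias_gradient(s0, z0, h)
    eps <- 1e-6
    fd <- c((bias_value(s0 + eps, z0, h) - bias_value(s0 - eps, z0, h)) /
              (2 * eps),
            (bias_value(s0, z0 + eps, h) - bias_value(s0, z0 - eps, h)) /
              (2 * eps))
    worst <- max(worst, max(abs(g - fd) / pmax(abs(fd), 1e-8)))
  }
  expect_lt(worst, 1e-4)
})

test_that("zero deposition rate reduces to plain Langevin dynamics bitwise", {
  dw <- double_well_1d(6, 2)
  fs <- dw_frameset()
  p <- langevin_params(seed = 33)
  run <- run_metadynamics(dw, conf1(-1), p, fs, metad_config(0),
                          max_steps = 5000, stop_on_recross = FALSE,
                          record_stride = 500, traj_stride = 500)
  ref <- run_langevin(dw, conf1(-1), p, 5000, record_stride = 500)
  expect_identical(run$trajectory$frames[[11]]$coords,
                   ref$frames[[11]]$coords)
  expect_equal(nrow(run$hills), 0)
})

test_that("hill bookkeeping: count and total height follow the schedule", {
  dw <- double_well_1d(6, 2)
  fs <- dw_frameset()
  mc <- metad_config(deposition_rate = 0.1, stride = 1)
  run <- run_metadynamics(dw, conf1(-1), langevin_params(seed = 5), fs, mc,
                          max_steps = 25000, stop_on_recross = FALSE)
  T_total <- 25000 * 0.002
  expect_equal(nrow(run$hills), floor(T_total / mc$stride))
  expect_equal(sum(run$hills$height), mc$deposition_rate * T_total,
               tolerance = 1e-9)
  expect_true(all(diff(run$hills$time) > 0))
  # determinism: same seed, same config -> identical log
  run2 <- run_metadynamics(dw, conf1(-1), langevin_params(seed = 5), fs, mc,
                           max_steps = 25000, stop_on_recross = FALSE)
  expect_identical(run$hills$s, run2$hills$s)
})

test_that("bias deposition accelerates well-to-well escape by > 10x", {
  dw <- double_well_1d(6, 2)
  fs <- dw_frameset()
  first_cross <- function(run) {
    i <- which(run$series$s > 11)[1]
    if (is.na(i)) Inf else run$series$time[i]
  }
  times <- vapply(17:19, function(sd) {
    p <- langevin_params(seed = sd)
    biased <- run_metadynamics(dw, conf1(-1), p, fs,
                               metad_config(1, 1, 0.5, 0.05),
                               max_steps = 2e6, stop_on_recross = FALSE,
                               record_stride = 50)
    unbiased <- run_metadynamics(dw, conf1(-1), p, fs, metad_config(0),
                                 max_steps = 4e6, stop_on_recross = FALSE,
                                 record_stride = 50)
    c(biased = first_cross(biased), unbiased = first_cross(unbiased))
  }, numeric(2))
  expect_lt(median(times["biased", ]) * 10, median(times["unbiased", ]))
})

test_that("engine grid bias forces track the analytic hill gradient", {
  set.seed(23)
  nh <- 150
  hs <- runif(nh, 2, 8); hz <- runif(nh, 0.2, 1.8); hh <- rep(0.1, nh)
  hills <- hill_log(seq_len(nh), hs, hz, hh, 0.3, 0.25)
  pts <- cbind(runif(30, 3, 7), runif(30, 0.5, 1.5))
  eng <- pathmeta:::.bias_grid_gradient_cpp(hs, hz, hh, 0.3, 0.25,
                                            0, 10, -0.5, 3, pts)
  scale <- max(abs(eng))
  for (i in seq_len(nrow(pts))) {
    g <- bias_gradient(pts[i, 1], pts[i, 2], hills)
    # bilinear interpolation on a sigma/10 grid: sub-percent of the
    # typical gradient magnitude
    expect_lt(max(abs(eng[i, ] - g)), 0.01 * scale)
  }
})

test_that("FES reconstruction conventions: empty log, single hill", {
  empty <- hill_log(numeric(0), numeric(0), numeric(0), numeric(0),
                    numeric(0), numeric(0))
  grid <- list(s = seq(0, 2, by = 0.1), z = seq(0, 2, by = 0.1))
  f0 <- reconstruct_fes(empty, grid = grid)
  expect_true(all(f0$values == 0))
  one <- hill_log(0, 1, 1, height = 0.3, sigma_s = 0.15, sigma_z = 0.2)
  f1 <- reconstruct_fes(one, grid = grid)
  # inverted Gaussian: minimum 0 at the centre, far field ~ h
  expect_equal(f1$values[which(f1$s == 1), which(f1$z == 1)], 0)
  expect_equal(max(f1$values), 0.3, tolerance = 1e-3)
})

test_that("FES estimate improves with simulation length on the double well", {
  dw <- double_well_1d(4, 2)
  fs <- dw_frameset()
  mc <- metad_config(0.1, 1, 0.4, 0.05)
  grid <- list(s = seq(2, 14, by = 0.2), z = seq(-0.1, 0.3, by = 0.02))
  x_of_s <- dw_s_to_x(grid$s)
  ref <- dw$analytic_free_energy(x_of_s)
  ref <- ref - min(ref)
  l1_at <- function(run, t) {
    fes <- reconstruct_fes(run$hills, t, grid)
    prof <- apply(fes$values, 1, min)
    prof <- prof - min(prof)
    mean(abs(prof - ref))
  }
  errs <- sapply(1:3, function(seed) {
    run <- run_metadynamics(dw, conf1(-1), langevin_params(seed = seed), fs,
                            mc, max_steps = 3e5, stop_on_recross = FALSE)
    Tend <- max(run$hills$time)
    vapply(Tend * c(0.25, 0.5, 0.75, 1), function(t) l1_at(run, t),
           numeric(1))
  })
  m <- rowMeans(errs)
  # mean L1 error against the analytic profile shrinks from early to late
  expect_lt(m[4], m[1])
  expect_lt(m[4], 0.6)
})

test_that("recrossing detection finds the first qualifying return", {
  expect_equal(detect_recrossing(c(3, 10, 18, 10, 4, 18, 3),
                                 c(1, 5), c(16, 18)), 4)
  expect_true(is.na(detect_recrossing(c(3, 10, 18), c(1, 5), c(16, 18))))
  expect_true(is.na(detect_recrossing(c(3, 10, 12), c(1, 5), c(16, 18))))
  expect_error(detect_recrossing(1:5, c(1, 5), c(4, 8)), "disjoint")
  # noisy series crossing several times: compare with an exhaustive scan
  set.seed(31)
  s <- c(2, cumsum(rnorm(400, 0, 1.2)) %% 20)
  got <- detect_recrossing(s, c(0, 4), c(16, 20))
  scan <- function(s) {
    seen_end <- FALSE
    left <- FALSE
    for (i in seq_along(s)) {
      if (!seen_end && s[i] >= 16 && s[i] <= 20) seen_end <- TRUE
      else if (seen_end && s[i] >= 0 && s[i] <= 4) return(i - 1)
    }
    NA_real_
  }
  expect_equal(got, scan(s))
})

test_that("metadynamics stops at the recrossing event", {
  dw <- double_well_1d(5, 2)
  fs <- dw_frameset()
  run <- run_metadynamics(dw, conf1(-1), langevin_params(seed = 11), fs,
                          metad_config(0.1, 1, 0.4, 0.05), max_steps = 4e6,
                          start_region = c(2, 4), end_region = c(12, 14))
  expect_false(is.na(run$recross_time))
  expect_lt(run$steps_done, 4e6)
})

test_that("hill logs round-trip through the PLUMED-style table", {
  h <- hill_log(c(1, 2, 3), s = c(1.1, 2.2, 3.3), z = c(0.1, 0.2, 0.3),
                height = 0.1, sigma_s = 0.15, sigma_z = 0.2)
  f <- tempfile(fileext = ".dat")
  write_hills(h, f)
  expect_match(readLines(f, n = 1), "^#! FIELDS")
  h2 <- read_hills(f)
  expect_equal(h2$s, h$s, tolerance = 1e-9)
  expect_equal(h2$height, h$height)
})
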