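test_that("schedule duration is extension over speed", {
  expect_equal(schedule_duration(
    smd_config(1, 2, speed = 0.005, target_extension = 7.5)), 1500)
  expect_equal(schedule_duration(
    smd_config(1, 2, speed = 0.005, target_extension = 0)), 0)
  expect_equal(schedule_duration(
    smd_config(1, 2, speed = 0.005, target_extension = 14)), 2800)
})

test_that("smd_config validates its inputs", {
  expect_error(smd_config(1, 2, force_constant = 0), "positive")
  expect_error(smd_config(1, 2, speed = -1), "positive")
  sys <- configuration(matrix(rnorm(9), 3, 3))
  lp <- linear_potential(1, n_atoms = 3)
  expect_error(run_smd(lp, sys, langevin_params(), smd_config(1:2, 2:3)),
               "disjoint")
})

# quasistatic pulls on a flat landscape do ~zero work
test_that("near-quasistatic pulling on a flat landscape gives ~zero work", {
  flat <- composite_potential(
    linear_potential(0, atom = 1, n_atoms = 2, k_perp = 100),
    harmonic_potential(100, n_atoms = 2, atoms = 2))
  start <- configuration(rbind(c(2, 0, 0), c(0, 0, 0)), masses = c(12, 1e7))
  cfg <- smd_config(1, 2, force_constant = 20, speed = 1e-3,
                    target_extension = 0.5)
  p <- langevin_params(friction = 20, seed = 6)
  w <- final_work(run_smd(flat, start, p, cfg, record_stride = 100))
  expect_lt(abs(w), 2 * thermal_energy(300))
})

test_that("pulling up a linear slope recovers the closed-form free energy", {
  g <- 2
  lin <- composite_potential(
    linear_potential(g, atom = 1, n_atoms = 2, k_perp = 100),
    harmonic_potential(50, n_atoms = 2, atoms = 2))
  start <- configuration(rbind(c(2, 0, 0), c(0, 0, 0)), masses = c(12, 1e7))
  cfg <- smd_config(1, 2, force_constant = 50, speed = 0.3,
                    target_extension = 3)
  works <- vapply(1:12, function(s)
    final_work(run_smd(lin, start, langevin_params(friction = 20, seed = s),
                       cfg, record_stride = 200, equilibrate = 20)),
    numeric(1))
  df <- g * 3
  expect_gte(mean(works), df)          # second law on the mean
  expect_lt(abs(mean(works) - df), 0.15 * df) # near-quasistatic regime
})

test_that("mean pocket-extraction work bounds the histogram free energy", {
  # shallow pocket so the unbiased oracle samples both states quickly
  sys <- build_toy_pocket(toy_pocket_spec(pocket_depth = 2, n_solvent = 0,
                                          channel_length = 5))
  lig <- sys$configuration$groups$ligand_heavy
  # fast pull: the dissipation dominates the statistical noise of the bound
  cfg <- smd_config("ligand_heavy", "pocket_bottom_ref", 20, 0.4,
                    target_extension = 6)
  works <- vapply(1:8, function(s)
    final_work(run_smd(sys$potential, sys$configuration,
                       langevin_params(seed = s), cfg, record_stride = 500)),
    numeric(1))
  # oracle: z-histogram free energy between equal-width start/end windows
  tr <- run_langevin(sys$potential, sys$configuration,
                     langevin_params(friction = 2, seed = 99), 4e6,
                     record_stride = 100)
  zc <- vapply(tr$frames, function(f) mean(f$coords[lig, 3]), numeric(1))
  kT <- thermal_energy(300)
  p_b <- mean(zc > -0.5 & zc < 1)
  p_u <- mean(zc > 4 & zc < 5.5)
  expect_gt(p_u, 0) # both states visited
  df_oracle <- -kT * log(p_u / p_b)
  expect_gte(mean(works), df_oracle)
})

test_that("work decreases with pulling speed (mean over seeds)", {
  g <- 2
  lin <- composite_potential(
    linear_potential(g, atom = 1, n_atoms = 2, k_perp = 100),
    harmonic_potential(50, n_atoms = 2, atoms = 2))
  start <- configuration(rbind(c(2, 0, 0), c(0, 0, 0)), masses = c(12, 1e7))
  mean_w <- vapply(c(1, 0.2, 0.04), function(v) {
    cfg <- smd_config(1, 2, force_constant = 50, speed = v,
                      target_extension = 3)
    mean(vapply(1:8, function(s)
      final_work(run_smd(lin, start, langevin_params(friction = 20, seed = s),
                         cfg, record_stride = 200, equilibrate = 20)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_w) < 0))
})

test_that("the guide tracks the moving centre at stiff force constants", {
  flat <- composite_potential(
    linear_potential(0, atom = 1, n_atoms = 2, k_perp = 100),
    harmonic_potential(100, n_atoms = 2, atoms = 2))
  start <- configuration(rbind(c(2, 0, 0), c(0, 0, 0)), masses = c(12, 1e7))
  k <- 500
  cfg <- smd_config(1, 2, force_constant = k, speed = 0.05,
                    target_extension = 3)
  rec <- run_smd(flat, start, langevin_params(seed = 3), cfg,
                 record_stride = 50)
  lag <- abs(rec$xi - rec$restraint_center)
  expect_lt(max(lag), 3 * sqrt(thermal_energy(300) / k) + 0.05)
})

test_that("work is non-decreasing where applied force and speed agree", {
  g <- 2
  lin <- composite_potential(
    linear_potential(g, atom = 1, n_atoms = 2, k_perp = 100),
    harmonic_potential(50, n_atoms = 2, atoms = 2))
  start <- configuration(rbind(c(2, 0, 0), c(0, 0, 0)), masses = c(12, 1e7))
  cfg <- smd_config(1, 2, force_constant = 50, speed = 0.05,
                    target_extension = 1)
  # on the integration grid each trapezoid increment is sign-definite
  rec <- run_smd(lin, start, langevin_params(seed = 8), cfg,
                 record_stride = 1)
  dw <- diff(rec$work)
  pos <- rec$force[-1] >= 0 & rec$force[-length(rec$force)] >= 0
  expect_true(all(dw[pos] >= 0))
})

test_that("lowest-work selection uses work, then force variation, then id", {
  mk_rec <- function(force, work, id) {
    r <- data.frame(time = seq_along(force), xi = 0, restraint_center = 0,
                    force = force, work = work)
    class(r) <- c("pull_record", class(r))
    attr(r, "run_id") <- id
    r
  }
  r1 <- mk_rec(c(0, 5, 0, 5), cumsum(c(0, 4, 4, 4.1)), 1)
  r2 <- mk_rec(c(0, 2, 1, 2), cumsum(c(0, 3, 3, 3.8)), 2)
  r3 <- mk_rec(c(0, 1, 1, 1), cumsum(c(0, 5, 5, 5)), 3)
  expect_equal(attr(select_lowest_work(list(r1, r2, r3)), "run_id"), 2)
  # tie on final work -> lower total variation wins
  r4 <- mk_rec(c(0, 5, 0, 5), c(0, 1, 2, 9.8), 4)
  r5 <- mk_rec(c(0, 2, 1, 2), c(0, 1, 2, 9.8), 5)
  expect_equal(attr(select_lowest_work(list(r4, r5)), "run_id"), 5)
  expect_error(select_lowest_work(list()), "no pull records")
})

test_that("five re-seeded pocket pulls select the run with minimal work", {
  sys <- build_toy_pocket(toy_pocket_spec(pocket_depth = 3, n_solvent = 0,
                                          channel_length = 5))
  cfg <- smd_config("ligand_heavy", "pocket_bottom_ref", 20, 0.05,
                    target_extension = 5)
  recs <- lapply(1:5, function(s)
    run_smd(sys$potential, sys$configuration, langevin_params(seed = s), cfg,
            run_id = s, record_stride = 500))
  works <- vapply(recs, final_work, numeric(1))
  expect_equal(final_work(select_lowest_work(recs)), min(works))
})

test_that("pull records round-trip through TSV", {
  r <- data.frame(time = 0:3, xi = c(1, 1.1, 1.3, 1.25),
                  restraint_center = seq(1, 1.3, by = 0.1),
                  force = c(0, 0.5, -0.2, 0.1), work = cumsum(c(0, 1, 1, 1)))
  class(r) <- c("pull_record", class(r))
  f <- tempfile(fileext = ".tsv")
  write_pull_record(r, f)
  r2 <- read_pull_record(f)
  expect_equal(r2$work, r$work)
  expect_equal(r2$xi, r$xi)
})
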