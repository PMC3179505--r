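# analytic two-Gaussian-well surface used across basin tests
two_well_fes <- function(d1 = 6, d2 = 3, s1 = 3, s2 = 9) {
  s <- seq(0, 12, by = 0.2)
  z <- seq(0, 4, by = 0.2)
  v <- outer(s, z, function(ss, zz)
    -d1 * exp(-((ss - s1)^2 / 2 + (zz - 2)^2 / 2)) -
      d2 * exp(-((ss - s2)^2 / 2 + (zz - 2)^2 / 2)))
  structure(list(s = s, z = z, values = v - min(v)), class = "fes")
}

test_that("two planted wells are found with their depth difference", {
  fes <- two_well_fes(6, 3)
  b <- find_basins(fes, min_depth = 1)
  expect_equal(nrow(b), 2)
  expect_equal(b$label, c("A", "B"))
  expect_close(b$s[1], 3, 0.21)
  expect_close(b$s[2], 9, 0.21)
  expect_close(basin_delta_g(b, "A", "B"), 3, 0.05)
  expect_equal(basin_delta_g(b, "A", "A"), 0)
  expect_error(basin_delta_g(b, "A", "Q"), "unknown")
})

test_that("a single well gives one basin; a flat surface none", {
  fes <- two_well_fes(5, 0)
  expect_equal(nrow(find_basins(fes, min_depth = 0.5)), 1)
  flat <- structure(list(s = 0:5, z = 0:5, values = matrix(0, 6, 6)),
                    class = "fes")
  expect_equal(nrow(find_basins(flat)), 0)
})

test_that("basin minima match an exhaustive local-minimum scan", {
  # construct a 3-well surface and compare against brute force
  s <- seq(0, 15, by = 0.25)
  z <- seq(0, 5, by = 0.25)
  v <- outer(s, z, function(ss, zz)
    -5 * exp(-((ss - 2)^2 + (zz - 2)^2) / 2) -
      4 * exp(-((ss - 7)^2 + (zz - 3)^2) / 2) -
      6 * exp(-((ss - 12)^2 + (zz - 1.5)^2) / 2))
  fes <- structure(list(s = s, z = z, values = v - min(v)), class = "fes")
  b <- find_basins(fes, min_depth = 1)
  # brute force: strict local minima over the 8-neighbourhood
  mins <- c()
  for (i in 2:(length(s) - 1)) for (j in 2:(length(z) - 1)) {
    patch <- fes$values[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (fes$values[i, j] == min(patch) && sum(patch == min(patch)) == 1)
      mins <- rbind(mins, c(s[i], z[j], fes$values[i, j]))
  }
  expect_equal(nrow(b), nrow(mins))
  expect_equal(sort(b$min_value), sort(mins[, 3]), tolerance = 1e-10)
})

test_that("shallow wrinkles merge into their spill basin", {
  s <- seq(0, 10, by = 0.2)
  z <- seq(0, 2, by = 0.2)
  v <- outer(s, z, function(ss, zz)
    -5 * exp(-(ss - 5)^2 / 8) + 0.3 * sin(3 * ss)) # wrinkled single well
  fes <- structure(list(s = s, z = z, values = v - min(v)), class = "fes")
  expect_equal(nrow(find_basins(fes, min_depth = 1)), 1)
  expect_gt(nrow(find_basins(fes, min_depth = 0.01)), 1)
})

test_that("barrier height recovers a planted ridge", {
  s <- seq(0, 10, by = 0.1)
  z <- seq(0, 2, by = 0.1)
  # two flat basins at 0 and 1 separated by a ridge of height 5 above the
  # deeper basin
  v <- outer(s, z, function(ss, zz)
    ifelse(ss < 4, 0, ifelse(ss > 6, 1, 5)))
  fes <- structure(list(s = s, z = z, values = v), class = "fes")
  b <- find_basins(fes, min_depth = 0.5)
  expect_equal(nrow(b), 2)
  expect_equal(barrier_height(b, "A", "B"), 5)
  expect_equal(barrier_height(b, "A", "A"), 0)
})

test_that("minimax barrier equals exhaustive threshold-flood search", {
  set.seed(41)
  for (rep in 1:3) {
    ns <- 8; nz <- 8
    v <- matrix(round(runif(ns * nz), 3), ns, nz)
    fes <- structure(list(s = seq_len(ns), z = seq_len(nz), values = v),
                     class = "fes")
    from <- c(1, 1); to <- c(ns, nz)
    got <- pathmeta:::minimax_level(v, from, to)
    want <- minimax_oracle(v, from, to)
    expect_equal(got, want)
  }
})

test_that("barrier asymmetry equals the basin depth difference", {
  fes <- two_well_fes(6, 3)
  b <- find_basins(fes, min_depth = 1)
  dab <- barrier_height(b, "A", "B")
  dba <- barrier_height(b, "B", "A")
  expect_equal(dab - dba, basin_delta_g(b, "A", "B"), tolerance = 1e-10)
})
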