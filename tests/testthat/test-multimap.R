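test_that("target maps: amplitude 0 is a flat sheet and masses are equal", {
  base <- gaussian_bump_field(16, 160, amplitude = 1, width = 30)
  maps <- build_target_maps(base, seq(0, 8, length.out = 4),
                            support_threshold = 0.3)
  masses <- vapply(maps$maps, sum, numeric(1))
  expect_equal(max(masses) / min(masses), 1, tolerance = 1e-6)
  # amplitude-0 map peaks at z = 0 in every support column
  m0 <- maps$maps[[1]]
  zs <- maps$z0 + (seq_len(dim(m0)[3]) - 1) * maps$dz
  support <- which(apply(m0, c(1, 2), max) > 0, arr.ind = TRUE)
  for (r in seq_len(min(nrow(support), 5))) {
    prof <- m0[support[r, 1], support[r, 2], ]
    expect_lt(abs(zs[which.max(prof)]), maps$dz)
  }
})

test_that("map voxels match a from-scratch Gaussian evaluation", {
  base <- gaussian_bump_field(12, 120, amplitude = 1, width = 25)
  amps <- c(0, 4, 8)
  s <- 2.5
  maps <- build_target_maps(base, amps, nz = 20, smoothing_sd = s,
                            support_threshold = 0)
  zs <- maps$z0 + (0:19) * maps$dz
  for (k in 1:3) for (i in c(1, 6)) for (j in c(3, 9)) {
    target <- amps[k] * base$values[i, j]
    expect_equal(maps$maps[[k]][i, j, ],
                 exp(-(zs - target)^2 / (2 * s^2)), tolerance = 1e-12)
  }
})

test_that("xi reduces to single-map and symmetric identities", {
  maps <- disjoint_mapset()
  # all points inside the support of map 2 only -> xi = label 2
  set.seed(1)
  pts <- cbind(x = runif(20, 20, 30), y = runif(20, 1, 54), z = runif(20, -8, 6))
  expect_equal(multimap_xi(pts, maps), 2)
  # equal mass in maps 1 and 2, none in 3 -> xi = 1.5
  pts2 <- rbind(cbind(5, 30, 0), cbind(25, 30, 0))
  expect_equal(multimap_xi(pts2, maps), 1.5)
  # outside every support -> undefined
  far <- cbind(30, 30, 100)
  expect_error(multimap_xi(far, maps), "outside the support")
})

test_that("xi matches an independent brute-force evaluation", {
  set.seed(7)
  base <- gaussian_bump_field(10, 100, amplitude = 1, width = 25)
  maps <- build_target_maps(base, c(0, 3, 6), nz = 16,
                            support_threshold = 0)
  pts <- cbind(runif(40, 0, 100), runif(40, 0, 100), runif(40, -5, 8))
  expect_equal(multimap_xi(pts, maps), oracle_xi(pts, maps),
               tolerance = 1e-10)
})

test_that("xi is bounded by the labels and invariant under map relabeling", {
  base <- gaussian_bump_field(12, 120, amplitude = 1, width = 25)
  maps <- build_target_maps(base, seq(0, 6, length.out = 5))
  set.seed(3)
  for (r in 1:10) {
    f <- height_field(matrix(rnorm(144, sd = 2), 12, 12), 10)
    xi <- multimap_xi(f, maps)
    expect_gte(xi, min(maps$labels))
    expect_lte(xi, max(maps$labels))
  }
  # permuting the (map, label) pairs together leaves xi unchanged: check
  # against the definition with permuted sums
  perm <- c(3, 1, 5, 2, 4)
  f <- height_field(matrix(rnorm(144, sd = 2), 12, 12), 10)
  d <- dim(f$values)
  xs <- (seq_len(d[1]) - 1) * f$spacing
  pts <- cbind(rep(xs, times = d[2]), rep(xs, each = d[1]),
               as.vector(f$values))
  S <- vapply(maps$maps, function(arr)
    sum(apply(pts, 1, function(p) oracle_interp(arr, p, maps$spacing,
                                                maps$origin, maps$z0,
                                                maps$dz))), numeric(1))
  expect_equal(multimap_xi(f, maps),
               sum(maps$labels[perm] * S[perm]) / sum(S[perm]),
               tolerance = 1e-12)
})

test_that("bias energy is zero at the centre, quadratic in k, exact in gradient", {
  base <- gaussian_bump_field(12, 120, amplitude = 1, width = 25)
  maps <- build_target_maps(base, c(0, 3, 6), support_threshold = 0.3)
  f <- height_field(2 * base$values, base$spacing)
  xi <- multimap_xi(f, maps)
  expect_equal(as.numeric(bias_energy(f, maps, center = xi,
                                      force_constant = 5)), 0)
  u1 <- as.numeric(bias_energy(f, maps, center = xi + 1, force_constant = 5))
  u2 <- as.numeric(bias_energy(f, maps, center = xi + 1, force_constant = 10))
  expect_equal(u2, 2 * u1)
  expect_equal(u1, 0.5 * 5 * 1^2, tolerance = 1e-10)
  # analytic gradient vs central finite differences
  u <- bias_energy(f, maps, center = xi + 1, force_constant = 5)
  g <- attr(u, "gradient")
  eps <- 1e-5
  set.seed(2)
  cells <- cbind(sample(12, 6, TRUE), sample(12, 6, TRUE))
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]
    fp <- f; fp$values[i, j] <- fp$values[i, j] + eps
    fm <- f; fm$values[i, j] <- fm$values[i, j] - eps
    fd <- (as.numeric(bias_energy(fp, maps, xi + 1, 5)) -
           as.numeric(bias_energy(fm, maps, xi + 1, 5))) / (2 * eps)
    if (abs(fd) > 1e-8)
      expect_equal(g[i, j], fd, tolerance = 1e-5)
    else
      expect_lt(abs(g[i, j] - fd), 1e-8)
  }
})

test_that("umbrella windows behave in the stiff and free limits", {
  base <- gaussian_bump_field(16, 160, amplitude = 1, width = 28)
  maps <- build_target_maps(base, seq(0, 10, length.out = 6))
  p <- helfrich_params(kappa = 15, grid_n = 16, box_l = 160, n_sweeps = 150,
                       seed = 6)
  # stiff spring pins xi at the centre
  stiff <- run_umbrella(p, maps, centers = 6, force_constant = 400,
                        burn_in = 50, seed = 2)
  expect_equal(mean(stiff[[1]]$series), 6, tolerance = 0.1)
  # near-zero bias reproduces the unbiased mean (long-run oracle)
  p2 <- helfrich_params(kappa = 15, grid_n = 16, box_l = 160, n_sweeps = 600,
                        seed = 6)
  free <- sample_helfrich(p2, umbrella_bias(maps, 5, 1e-9), burn_in = 50)
  unb <- sample_helfrich(p2)
  xi_unb <- vapply(unb, function(f) multimap_xi(f, maps), numeric(1))
  se <- sd(xi_unb) / sqrt(30)  # generous effective-sample allowance
  expect_lt(abs(mean(attr(free, "xi")) - mean(xi_unb)), 4 * se)
})

test_that("the production-scale window plan defaults to 61 windows", {
  plan <- default_window_plan(0, 10)
  expect_length(plan, 61)
  expect_equal(plan[1], 0)
  expect_equal(plan[61], 10)
})

test_that("map sets round-trip through OpenDX with labels intact", {
  base <- gaussian_bump_field(10, 100, amplitude = 1, width = 25)
  maps <- build_target_maps(base, c(0, 2, 4), nz = 12)
  dir <- tempfile("dx")
  man <- write_mapset_dx(maps, dir)
  back <- read_mapset_dx(man)
  expect_equal(back$labels, maps$labels)
  expect_equal(back$maps[[2]], maps$maps[[2]], tolerance = 1e-6)
  expect_equal(back$z0, maps$z0, tolerance = 1e-6)
})
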