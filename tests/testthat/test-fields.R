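test_that("far-field referencing removes rigid vertical offsets", {
  fr <- flat_frame(n = 400, box = 120, z_offset = 5)
  d <- midplane_deflection(list(fr), spacing = 10, far_field_radius = 40)
  expect_lt(max(abs(d$values), na.rm = TRUE), 1e-9)
  expect_equal(d$reference_level, 5, tolerance = 1e-9)
  # invariance: translating the whole bilayer in z changes nothing
  fr2 <- flat_frame(n = 400, box = 120, z_offset = -13)
  d2 <- midplane_deflection(list(fr2), spacing = 10, far_field_radius = 40)
  expect_equal(d$values, d2$values, tolerance = 1e-9)
})

test_that("deflection maps recover a known bump within the stated bound", {
  bf <- bump_frames(n_frames = 3, n = 900, box = 160, amplitude = 10,
                    width = 25, noise = 1, seed = 5)
  spacing <- 8
  d <- midplane_deflection(bf$frames, spacing = spacing,
                           far_field_radius = 60)
  # oracle: generator surface averaged per cell, referenced the same way
  n <- dim(d$values)
  xs <- (seq_len(n[1]) - 0.5) * spacing
  oracle <- outer(xs, xs, function(x, y) eval_height(bf$surface, x, y))
  dist <- sqrt(outer((xs - 80)^2, (xs - 80)^2, `+`))
  oracle <- oracle - mean(oracle[dist > 60])
  occ <- d$counts > 0
  rmse <- sqrt(mean((d$values[occ] - oracle[occ])^2))
  mean_counts <- mean(d$counts[occ])
  expect_lt(rmse, 1 / sqrt(mean_counts) + spacing / 2)
  expect_equal(max(d$values, na.rm = TRUE), 10, tolerance = 0.15 * 10)
})

test_that("thickness is insensitive to bending and tracks leaflet offsets", {
  # flat, zero noise: exactly 16 A
  fr <- flat_frame(n = 300, box = 100)
  th <- thickness_map(list(fr), spacing = 10)
  expect_equal(unique(round(as.vector(th$values[th$counts > 0]), 9)), 16)
  # draped on a 10 A bump: still 16 A (bending is not thinning)
  bf <- bump_frames(n_frames = 2, noise = 0, seed = 3)
  th2 <- thickness_map(bf$frames, spacing = 8)
  occ <- th2$counts > 0
  expect_equal(mean(th2$values[occ]), 16, tolerance = 0.2)
  expect_lt(diff(range(th2$values[occ])), 1.5)
  # upper leaflet shifted +2 A -> uniform 18 A
  fr3 <- flat_frame(n = 300, box = 100)
  up <- fr3$particles$leaflet == "upper"
  fr3$particles$z[up] <- fr3$particles$z[up] + 2
  th3 <- thickness_map(list(fr3), spacing = 10)
  expect_equal(unique(round(as.vector(th3$values[th3$counts > 0]), 9)), 18)
})

test_that("order parameter hits its closed-form limits", {
  fr <- flat_frame(n = 200, box = 100)  # generator tails run along z
  p2 <- order_parameter_map(list(fr), spacing = 20)
  expect_equal(unique(round(as.vector(
    p2$upper$values[p2$upper$counts > 0]), 9)), 1)
  # tails rotated into the membrane plane -> P2 = -0.5
  fr2 <- flat_frame(n = 200, box = 100)
  t <- fr2$particles$role == "tail"
  heads <- fr2$particles[fr2$particles$role == "head", ]
  hz <- heads$z[match(fr2$particles$lipid_id[t], heads$lipid_id)]
  hx <- heads$x[match(fr2$particles$lipid_id[t], heads$lipid_id)]
  off <- abs(fr2$particles$z[t] - hz)
  fr2$particles$z[t] <- hz
  fr2$particles$x[t] <- hx + off
  p2b <- order_parameter_map(list(fr2), spacing = 20)
  expect_equal(unique(round(as.vector(
    p2b$upper$values[p2b$upper$counts > 0]), 9)), -0.5)
  # isotropic orientations -> P2 near 0, matching a direct MC average
  set.seed(9)
  nl <- 4000
  z <- runif(nl, -1, 1); th <- runif(nl, 0, 2 * pi)
  r <- sqrt(1 - z^2); len <- 4
  x <- runif(nl, 0, 100); y <- runif(nl, 0, 100)
  parts <- rbind(
    data.frame(lipid_id = 1:nl, leaflet = "upper", role = "head",
               name = "HD", x = x, y = y, z = 8),
    data.frame(lipid_id = 1:nl, leaflet = "upper", role = "tail",
               name = "T1", x = x + len * r * cos(th),
               y = y + len * r * sin(th), z = 8 + len * z))
  friso <- membrane_frame(parts, box = c(100, 100, 120))
  p2c <- order_parameter_map(list(friso), spacing = 100)
  mc_oracle <- mean((3 * z^2 - 1) / 2)
  expect_equal(p2c$upper$values[1, 1], mc_oracle, tolerance = 1e-9)
  expect_lt(abs(p2c$upper$values[1, 1]), 0.05)
})

test_that("alkyl density normalizes to particles per cubic Angstrom", {
  fr <- flat_frame(n = 100, box = 100)
  pro <- data.frame(residue_id = 1, domain = "d", x = 50, y = 50, z = 0)
  dd <- alkyl_density(list(fr), protein = pro, cutoff = 10, voxel = 5)
  # single voxel sanity: a tail particle at a known spot
  one <- membrane_frame(
    data.frame(lipid_id = c(1, 1), leaflet = "upper",
               role = c("head", "tail"), name = c("HD", "T1"),
               x = c(52, 52), y = c(52, 52), z = c(8, 2)),
    box = c(100, 100, 120))
  d1 <- alkyl_density(list(one), protein = pro, cutoff = 10, voxel = 5)
  expect_equal(max(d1$density), 1 / 125)
  expect_equal(sum(d1$density > 0), 1)
  # nothing within cutoff -> all zero
  far_pro <- data.frame(residue_id = 1, domain = "d", x = 10, y = 10, z = 60)
  d2 <- alkyl_density(list(one), protein = far_pro, cutoff = 5, voxel = 5)
  expect_true(all(d2$density == 0))
  expect_error(alkyl_density(list(one), protein = NULL), "protein")
})

test_that("radial profiles reproduce constant and radial maps", {
  vals <- matrix(3.7, 20, 20)
  m <- scalar_map2d(vals, matrix(1, 20, 20), spacing = 5)
  pr <- radial_profile(m, origin = c(50, 50))
  expect_true(all(abs(pr$mean - 3.7) < 1e-12))
  # radially symmetric Gaussian map
  xs <- (1:20 - 0.5) * 5
  g <- outer(xs, xs, function(x, y) 10 * exp(-((x - 50)^2 + (y - 50)^2) / 800))
  mg <- scalar_map2d(g, matrix(1, 20, 20), spacing = 5)
  pg <- radial_profile(mg, origin = c(50, 50), bin_width = 5)
  expected <- 10 * exp(-pg$bins^2 / 800)
  close <- pg$bins < 40
  expect_lt(max(abs(pg$mean[close] - expected[close])), 0.6)
  expect_error(radial_profile(mg, origin = c(50, 50),
                              sector = c(0.1, 0.100001)), "sector")
})

test_that("shell exchange counts transitions exactly", {
  pro <- data.frame(residue_id = 1, domain = "d", x = 0, y = 0, z = 0)
  mk <- function(x1, x2) membrane_frame(
    data.frame(lipid_id = c(1, 2), leaflet = "upper", role = "head",
               name = "HD", x = c(x1, x2), y = 0, z = 0),
    box = c(100, 100, 50))
  # lipid 1: in,in,out,in  (2 transitions); lipid 2: out,in,in,in (1)
  frames <- list(mk(3, 40), mk(4, 5), mk(40, 6), mk(2, 3))
  ex <- shell_exchange(frames, protein = pro, cutoff = 10)
  expect_equal(ex$exchanges, 3)
  expect_equal(sum(ex$segments$state == "in" &
                   ex$segments$lipid_id == 1), 2)
  # static frames: zero exchanges
  ex0 <- shell_exchange(list(mk(3, 40), mk(3, 40)), protein = pro, cutoff = 10)
  expect_equal(ex0$exchanges, 0)
  # infinite cutoff: everyone always in shell, zero exchanges
  exinf <- shell_exchange(frames, protein = pro, cutoff = 1e6)
  expect_true(all(exinf$in_shell))
  expect_equal(exinf$exchanges, 0)
})

test_that("domain offsets are measured against the far-field mid-plane", {
  fr <- flat_frame(n = 400, box = 120)
  fr$protein <- data.frame(residue_id = 1:3, domain = "scaffold",
                           x = 60, y = 60, z = 3)
  off <- domain_z_offset(list(fr), spacing = 10, far_field_radius = 40)
  expect_equal(off$offset[off$domain == "scaffold"], 3, tolerance = 1e-9)
  # a 2 A rigid shift between two constructed states
  fr2 <- fr
  fr2$protein$z <- fr2$protein$z + 2
  off2 <- domain_z_offset(list(fr2), spacing = 10, far_field_radius = 40)
  expect_equal(off2$offset - off$offset, 2, tolerance = 1e-9)
})

test_that("replicate maps combine into exact means and standard errors", {
  mk <- function(v) scalar_map2d(matrix(v, 4, 4), matrix(5, 4, 4), spacing = 5)
  same <- replicate_stderr(list(mk(2), mk(2), mk(2)))
  expect_true(all(same$stderr == 0))
  # two replicates differing by a 2 A constant: se = sd/sqrt(2) = 1
  two <- replicate_stderr(list(mk(1), mk(3)))
  expect_true(all(abs(two$stderr - 1) < 1e-12))
  expect_true(all(two$values == 2))
  expect_equal(attr(two, "mean_stderr"), 1)
  # known per-cell variance is recovered within tolerance
  set.seed(4)
  reps <- lapply(1:40, function(i) mk(rnorm(16, mean = 5, sd = 2)))
  r <- replicate_stderr(reps)
  expect_equal(mean(r$stderr) * sqrt(40), 2, tolerance = 0.2)
})

test_that("empty cells are flagged, not silently zeroed", {
  # lipids confined to one quadrant leave the rest of the map empty
  fr <- flat_frame(n = 100, box = 100)
  keep <- fr$particles$x < 50 & fr$particles$y < 50
  ids <- unique(fr$particles$lipid_id[keep])
  fr$particles <- fr$particles[fr$particles$lipid_id %in% ids &
                                 fr$particles$x < 50 &
                                 fr$particles$y < 50, ]
  th <- thickness_map(list(fr), spacing = 10)
  expect_true(any(th$counts == 0))
  expect_true(all(is.na(th$values[th$counts == 0])))
})
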