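test_that("isolated sphere matches the closed form", {
  st <- data.frame(residue_id = 1, residue_type = "ALA", atom = "CA",
                   element = "C", x = 0, y = 0, z = 0, radius = 1.9)
  s <- sasa(st, probe = 1.4, n_points = 960)
  expect_equal(s$residue$area, 4 * pi * 3.3^2, tolerance = 1e-12)
  # and converges as the point count grows (deterministic point set)
  s2 <- sasa(st, probe = 1.4, n_points = 5000)
  expect_equal(s2$residue$area, 4 * pi * 3.3^2)
})

test_that("two overlapping spheres match the analytic cap formula", {
  mk <- function(d) data.frame(residue_id = 1:2, residue_type = "ALA",
                               atom = "CA", element = "C",
                               x = c(0, d), y = 0, z = 0, radius = 1.9)
  probe <- 1.4; R <- 1.9 + probe
  for (d in c(1.5, 3, 4.5, 6)) {
    s <- sasa(mk(d), probe = probe, n_points = 10000)
    exact <- two_sphere_exposed(R, R, d)
    expect_equal(s$atom$area[1], exact, tolerance = 0.01)
  }
})

test_that("fully enclosed atoms and distant atoms behave correctly", {
  enc <- generate_toy_protein(20, "clustered", seed = 1)
  s <- sasa(enc, n_points = 960)
  expect_equal(s$residue$area[s$residue$residue_id == 1], 0)
  # adding a distant non-overlapping atom changes no other area
  st <- generate_toy_protein(4, "linear", seed = 2)
  base_areas <- sasa(st, n_points = 960)$atom$area
  far <- st[1, ]; far$residue_id <- 99L; far$x <- 500
  with_far <- sasa(rbind(st, far), n_points = 960)$atom$area
  expect_equal(with_far[1:4], base_areas)
})

test_that("engine agrees with a random-point oracle on random structures", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 6
    st <- data.frame(residue_id = 1:n, residue_type = "ALA", atom = "CA",
                     element = "C",
                     x = runif(n, 0, 6), y = runif(n, 0, 6),
                     z = runif(n, 0, 6), radius = runif(n, 1.5, 2.0))
    eng <- sasa(st, probe = 1.4, n_points = 3000)$atom$area
    ora <- mc_sasa(st, probe = 1.4, n_mc = 30000, seed = rep)
    rel <- abs(eng - ora) / (4 * pi * (st$radius + 1.4)^2)
    expect_lt(max(rel), 0.02)
  }
})

test_that("membrane slab occludes exactly as the geometry dictates", {
  st <- data.frame(residue_id = 1, residue_type = "ALA", atom = "CA",
                   element = "C", x = 0, y = 0, z = 0, radius = 1.9)
  slab <- membrane_model("flat", half_thickness = 8, surface = 0)
  full <- 4 * pi * 3.3^2
  # centred in the slab: fully occluded
  expect_equal(occluded_sasa(st, slab)$residue$area, 0)
  # far above the slab: fully exposed
  st_hi <- st; st_hi$z <- 8 + 3.3 + 0.5
  expect_equal(occluded_sasa(st_hi, slab)$residue$area, full)
  # centred on the boundary: one hemisphere exposed
  st_b <- st; st_b$z <- 8
  expect_equal(occluded_sasa(st_b, slab, n_points = 960)$residue$area,
               full / 2, tolerance = 0.01)
  # occluded <= unoccluded element-wise on a random structure
  rnd <- generate_toy_protein(10, "linear", seed = 7)
  rnd$z <- rnd$z + seq(-10, 10, length.out = 10)
  a_occ <- occluded_sasa(rnd, slab)$residue$area
  a_free <- sasa(rnd)$residue$area
  expect_true(all(a_occ <= a_free + 1e-9))
})

test_that("deformed-membrane occlusion follows the height field", {
  surf <- gaussian_bump_field(16, 80, amplitude = -10, width = 15)
  dm <- membrane_model("deformed", half_thickness = 8, surface = surf)
  st <- data.frame(residue_id = 1, residue_type = "ALA", atom = "CA",
                   element = "C", x = 40, y = 40, z = 0, radius = 1.9)
  # at the bump centre the surface sits at -10, so z = 0 is near the upper
  # slab face (-10 + 8 = -2): mostly exposed
  a_def <- occluded_sasa(st, dm)$residue$area
  flat <- membrane_model("flat", 8, 0)
  a_flat <- occluded_sasa(st, flat)$residue$area
  expect_equal(a_flat, 0)
  expect_gt(a_def, 0.7 * 4 * pi * 3.3^2)
  expect_error(membrane_model("deformed", surface = NULL), "height_field")
})

test_that("flat counterpart aligns at the requested mask", {
  surf <- gaussian_bump_field(16, 80, amplitude = -10, width = 15)
  dm <- membrane_model("deformed", 8, surf)
  fl <- flat_from_deformed(dm)
  expect_equal(fl$surface, mean(surf$values))
  mask <- matrix(FALSE, 16, 16); mask[1:2, 1:2] <- TRUE
  fl2 <- flat_from_deformed(dm, mask)
  expect_equal(fl2$surface, mean(surf$values[1:2, 1:2]))
})

test_that("GXG reference areas dominate folded-context areas", {
  amax <- reference_area(c("ALA", "GLY", "ARG", "TRP"))
  expect_true(all(amax > 0))
  expect_gt(amax["ARG"], amax["ALA"])  # larger side chain, larger reference
  # A_max >= area of the same residue type in a crowded context
  crowd <- generate_toy_protein(14, "clustered", seed = 3,
                                residue_types = "ALA")
  crowd$atom <- "CB"; crowd$element <- "C"; crowd$radius <- 1.7
  areas <- sasa(crowd)$residue$area
  # compare against the single-sphere contribution bound via A_max engine
  expect_true(all(areas <= reference_area("ALA") + 4 * pi * 3.1^2))
  # override table takes precedence
  expect_equal(unname(reference_area("ALA", override = c(ALA = 123))), 123)
})
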