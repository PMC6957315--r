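don_p <- data.frame(kind = "protein", res = "ARG", atom = "NH1",
                    hydrogen = "HH11")
acc_l <- data.frame(kind = "lipid", res = "POPC", atom = "O13",
                    hydrogen = NA)

mk_protein <- function(xO = 0, with_h = TRUE) {
  p <- data.frame(residue_id = 105, residue_type = "ARG",
                  atom = "NH1", x = xO, y = 0, z = 0)
  if (with_h) p <- rbind(p, data.frame(residue_id = 105,
                                       residue_type = "ARG", atom = "HH11",
                                       x = xO + 1, y = 0, z = 0))
  p
}
mk_lipid <- function(x) data.frame(lipid_id = 7, lipid_type = "POPC",
                                   atom = "O13", x = x, y = 0, z = 0)

test_that("ideal collinear donor-H-acceptor geometry is detected", {
  ev <- detect_hbonds(mk_protein(0), mk_lipid(2.8), NULL, don_p, acc_l)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "direct")
  expect_equal(ev$residue_id, 105)
  # same pair at 6 A: nothing
  ev2 <- detect_hbonds(mk_protein(0), mk_lipid(6), NULL, don_p, acc_l)
  expect_equal(nrow(ev2), 0)
})

test_that("the angle criterion rejects bent geometries when H exists", {
  # acceptor placed behind the donor relative to H: D-H-A angle ~ 0
  p <- mk_protein(0)
  l <- mk_lipid(-1.5)
  ev <- detect_hbonds(p, l, NULL, don_p, acc_l,
                      criteria = hbond_criteria(max_DA_distance = 3.5,
                                                min_DHA_angle = 120))
  expect_equal(nrow(ev), 0)
  # hydrogen-free input falls back to distance-only, with a message
  expect_message(
    ev2 <- detect_hbonds(mk_protein(0, with_h = FALSE), mk_lipid(2.8),
                         NULL, don_p, acc_l),
    "distance-only")
  expect_equal(nrow(ev2), 1)
})

test_that("a single water bridges a side chain and a lipid as one mediated event", {
  p <- mk_protein(0)
  l <- mk_lipid(6)   # too far for a direct bond
  w <- data.frame(water_id = 1, atom = "OW", x = 3, y = 0, z = 0)
  ev <- detect_hbonds(p, l, w, don_p, acc_l)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "mediated")
  expect_equal(ev$water_id, 1)
  # direct and mediated are disjoint: at direct distance the pair is direct
  w2 <- data.frame(water_id = 1, atom = "OW", x = 1.4, y = 0.5, z = 0)
  ev2 <- detect_hbonds(mk_protein(0), mk_lipid(2.8), w2, don_p, acc_l)
  expect_equal(sort(unique(ev2$type)), "direct")
})

test_that("unannotated polar residues trigger a named error", {
  p <- rbind(mk_protein(0),
             data.frame(residue_id = 230, residue_type = "LYS",
                        atom = "NZ", x = 20, y = 0, z = 0))
  expect_error(detect_hbonds(p, mk_lipid(2.8), NULL, don_p, acc_l), "LYS")
})

test_that("occupancy counts each frame once regardless of event multiplicity", {
  ev_all <- do.call(rbind, lapply(1:10, function(f)
    detect_hbonds(mk_protein(0), mk_lipid(2.8), NULL, don_p, acc_l,
                  frame = f)))
  occ <- occupancy(ev_all, 10)
  expect_equal(occ$occupancy_direct, 1.0)
  # events in 3 of 10 frames
  ev3 <- do.call(rbind, lapply(c(2, 5, 9), function(f)
    detect_hbonds(mk_protein(0), mk_lipid(2.8), NULL, don_p, acc_l,
                  frame = f)))
  expect_equal(occupancy(ev3, 10)$occupancy_direct, 0.3)
  # two lipids bonded to the same residue in one frame still count once
  two <- rbind(mk_lipid(2.8),
               data.frame(lipid_id = 8, lipid_type = "POPC", atom = "O13",
                          x = 0, y = 2.8, z = 0))
  # collinearity fails for the second lipid with the H at +x; drop angle
  evtwo <- detect_hbonds(mk_protein(0, with_h = FALSE), two, NULL,
                         don_p, acc_l)
  expect_equal(nrow(evtwo), 2)
  expect_equal(occupancy(evtwo, 5)$occupancy_direct, 0.2)
})

test_that("occupancy is monotone in the distance criterion", {
  frames_at <- function(maxd) {
    ev <- do.call(rbind, lapply(1:6, function(f)
      detect_hbonds(mk_protein(0), mk_lipid(2.6 + 0.2 * f), NULL,
                    don_p, acc_l,
                    criteria = hbond_criteria(max_DA_distance = maxd),
                    frame = f)))
    if (nrow(ev)) occupancy(ev, 6)$occupancy_direct else 0
  }
  occs <- vapply(c(2.9, 3.3, 3.7, 4.1), frames_at, numeric(1))
  expect_true(all(diff(occs) >= 0))
})
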