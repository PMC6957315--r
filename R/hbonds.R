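#' Geometric hydrogen-bond criteria
#'
#' Conventional donor-acceptor geometry: D-A distance at most
#' `max_DA_distance` and, when explicit hydrogens are available, a D-H-A
#' angle of at least `min_DHA_angle`. Water-mediated bridges apply the same
#' criteria on both legs, with `water_link_distance` as the leg distance
#' cut-off.
#'
#' @param max_DA_distance Donor-acceptor distance cut-off, Angstrom.
#' @param min_DHA_angle Minimum donor-hydrogen-acceptor angle, degrees.
#' @param water_link_distance Leg distance for water bridges, Angstrom.
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_DA_distance = 3.5, min_DHA_angle = 120,
                           water_link_distance = 3.5) {
  stopifnot(max_DA_distance > 0, water_link_distance > 0,
            min_DHA_angle > 0, min_DHA_angle <= 180)
  structure(list(max_DA_distance = max_DA_distance,
                 min_DHA_angle = min_DHA_angle,
                 water_link_distance = water_link_distance),
            class = "hbond_criteria")
}

# one leg: do donor atom D (with optional H) and acceptor A H-bond?
hb_leg <- function(D, H, A, max_d, min_ang) {
  d <- sqrt(sum((D - A)^2))
  if (d > max_d) return(FALSE)
  if (is.null(H) || anyNA(H)) return(TRUE)   # distance-only mode
  v1 <- D - H; v2 <- A - H
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ang >= min_ang
}

annotate_atoms <- function(atoms, res_col, table, kind) {
  tb <- table[table$kind == kind, , drop = FALSE]
  key_a <- paste(atoms[[res_col]], atoms$atom)
  key_t <- paste(tb$res, tb$atom)
  idx <- match(key_a, key_t)
  hit <- !is.na(idx)
  out <- atoms[hit, , drop = FALSE]
  if ("hydrogen" %in% names(tb)) out$hydrogen <- tb$hydrogen[idx[hit]]
  out
}

atom_xyz <- function(df, i) c(df$x[i], df$y[i], df$z[i])

find_hydrogen <- function(atoms, group_col, group_val, hname) {
  if (is.na(hname) || !nzchar(hname)) return(NULL)
  j <- which(atoms[[group_col]] == group_val & atoms$atom == hname)
  if (!length(j)) return(NULL)
  atom_xyz(atoms, j[1])
}

#' Detect direct and water-mediated protein-lipid hydrogen bonds
#'
#' A direct event is a protein-lipid donor/acceptor pair meeting the
#' distance (and, when the donor's hydrogen exists in the structure, angle)
#' criteria; a mediated event is a single water molecule H-bonded to both a
#' protein side chain and a lipid in the same frame. When no hydrogen atoms
#' exist at all (coarse-grained input) the angle criterion is skipped with
#' a message.
#'
#' Donor and acceptor annotations are data.frames keyed by residue/molecule
#' type and atom name, with columns `kind` ("protein", "lipid", "water"),
#' `res`, `atom`, and for donors `hydrogen` (name of the bonded H; NA for
#' distance-only). Every polar protein residue type present in the
#' structure must be covered by at least one annotation row, otherwise an
#' error lists the unannotated residues.
#'
#' @param protein data.frame: residue_id, residue_type, atom, x, y, z.
#' @param lipid data.frame: lipid_id, lipid_type, atom, x, y, z.
#' @param water Optional data.frame: water_id, atom, x, y, z.
#' @param donors,acceptors Annotation data.frames (see Details).
#' @param criteria An [hbond_criteria()].
#' @param frame Frame index recorded in the events.
#' @return data.frame of events: frame, residue_id, residue_type, lipid_id,
#'   type ("direct"/"mediated"), water_id (NA for direct).
#' @export
detect_hbonds <- function(protein, lipid, water = NULL, donors, acceptors,
                          criteria = hbond_criteria(), frame = 1L) {
  stopifnot(is.data.frame(donors), is.data.frame(acceptors))
  polar <- unique(protein$residue_type[grepl("^[NO]", protein$atom) &
                                       !protein$atom %in% c("N", "O")])
  covered <- unique(c(donors$res[donors$kind == "protein"],
                      acceptors$res[acceptors$kind == "protein"]))
  missing <- setdiff(polar, covered)
  if (length(missing))
    stop("protein residue type(s) without donor/acceptor annotation: ",
         paste(missing, collapse = ", "))
  has_h <- any(grepl("^H", protein$atom)) || any(grepl("^H", lipid$atom))
  if (!has_h) message("no hydrogen atoms found; using distance-only criteria")

  pd <- annotate_atoms(protein, "residue_type", donors, "protein")
  pa <- annotate_atoms(protein, "residue_type", acceptors, "protein")
  ld <- annotate_atoms(lipid, "lipid_type", donors, "lipid")
  la <- annotate_atoms(lipid, "lipid_type", acceptors, "lipid")

  events <- list()
  add <- function(rid, rtype, lid, type, wid = NA)
    events[[length(events) + 1L]] <<- data.frame(
      frame = frame, residue_id = rid, residue_type = rtype,
      lipid_id = lid, type = type, water_id = wid)

  crit_d <- criteria$max_DA_distance
  crit_a <- criteria$min_DHA_angle
  # direct: protein donor -> lipid acceptor
  for (i in seq_len(nrow(pd))) for (j in seq_len(nrow(la))) {
    H <- find_hydrogen(protein, "residue_id", pd$residue_id[i],
                       if ("hydrogen" %in% names(pd)) pd$hydrogen[i] else NA)
    if (hb_leg(atom_xyz(pd, i), H, atom_xyz(la, j), crit_d, crit_a))
      add(pd$residue_id[i], pd$residue_type[i], la$lipid_id[j], "direct")
  }
  # direct: lipid donor -> protein acceptor
  for (i in seq_len(nrow(ld))) for (j in seq_len(nrow(pa))) {
    H <- find_hydrogen(lipid, "lipid_id", ld$lipid_id[i],
                       if ("hydrogen" %in% names(ld)) ld$hydrogen[i] else NA)
    if (hb_leg(atom_xyz(ld, i), H, atom_xyz(pa, j), crit_d, crit_a))
      add(pa$residue_id[j], pa$residue_type[j], ld$lipid_id[i], "direct")
  }
  # water-mediated: one water bridging a protein side chain and a lipid
  if (!is.null(water) && nrow(water)) {
    wl <- criteria$water_link_distance
    wo <- water[grepl("^O", water$atom), , drop = FALSE]
    prot_sites <- rbind(pd[, c("residue_id", "residue_type", "x", "y", "z")],
                        pa[, c("residue_id", "residue_type", "x", "y", "z")])
    lip_sites <- rbind(ld[, c("lipid_id", "x", "y", "z")],
                       la[, c("lipid_id", "x", "y", "z")])
    for (w in seq_len(nrow(wo))) {
      W <- atom_xyz(wo, w)
      pd2 <- (prot_sites$x - W[1])^2 + (prot_sites$y - W[2])^2 +
        (prot_sites$z - W[3])^2
      ld2 <- (lip_sites$x - W[1])^2 + (lip_sites$y - W[2])^2 +
        (lip_sites$z - W[3])^2
      pi_ok <- which(pd2 <= wl^2)
      li_ok <- which(ld2 <= wl^2)
      for (a in pi_ok) for (b in li_ok)
        add(prot_sites$residue_id[a], prot_sites$residue_type[a],
            lip_sites$lipid_id[b], "mediated", wo$water_id[w])
    }
  }
  if (!length(events))
    return(data.frame(frame = integer(), residue_id = integer(),
                      residue_type = character(), lipid_id = integer(),
                      type = character(), water_id = integer()))
  out <- do.call(rbind, events)
  # a pair counted direct is not additionally counted mediated
  if (any(out$type == "mediated")) {
    dk <- paste(out$residue_id, out$lipid_id)[out$type == "direct"]
    drop <- out$type == "mediated" & paste(out$residue_id, out$lipid_id) %in% dk
    out <- out[!drop, , drop = FALSE]
  }
  unique(out)
}

#' Per-side-chain interaction occupancy
#'
#' Fraction of frames in which each residue has at least one qualifying
#' lipid interaction; multiple simultaneous events in a frame count once.
#' Direct and water-mediated occupancies are reported separately and
#' combined.
#'
#' @param events Event data.frame from [detect_hbonds()] (possibly several
#'   frames row-bound).
#' @param n_frames Total number of frames analysed.
#' @return data.frame: residue_id, residue_type, occupancy_direct,
#'   occupancy_mediated, occupancy_any (all in [0, 1]).
#' @export
occupancy <- function(events, n_frames) {
  stopifnot(n_frames >= 1)
  if (!nrow(events))
    return(data.frame(residue_id = integer(), residue_type = character(),
                      occupancy_direct = numeric(),
                      occupancy_mediated = numeric(),
                      occupancy_any = numeric()))
  res <- unique(events[, c("residue_id", "residue_type")])
  res <- res[order(res$residue_id), ]
  frac <- function(rid, type) {
    sel <- events$residue_id == rid
    if (!is.null(type)) sel <- sel & events$type == type
    length(unique(events$frame[sel])) / n_frames
  }
  out <- data.frame(
    residue_id = res$residue_id, residue_type = res$residue_type,
    occupancy_direct = vapply(res$residue_id, frac, 0, type = "direct"),
    occupancy_mediated = vapply(res$residue_id, frac, 0, type = "mediated"),
    occupancy_any = vapply(res$residue_id, frac, 0, type = NULL))
  rownames(out) <- NULL
  out
}
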