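#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Classic point-sampling SASA: each atom is expanded by the probe radius
#' and covered with a deterministic Fibonacci-sphere point set; a point is
#' exposed when it lies inside no neighbouring expanded sphere. The exposed
#' area of an atom is 4*pi*(r + probe)^2 times its unoccluded point
#' fraction; residue areas are atom sums. The Fibonacci point set makes the
#' computation deterministic - no RNG is involved.
#'
#' @param structure A `structure_atoms` data.frame (columns residue_id,
#'   residue_type, atom, element, x, y, z, radius).
#' @param probe Probe radius, Angstrom (default 1.4, a water-sized probe).
#' @param n_points Sphere points per atom (>= 100; default 960).
#' @param membrane Optional [membrane_model()]: surface points inside the
#'   membrane slab are counted occluded (solvent excluded by the bilayer).
#' @return List with `atom` (data.frame: per-atom area, Angstrom^2) and
#'   `residue` (data.frame: residue_id, residue_type, area).
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960, membrane = NULL) {
  stopifnot(probe >= 0, n_points >= 100)
  st <- as.data.frame(structure)
  n <- nrow(st)
  if (!n) stop("empty structure")
  if (any(st$radius <= 0)) stop("radii must be > 0")
  xyz <- as.matrix(st[, c("x", "y", "z")])
  # duplicate-position warning: identical atoms occlude each other entirely
  if (n > 1) {
    d0 <- stats::dist(xyz)
    if (any(d0 < 1e-6))
      warning("overlapping identical atom positions; areas computed as-is")
  }
  pts <- fibonacci_sphere(n_points)
  rext <- st$radius + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * rext[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    dij2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(dij2 < (rext + rext[i])^2 & seq_len(n) != i)
    for (j in nb) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > rext[j]^2
      if (!any(exposed)) break
    }
    if (!is.null(membrane) && any(exposed)) {
      inside <- membrane_contains(membrane, p[exposed, , drop = FALSE])
      exposed[exposed] <- !inside
    }
    areas[i] <- 4 * pi * rext[i]^2 * mean(exposed)
  }
  atom <- data.frame(residue_id = st$residue_id,
                     residue_type = st$residue_type,
                     atom = st$atom, area = areas)
  res <- stats::aggregate(area ~ residue_id + residue_type, atom, sum)
  res <- res[order(res$residue_id), c("residue_id", "residue_type", "area")]
  rownames(res) <- NULL
  list(atom = atom, residue = res)
}

# Deterministic quasi-uniform unit-sphere point set.
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * i
  cbind(r * cos(th), r * sin(th), z)
}

#' Membrane slab model for SASA occlusion
#'
#' The solvent-excluded region of the bilayer: all points with
#' `|z - surface(x, y)| <= half_thickness`. In `flat` mode the surface is a
#' constant z level; in `deformed` mode it is a `height_field`.
#'
#' @param mode "flat" or "deformed".
#' @param half_thickness Half the hydrophobic width, Angstrom (default 8,
#'   i.e. a 16 Angstrom slab).
#' @param surface Flat mode: numeric z level (default 0). Deformed mode: a
#'   `height_field` (required).
#' @return Object of class `membrane_model`.
#' @export
membrane_model <- function(mode = c("flat", "deformed"), half_thickness = 8,
                           surface = if (mode == "flat") 0 else NULL) {
  mode <- match.arg(mode)
  stopifnot(half_thickness > 0)
  if (mode == "deformed" && !inherits(surface, "height_field"))
    stop("deformed mode requires a height_field surface")
  if (mode == "flat" && !is.numeric(surface))
    stop("flat mode requires a numeric z level")
  structure(list(mode = mode, half_thickness = half_thickness,
                 surface = surface), class = "membrane_model")
}

# TRUE for points inside the membrane slab.
membrane_contains <- function(model, pts) {
  z0 <- if (model$mode == "flat") model$surface
        else eval_height(model$surface, pts[, 1], pts[, 2])
  abs(pts[, 3] - z0) <= model$half_thickness
}

#' Flat membrane aligned to a deformed surface
#'
#' Builds the flat counterpart of a deformed membrane: same half-thickness,
#' level set to the mean deformed-surface height over an alignment mask
#' (e.g. the cells under an anchoring scaffold domain); with no mask, the
#' whole surface is averaged.
#'
#' @param deformed A deformed [membrane_model()].
#' @param alignment_mask Optional logical matrix over the surface grid.
#' @return A flat `membrane_model`.
#' @export
flat_from_deformed <- function(deformed, alignment_mask = NULL) {
  stopifnot(inherits(deformed, "membrane_model"), deformed$mode == "deformed")
  v <- deformed$surface$values
  lvl <- if (is.null(alignment_mask)) mean(v) else {
    if (!identical(dim(alignment_mask), dim(v)))
      stop("alignment mask must match the surface grid")
    mean(v[alignment_mask])
  }
  membrane_model("flat", deformed$half_thickness, lvl)
}

#' SASA with membrane-slab occlusion
#'
#' Identical to [sasa()] but counts surface points lying inside the
#' membrane's solvent-excluded slab as occluded. A_flat and A_bent of the
#' solvation ledger are this quantity under the flat and deformed membrane
#' models respectively.
#'
#' @inheritParams sasa
#' @param membrane A [membrane_model()].
#' @return Same shape as [sasa()].
#' @export
occluded_sasa <- function(structure, membrane, probe = 1.4, n_points = 960) {
  if (!inherits(membrane, "membrane_model"))
    stop("membrane must be a membrane_model")
  sasa(structure, probe = probe, n_points = n_points, membrane = membrane)
}

# -- GXG reference areas ----------------------------------------------------

# Side-chain heavy-atom element sequences for the standard residues. The
# template places them as an extended zigzag off CB: a synthetic geometry,
# adequate because A_max only serves as the engine-consistent normalizer.
side_chain_elements <- list(
  ALA = "C", ARG = c("C","C","C","N","C","N","N"), ASN = c("C","C","O","N"),
  ASP = c("C","C","O","O"), CYS = c("C","S"), GLN = c("C","C","C","O","N"),
  GLU = c("C","C","C","O","O"), GLY = character(),
  HIS = c("C","C","N","C","C","N"), ILE = c("C","C","C","C"),
  LEU = c("C","C","C","C"), LYS = c("C","C","C","C","N"),
  MET = c("C","C","S","C"), PHE = c("C","C","C","C","C","C","C"),
  PRO = c("C","C","C"), SER = c("C","O"), THR = c("C","O","C"),
  TRP = c("C","C","C","C","N","C","C","C","C","C"),
  TYR = c("C","C","C","C","C","C","C","O"), VAL = c("C","C","C"))

# Build one residue's atoms at a backbone offset along x.
template_residue <- function(type, residue_id, x_off) {
  bb <- data.frame(
    atom = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    x = x_off + c(0, 1.46, 2.45, 2.75),
    y = c(0, 0.55, -0.35, -1.55), z = 0)
  sc_el <- side_chain_elements[[type]]
  if (is.null(sc_el)) stop("unknown residue type: ", type)
  sc <- NULL
  if (length(sc_el)) {
    k <- seq_along(sc_el)
    sc <- data.frame(
      atom = paste0("S", k), element = sc_el,
      x = x_off + 1.46 + 0.45 * ((k %% 2) - 0.5),
      y = 0.55 + 1.35 * k,
      z = 0.35 * ((k %/% 2) %% 2 - 0.5))
  }
  out <- rbind(bb, sc)
  out$residue_id <- residue_id
  out$residue_type <- type
  out$radius <- element_radius(out$element)
  out[, c("residue_id", "residue_type", "atom", "element",
          "x", "y", "z", "radius")]
}

#' Extended GXG tripeptide template
#'
#' Gly-X-Gly heavy-atom template used to compute the maximal-exposure
#' reference area A_max of residue type X with the same SASA engine and
#' probe as the folded-structure areas. The geometry is synthetic (extended
#' backbone, zigzag side chain) and documented as such.
#'
#' @param x_type 3-letter residue type of the central residue.
#' @return A `structure_atoms` data.frame of the 3 residues.
#' @export
gxg_template <- function(x_type) {
  df <- rbind(template_residue("GLY", 1L, 0),
              template_residue(toupper(x_type), 2L, 3.8),
              template_residue("GLY", 3L, 7.6))
  class(df) <- c("structure_atoms", "data.frame")
  df
}

.amax_cache <- new.env(parent = emptyenv())

#' Maximal-exposure reference area A_max
#'
#' SASA of residue X fully exposed in an extended GXG tripeptide, computed
#' with the same engine settings. Values are cached per (type, probe,
#' n_points). An override table (named numeric vector, Angstrom^2) takes
#' precedence when supplied.
#'
#' @param residue_type 3-letter code(s).
#' @param probe,n_points Engine settings, as in [sasa()].
#' @param override Optional named numeric vector of A_max values.
#' @return Named numeric vector of areas, Angstrom^2.
#' @export
reference_area <- function(residue_type, probe = 1.4, n_points = 960,
                           override = NULL) {
  residue_type <- toupper(residue_type)
  vapply(residue_type, function(tp) {
    if (!is.null(override) && tp %in% names(override))
      return(unname(override[tp]))
    key <- sprintf("%s_%g_%d", tp, probe, n_points)
    if (!is.null(.amax_cache[[key]])) return(.amax_cache[[key]])
    s <- sasa(gxg_template(tp), probe = probe, n_points = n_points)
    a <- s$residue$area[s$residue$residue_id == 2L]
    .amax_cache[[key]] <- a
    a
  }, numeric(1))
}
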