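#' Bilayer generation parameters
#'
#' Defines a synthetic two-leaflet bilayer of labeled lipids. The default
#' half-thickness of 8 Angstrom gives a 16 Angstrom hydrophobic slab, the
#' reference width used by the membrane-occlusion model; systems on the scale
#' of the simulations this emulates hold ~7500 lipids in a ~500 x 500
#' Angstrom box.
#'
#' @param lipids_per_leaflet Lipids in each leaflet (> 0).
#' @param box_xy Length-2 (or scalar) box side lengths, Angstrom.
#' @param half_thickness Head-surface distance from the mid-plane, Angstrom.
#' @param beads_per_lipid Particles per lipid: one head plus >= 1 tail beads.
#' @param vertical_noise_sd Gaussian sd of per-lipid vertical displacement,
#'   Angstrom.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return An object of class `bilayer_spec`.
#' @export
bilayer_spec <- function(lipids_per_leaflet, box_xy, half_thickness = 8,
                         beads_per_lipid = 3, vertical_noise_sd = 0,
                         seed = 1L) {
  if (length(box_xy) == 1) box_xy <- c(box_xy, box_xy)
  stopifnot(lipids_per_leaflet > 0, all(box_xy > 0), half_thickness > 0,
            beads_per_lipid >= 2, vertical_noise_sd >= 0)
  structure(list(lipids_per_leaflet = as.integer(lipids_per_leaflet),
                 box_xy = as.numeric(box_xy),
                 half_thickness = half_thickness,
                 beads_per_lipid = as.integer(beads_per_lipid),
                 vertical_noise_sd = vertical_noise_sd,
                 seed = as.integer(seed)),
            class = "bilayer_spec")
}

#' Generate a labeled bilayer draped on a surface
#'
#' Places lipids on a jittered square lattice per leaflet. The head bead of
#' an upper-leaflet lipid sits at z = h(x, y) + half_thickness + eps and a
#' lower-leaflet head at z = h(x, y) - half_thickness - eps, with
#' eps ~ N(0, vertical_noise_sd) rigid per lipid; tail beads run from the
#' head towards the local mid-plane, so tail vectors follow the membrane
#' normal (here the z axis). With `surface = NULL` the bilayer is flat at
#' z = 0.
#'
#' @param spec A [bilayer_spec()].
#' @param surface Optional `height_field` whose box must match `spec$box_xy`.
#' @param protein Optional protein particle data.frame passed through to the
#'   frame (columns residue_id, domain, x, y, z).
#' @return A [membrane_frame()].
#' @export
generate_bilayer <- function(spec, surface = NULL, protein = NULL) {
  if (!inherits(spec, "bilayer_spec")) stop("spec must be a bilayer_spec")
  if (!is.null(surface)) {
    sb <- field_box(surface)
    if (any(abs(sb - spec$box_xy) > 1e-6 * max(sb)))
      stop("surface box (", paste(signif(sb, 6), collapse = " x "),
           ") does not match spec box (",
           paste(signif(spec$box_xy, 6), collapse = " x "), ")")
  }
  n <- spec$lipids_per_leaflet
  nb <- spec$beads_per_lipid
  with_seed(spec$seed, {
    frames_per_leaflet <- lapply(c(upper = 1, lower = -1), function(side) {
      m <- ceiling(sqrt(n))
      cell <- spec$box_xy / m
      idx <- seq_len(n) - 1L
      gx <- idx %% m
      gy <- idx %/% m
      # jittered square lattice: uniform cover without a packing algorithm
      x <- (gx + 0.5 + stats::runif(n, -0.35, 0.35)) * cell[1]
      y <- (gy + 0.5 + stats::runif(n, -0.35, 0.35)) * cell[2]
      h <- if (is.null(surface)) rep(0, n) else eval_height(surface, x, y)
      eps <- if (spec$vertical_noise_sd > 0)
        stats::rnorm(n, 0, spec$vertical_noise_sd) else rep(0, n)
      head_z <- h + side * (spec$half_thickness + eps)
      # bead k of nb: head at offset half_thickness, tail end at mid-plane
      offs <- spec$half_thickness * (1 - (seq_len(nb) - 1) / (nb - 1))
      z <- as.vector(vapply(offs, function(o) h + side * (o + eps),
                            numeric(n)))
      data.frame(
        x = rep(x, nb), y = rep(y, nb), z = z,
        role = rep(c("head", rep("tail", nb - 1L)), each = n),
        name = rep(c("HD", paste0("T", seq_len(nb - 1L))), each = n),
        bead = rep(seq_len(nb), each = n),
        lipid_local = rep(seq_len(n), nb),
        side = side)
    })
    df <- rbind(frames_per_leaflet$upper, frames_per_leaflet$lower)
    df$leaflet <- ifelse(df$side > 0, "upper", "lower")
    df$lipid_id <- df$lipid_local + ifelse(df$side > 0, 0L, n)
    ord <- order(df$lipid_id, df$bead)
    df <- df[ord, ]
    zspan <- max(abs(df$z)) + spec$half_thickness
    box_z <- max(120, 4 * zspan)
    membrane_frame(
      data.frame(lipid_id = df$lipid_id, leaflet = df$leaflet,
                 role = df$role, name = df$name,
                 x = df$x, y = df$y, z = df$z),
      box = c(spec$box_xy, box_z), protein = protein)
  })
}
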