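#' Generate a toy multi-sphere protein structure
#'
#' Builds small synthetic structures for exercising the SASA engine and the
#' hydrogen-bond detector: spheres with residue ids, residue types, element
#' names and radii. Layouts:
#' \describe{
#'   \item{`linear`}{residues on a straight chain, one sphere per residue,
#'     spaced `spacing` Angstrom apart.}
#'   \item{`clustered`}{residue 1 at the origin, fully enclosed by the
#'     remaining residues arranged on a tight surrounding shell (its SASA is
#'     zero for sensible radii).}
#' }
#'
#' @param n_residues Number of residues (>= 1).
#' @param layout "linear" or "clustered".
#' @param seed Integer seed (small jitter on sphere positions in the linear
#'   layout; the clustered layout is deterministic geometry).
#' @param radius Sphere radius, Angstrom.
#' @param spacing Inter-residue spacing for the linear layout, Angstrom.
#' @param residue_types Character vector recycled over residues (3-letter
#'   codes).
#' @return A `structure_atoms` data.frame with columns residue_id,
#'   residue_type, atom, element, x, y, z, radius.
#' @export
generate_toy_protein <- function(n_residues, layout = c("linear", "clustered"),
                                 seed = 1L, radius = 1.9, spacing = 5,
                                 residue_types = "ALA") {
  stopifnot(n_residues >= 1)
  layout <- match.arg(layout)
  types <- rep_len(residue_types, n_residues)
  with_seed(seed, {
    if (layout == "linear") {
      jit <- matrix(stats::runif(3 * n_residues, -0.2, 0.2), ncol = 3)
      xyz <- cbind((seq_len(n_residues) - 1) * spacing, 0, 0) + jit
    } else {
      if (n_residues < 13)
        warning("clustered layout with < 13 residues may not fully enclose residue 1")
      # residue 1 at origin; the rest on a shell close enough to occlude it
      shell_r <- 2 * radius * 0.9
      k <- n_residues - 1L
      i <- seq_len(k)
      # Fibonacci sphere directions for even coverage
      golden <- pi * (3 - sqrt(5))
      zs <- 1 - 2 * (i - 0.5) / k
      rs <- sqrt(pmax(0, 1 - zs^2))
      th <- golden * i
      dirs <- cbind(rs * cos(th), rs * sin(th), zs)
      xyz <- rbind(c(0, 0, 0), shell_r * dirs)
    }
    df <- data.frame(residue_id = seq_len(n_residues),
                     residue_type = types,
                     atom = "CA", element = "C",
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     radius = radius)
    class(df) <- c("structure_atoms", "data.frame")
    df
  })
}

#' Read a protein structure from PDB into the package's atom table
#'
#' Uses bio3d to parse the PDB, assigns radii from the embedded element
#' table, and (by default) drops hydrogens.
#'
#' @param path PDB file.
#' @param include_hydrogens Keep H atoms (default FALSE).
#' @return A `structure_atoms` data.frame.
#' @export
read_structure_pdb <- function(path, include_hydrogens = FALSE) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  el <- ifelse(is.na(a$elesy) | a$elesy == "", substr(trimws(a$elety), 1, 1),
               trimws(a$elesy))
  keep <- rep(TRUE, nrow(a))
  if (!include_hydrogens) keep <- toupper(el) != "H"
  a <- a[keep, ]; el <- el[keep]
  df <- data.frame(residue_id = a$resno,
                   residue_type = a$resid,
                   atom = trimws(a$elety),
                   element = toupper(el),
                   x = a$x, y = a$y, z = a$z,
                   radius = element_radius(toupper(el)))
  class(df) <- c("structure_atoms", "data.frame")
  df
}

#' Van der Waals radii by element
#'
#' Fixed embedded table (Bondi-style radii, Angstrom) used when structures
#' arrive without explicit radii. Unknown elements fall back to 1.7 A.
#'
#' @param element Character vector of element symbols.
#' @return Numeric radii, Angstrom.
#' @export
element_radius <- function(element) {
  tab <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.9,
           NA. = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.4)
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  r <- tab[key]
  r[is.na(r)] <- 1.7
  unname(r)
}
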