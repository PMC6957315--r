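#' Hydrophobicity scales
#'
#' Loads one of the two shipped side-chain transfer free-energy scales
#' (kcal/mol): `"fleming"` (whole-protein folding-stability measurements)
#' or `"tieleman"` (side-chain analog membrane-insertion PMFs). The
#' Tieleman scale lacks His, Gly and Pro; those entries are filled from the
#' Fleming scale, so both returned scales cover the 20 standard residues.
#'
#' @param name "fleming" or "tieleman", or a data.frame with columns
#'   `residue_type`, `s_transfer` for a custom scale.
#' @return Object of class `hydrophobicity_scale`: data.frame
#'   (residue_type, s_transfer) with attribute `name`.
#' @export
hydrophobicity_scale <- function(name = c("fleming", "tieleman")) {
  if (is.data.frame(name)) {
    stopifnot(all(c("residue_type", "s_transfer") %in% names(name)))
    out <- name
    attr(out, "name") <- "custom"
    class(out) <- c("hydrophobicity_scale", "data.frame")
    return(out)
  }
  name <- match.arg(name)
  read_scale <- function(nm)
    utils::read.csv(system.file("extdata", paste0("scale_", nm, ".csv"),
                                package = "memmorph"), comment.char = "#")
  tab <- read_scale(name)
  if (name == "tieleman") {
    fl <- read_scale("fleming")
    missing <- setdiff(fl$residue_type, tab$residue_type)
    tab <- rbind(tab, fl[fl$residue_type %in% missing, ])
  }
  tab <- tab[order(tab$residue_type), ]
  rownames(tab) <- NULL
  attr(tab, "name") <- name
  class(tab) <- c("hydrophobicity_scale", "data.frame")
  tab
}

scale_lookup <- function(scale, residue_type) {
  idx <- match(toupper(residue_type), scale$residue_type)
  if (anyNA(idx))
    stop("residue type(s) absent from scale '", attr(scale, "name"), "': ",
         paste(unique(residue_type[is.na(idx)]), collapse = ", "))
  scale$s_transfer[idx]
}

#' Per-residue solvation free-energy change of membrane bending
#'
#' \deqn{\delta G_{sol}(i) = S_{transfer}(i) \times
#'       [A_{flat}(i) - A_{bent}(i)] / A_{max}(i)}
#' Negative values mean the deformed membrane state is favoured, positive
#' values favour the flat state. The total is the exact sum of the
#' per-residue values.
#'
#' @param A_flat,A_bent Per-residue SASA under the flat and deformed
#'   membrane models, Angstrom^2.
#' @param A_max Per-residue maximal-exposure reference areas (> 0).
#' @param scale A [hydrophobicity_scale()].
#' @param residue_types 3-letter residue types, same length as the areas.
#' @return List with `per_residue` (numeric vector, kcal/mol) and `total`.
#' @export
delta_g_sol <- function(A_flat, A_bent, A_max, scale, residue_types) {
  stopifnot(length(A_flat) == length(A_bent),
            length(A_flat) == length(A_max),
            length(A_flat) == length(residue_types))
  if (any(A_max <= 0)) stop("A_max must be > 0")
  if (any(c(A_flat, A_bent) < 0)) stop("areas must be >= 0")
  s <- scale_lookup(scale, residue_types)
  dg <- s * (A_flat - A_bent) / A_max
  list(per_residue = dg, total = sum(dg))
}

#' Build the full solvation ledger for a structure and membrane pair
#'
#' Computes per-residue A_flat (SASA occluded by the flat slab), A_bent
#' (occluded by the deformed membrane), A_max (GXG reference) and the
#' resulting delta-G under both hydrophobicity scales, plus exact totals.
#' The flat model defaults to the level-matched counterpart of the deformed
#' model ([flat_from_deformed()]).
#'
#' @param structure A `structure_atoms` data.frame.
#' @param deformed A deformed [membrane_model()].
#' @param flat Optional flat [membrane_model()].
#' @param probe,n_points SASA engine settings.
#' @param amax_override Optional named A_max override table.
#' @return Object of class `solvation_ledger`: data.frame with residue_id,
#'   residue_type, A_flat, A_bent, A_max, dG_fleming, dG_tieleman;
#'   attribute `totals` (named numeric).
#' @export
solvation_ledger <- function(structure, deformed, flat = NULL,
                             probe = 1.4, n_points = 960,
                             amax_override = NULL) {
  if (is.null(flat)) flat <- flat_from_deformed(deformed)
  sb <- occluded_sasa(structure, deformed, probe, n_points)$residue
  sf <- occluded_sasa(structure, flat, probe, n_points)$residue
  stopifnot(identical(sb$residue_id, sf$residue_id))
  amax <- reference_area(sb$residue_type, probe, n_points,
                         override = amax_override)
  fl <- hydrophobicity_scale("fleming")
  tl <- hydrophobicity_scale("tieleman")
  g_f <- delta_g_sol(sf$area, sb$area, amax, fl, sb$residue_type)
  g_t <- delta_g_sol(sf$area, sb$area, amax, tl, sb$residue_type)
  out <- data.frame(residue_id = sb$residue_id,
                    residue_type = sb$residue_type,
                    A_flat = sf$area, A_bent = sb$area, A_max = unname(amax),
                    dG_fleming = g_f$per_residue,
                    dG_tieleman = g_t$per_residue)
  attr(out, "totals") <- c(fleming = g_f$total, tieleman = g_t$total)
  class(out) <- c("solvation_ledger", "data.frame")
  out
}

#' @export
print.solvation_ledger <- function(x, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("<solvation_ledger> %d residues\n", nrow(x)))
  cat(sprintf("  total dG_sol: %.3g (fleming), %.3g (tieleman) kcal/mol\n",
              tot["fleming"], tot["tieleman"]))
  NextMethod()
}

#' Classify residues by their bending preference
#'
#' A residue is non-neutral only when |delta-G| meets the threshold under
#' BOTH scales with the same sign: negative under both = favors_deformed,
#' positive under both = favors_flat. Discordant signs or sub-threshold
#' magnitudes are neutral (discordant cases are reported via message).
#'
#' @param ledger A [solvation_ledger()].
#' @param threshold Threshold in k_B*T units (default 1).
#' @param temperature Kelvin at which k_B*T is evaluated (default 323, the
#'   usual temperature of the atomistic snapshots this analysis targets).
#' @return The ledger with an added `class` column
#'   ("favors_deformed"/"favors_flat"/"neutral").
#' @export
classify_residues <- function(ledger, threshold = 1, temperature = 323) {
  thr <- threshold * kBT(temperature)
  f <- ledger$dG_fleming; t <- ledger$dG_tieleman
  big <- abs(f) >= thr & abs(t) >= thr
  same <- sign(f) == sign(t)
  discord <- big & !same
  if (any(discord))
    message(sum(discord), " residue(s) exceed the threshold with discordant signs; kept neutral")
  cls <- rep("neutral", nrow(ledger))
  cls[big & same & f < 0] <- "favors_deformed"
  cls[big & same & f > 0] <- "favors_flat"
  ledger$class <- cls
  ledger
}

#' Write a solvation ledger as CSV
#' @param ledger A `solvation_ledger` (classified or not).
#' @param path Output CSV.
#' @export
write_ledger_csv <- function(ledger, path) {
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE)
  invisible(path)
}
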