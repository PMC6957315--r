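#' Labeled bilayer snapshot
#'
#' The universal input record of the analysis pipeline: one time frame of a
#' particle-based bilayer, with per-particle lipid id, leaflet and role
#' labels, plus optional protein particles carrying residue ids and domain
#' tags.
#'
#' @param particles data.frame with columns `lipid_id` (integer),
#'   `leaflet` ("upper"/"lower"), `role` ("head"/"tail"/"other"),
#'   `name` (bead/atom name), `x`, `y`, `z` (Angstrom).
#' @param box Length-3 numeric (Lx, Ly, Lz), Angstrom, all > 0.
#' @param protein Optional data.frame with columns `residue_id`, `domain`,
#'   `x`, `y`, `z`.
#' @param time Frame time in ps.
#' @return An object of class `membrane_frame`.
#' @export
membrane_frame <- function(particles, box, protein = NULL, time = 0) {
  need <- c("lipid_id", "leaflet", "role", "name", "x", "y", "z")
  if (!all(need %in% names(particles)))
    stop("particles must have columns: ", paste(need, collapse = ", "))
  if (!all(box > 0) || length(box) != 3) stop("box must be 3 positive lengths")
  if (!all(particles$leaflet %in% c("upper", "lower")))
    stop("leaflet labels must be 'upper' or 'lower'")
  heads <- particles$role == "head"
  nh <- table(particles$lipid_id[heads])
  if (length(nh) && any(nh != 1L))
    stop("every lipid must have exactly one head particle")
  if (!is.null(protein)) {
    pneed <- c("residue_id", "domain", "x", "y", "z")
    if (!all(pneed %in% names(protein)))
      stop("protein must have columns: ", paste(pneed, collapse = ", "))
  }
  structure(list(particles = particles, protein = protein,
                 box = as.numeric(box), time = time),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("<membrane_frame> %d lipid particles (%d lipids), box %.4g x %.4g x %.4g A, t = %g ps\n",
              nrow(x$particles), length(unique(x$particles$lipid_id)),
              x$box[1], x$box[2], x$box[3], x$time))
  if (!is.null(x$protein))
    cat(sprintf("  + %d protein particles, %d residues\n",
                nrow(x$protein), length(unique(x$protein$residue_id))))
  invisible(x)
}

#' Write a membrane frame in GRO format
#'
#' Plain-text Gromos87 coordinate file (nm units in file; the frame is in
#' Angstrom and converted on write). Lipid particles come first, protein
#' particles after; a sidecar labels CSV preserves the label columns that
#' GRO cannot carry.
#'
#' @param frame A `membrane_frame`.
#' @param path Output `.gro` path; labels go to `paste0(path, ".labels.csv")`.
#' @export
write_frame_gro <- function(frame, path) {
  p <- frame$particles
  n_lip <- nrow(p)
  n_pro <- if (is.null(frame$protein)) 0L else nrow(frame$protein)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("memmorph frame t=%g", frame$time), con)
  writeLines(sprintf("%5d", n_lip + n_pro), con)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   (p$lipid_id - 1L) %% 100000L + 1L, "LIP",
                   substr(p$name, 1, 5), (seq_len(n_lip) - 1L) %% 100000L + 1L,
                   p$x / 10, p$y / 10, p$z / 10)
  writeLines(lines, con)
  if (n_pro > 0) {
    q <- frame$protein
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       (q$residue_id - 1L) %% 100000L + 1L, "PROT", "BB",
                       (n_lip + seq_len(n_pro) - 1L) %% 100000L + 1L,
                       q$x / 10, q$y / 10, q$z / 10), con)
  }
  writeLines(sprintf("%10.5f%10.5f%10.5f",
                     frame$box[1] / 10, frame$box[2] / 10, frame$box[3] / 10), con)
  labels <- data.frame(index = seq_len(n_lip), lipid_id = p$lipid_id,
                       leaflet = p$leaflet, role = p$role, name = p$name)
  utils::write.csv(labels, paste0(path, ".labels.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a membrane frame written by [write_frame_gro()]
#'
#' @param path `.gro` path; the sidecar labels CSV must sit next to it.
#' @return A `membrane_frame`.
#' @export
read_frame_gro <- function(path) {
  txt <- readLines(path)
  n <- as.integer(txt[2])
  body <- txt[3:(2 + n)]
  resname <- trimws(substr(body, 6, 10))
  xyz <- cbind(as.numeric(substr(body, 21, 28)),
               as.numeric(substr(body, 29, 36)),
               as.numeric(substr(body, 37, 44))) * 10
  box <- as.numeric(strsplit(trimws(txt[3 + n]), "\\s+")[[1]])[1:3] * 10
  is_lip <- resname == "LIP"
  labels <- utils::read.csv(paste0(path, ".labels.csv"))
  p <- data.frame(lipid_id = labels$lipid_id, leaflet = labels$leaflet,
                  role = labels$role, name = labels$name,
                  x = xyz[is_lip, 1], y = xyz[is_lip, 2], z = xyz[is_lip, 3])
  protein <- NULL
  if (any(!is_lip)) {
    resid <- as.integer(substr(body, 1, 5))
    protein <- data.frame(residue_id = resid[!is_lip], domain = "protein",
                          x = xyz[!is_lip, 1], y = xyz[!is_lip, 2],
                          z = xyz[!is_lip, 3])
  }
  membrane_frame(p, box, protein = protein)
}

# Run code with a temporarily-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
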