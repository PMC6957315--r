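#' Write a 3D scalar grid in OpenDX format
#'
#' Regular-grid OpenDX text output (the volumetric format molecular
#' visualization tools read). Values are written in C order (z fastest).
#'
#' @param arr 3D numeric array.
#' @param path Output `.dx` path.
#' @param origin Length-3 grid origin, Angstrom.
#' @param delta Length-3 grid spacings along x, y, z.
#' @export
write_dx <- function(arr, path, origin = c(0, 0, 0), delta = c(1, 1, 1)) {
  d <- dim(arr)
  stopifnot(length(d) == 3, length(origin) == 3, length(delta) == 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6g %.6g %.6g", origin[1], origin[2], origin[3]),
    sprintf("delta %.6g 0 0", delta[1]),
    sprintf("delta 0 %.6g 0", delta[2]),
    sprintf("delta 0 0 %.6g", delta[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  v <- as.vector(aperm(arr, c(3, 2, 1)))  # z fastest
  n3 <- (length(v) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(v[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.8g %.8g %.8g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(v))
    writeLines(paste(sprintf("%.8g", v[(n3 + 1):length(v)]), collapse = " "),
               con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field'), con)
  invisible(path)
}

#' Read a 3D scalar grid from OpenDX format
#'
#' @param path A `.dx` file written by [write_dx()] (or compatible
#'   regular-grid DX).
#' @return List with `values` (3D array), `origin`, `delta`.
#' @export
read_dx <- function(path) {
  txt <- readLines(path)
  gp <- grep("gridpositions", txt, value = TRUE)[1]
  d <- as.integer(utils::tail(strsplit(gp, "\\s+")[[1]], 3))
  origin <- as.numeric(strsplit(trimws(sub("origin", "",
    grep("^origin", txt, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- grep("^delta", txt, value = TRUE)
  dv <- t(vapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  delta <- unname(c(dv[1, 1], dv[2, 2], dv[3, 3]))
  start <- grep("data follows", txt)[1] + 1L
  end <- length(txt)
  body <- txt[start:end]
  body <- body[!grepl("^(attribute|object)", body)]
  v <- as.numeric(unlist(strsplit(trimws(body[nzchar(trimws(body))]), "\\s+")))
  stopifnot(length(v) == prod(d))
  arr <- aperm(array(v, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  list(values = arr, origin = origin, delta = delta)
}

#' Write / read a density-map set as OpenDX files plus a JSON manifest
#'
#' One `.dx` file per map and a manifest recording labels and grid
#' geometry, so a set can round-trip.
#'
#' @param maps A [density_map_set()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Path of the manifest JSON.
#' @export
write_mapset_dx <- function(maps, dir, prefix = "map") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(maps$maps))
  for (k in seq_along(maps$maps)) {
    files[k] <- file.path(dir, sprintf("%s_%02d.dx", prefix, k))
    write_dx(maps$maps[[k]], files[k],
             origin = c(maps$origin, maps$z0),
             delta = c(maps$spacing, maps$spacing, maps$dz))
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(list(labels = maps$labels, files = basename(files),
                            spacing = maps$spacing, origin = maps$origin,
                            z0 = maps$z0, dz = maps$dz),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_mapset_dx
#' @param manifest Path of a manifest written by [write_mapset_dx()].
#' @export
read_mapset_dx <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  arrs <- lapply(file.path(dir, m$files), function(f) read_dx(f)$values)
  density_map_set(arrs, labels = m$labels, spacing = m$spacing,
                  origin = m$origin, z0 = m$z0, dz = m$dz)
}
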