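#' 2D scalar map with counts and standard errors
#'
#' Gridded membrane observable (deflection or thickness in Angstrom, order
#' parameter dimensionless) on half-open cells `[x, x + spacing)`. Cells
#' with no observations are empty (NA), never silently zero.
#'
#' @param values,counts,stderr Nx x Ny matrices.
#' @param spacing Cell size, Angstrom.
#' @param origin (x0, y0) of cell [1, 1].
#' @param reference_level Value subtracted as zero level (deflection maps).
#' @param units Unit string.
#' @return Object of class `scalar_map2d`.
#' @export
scalar_map2d <- function(values, counts, stderr = NULL, spacing,
                         origin = c(0, 0), reference_level = 0,
                         units = "A") {
  if (is.null(stderr)) stderr <- matrix(NA_real_, nrow(values), ncol(values))
  stopifnot(identical(dim(values), dim(counts)),
            identical(dim(values), dim(stderr)))
  if (any(stats::na.omit(as.vector(stderr)) < 0)) stop("stderr must be >= 0")
  structure(list(values = values, counts = counts, stderr = stderr,
                 spacing = spacing, origin = as.numeric(origin),
                 reference_level = reference_level, units = units),
            class = "scalar_map2d")
}

#' @export
print.scalar_map2d <- function(x, ...) {
  d <- dim(x$values)
  occ <- sum(x$counts > 0)
  cat(sprintf("<scalar_map2d> %d x %d cells (%.3g A), %d occupied, units %s\n",
              d[1], d[2], x$spacing, occ, x$units))
  v <- x$values[x$counts > 0]
  if (length(v))
    cat(sprintf("  value range [%.3g, %.3g], mean stderr %.3g\n",
                min(v), max(v), mean(x$stderr[x$counts > 0], na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.scalar_map2d <- function(x, ...) {
  graphics::image(seq_len(nrow(x$values)) * x$spacing,
                  seq_len(ncol(x$values)) * x$spacing,
                  x$values, xlab = "x (A)", ylab = "y (A)", ...)
  invisible(x)
}

#' Write a scalar map as CSV (x, y, value, counts, stderr)
#' @param map A `scalar_map2d`.
#' @param path Output CSV.
#' @export
write_map_csv <- function(map, path) {
  d <- dim(map$values)
  xs <- map$origin[1] + (seq_len(d[1]) - 0.5) * map$spacing
  ys <- map$origin[2] + (seq_len(d[2]) - 0.5) * map$spacing
  utils::write.csv(data.frame(
    x = rep(xs, times = d[2]), y = rep(ys, each = d[1]),
    value = as.vector(map$values), counts = as.vector(map$counts),
    stderr = as.vector(map$stderr)), path, row.names = FALSE)
  invisible(path)
}

# cell index (1-based) of coordinates, half-open cells, periodic wrap
cell_index <- function(x, spacing, n) {
  as.integer(floor(x / spacing) %% n) + 1L
}

map_dims <- function(box, spacing) {
  n <- round(box[1:2] / spacing)
  if (any(n < 1)) stop("spacing larger than the box")
  as.integer(n)
}

# Per-frame per-cell mean head z for one leaflet; NA where leaflet absent.
leaflet_cell_mean <- function(frame, spacing, leaflet, n) {
  p <- frame$particles
  sel <- p$role == "head" & p$leaflet == leaflet
  if (!any(sel)) return(list(mean = matrix(NA_real_, n[1], n[2]),
                             count = matrix(0, n[1], n[2])))
  ix <- cell_index(p$x[sel], spacing, n[1])
  iy <- cell_index(p$y[sel], spacing, n[2])
  lin <- ix + (iy - 1L) * n[1]
  s <- rowsum(p$z[sel], lin)
  cnt <- rowsum(rep(1, length(lin)), lin)
  m <- matrix(NA_real_, n[1], n[2]); cm <- matrix(0, n[1], n[2])
  idx <- as.integer(rownames(s))
  m[idx] <- s / cnt
  cm[idx] <- cnt
  list(mean = m, count = cm)
}

# Accumulate per-frame cell statistics into mean/stderr/count maps. Cells
# whose value is undefined in every frame get count 0 (flagged empty).
accumulate_maps <- function(per_frame_vals, per_frame_counts) {
  d <- dim(per_frame_vals[[1]])
  stack <- array(unlist(per_frame_vals), c(d[1], d[2], length(per_frame_vals)))
  cnts <- Reduce(`+`, per_frame_counts)
  nobs <- apply(!is.na(stack), c(1, 2), sum)
  mean_m <- apply(stack, c(1, 2), function(v) mean(v, na.rm = TRUE))
  mean_m[nobs == 0] <- NA_real_
  sd_m <- apply(stack, c(1, 2), function(v) stats::sd(v, na.rm = TRUE))
  se_m <- sd_m / sqrt(pmax(nobs, 1))
  se_m[nobs <= 1] <- NA_real_
  cnts[nobs == 0] <- 0
  list(mean = mean_m, counts = cnts, stderr = se_m)
}

map_center <- function(frames, box) {
  pro <- frames[[1]]$protein
  if (!is.null(pro)) c(mean(pro$x), mean(pro$y)) else box[1:2] / 2
}

# minimum-image in-plane distance of cell centres from a point
cell_center_dist <- function(n, spacing, origin, center, box) {
  xs <- origin[1] + (seq_len(n[1]) - 0.5) * spacing
  ys <- origin[2] + (seq_len(n[2]) - 0.5) * spacing
  dx <- outer(xs - center[1], rep(1, n[2]))
  dy <- outer(rep(1, n[1]), ys - center[2])
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  sqrt(dx^2 + dy^2)
}

#' Mid-plane deflection map
#'
#' Time-averaged map of the bilayer mid-plane height: per cell and frame the
#' mid-plane is the midpoint between the mean upper-leaflet and mean
#' lower-leaflet head heights; frames are averaged, and the zero level is
#' set to the mean over all far-field cells (those beyond
#' `far_field_radius` from the map centre - the protein's in-plane centre
#' of mass when protein particles are present, the box centre otherwise).
#' Positive values are outward deflections.
#'
#' @param frames List of `membrane_frame` (>= 1), one box.
#' @param spacing Cell size, Angstrom (default 5).
#' @param far_field_radius Zero-level radius, Angstrom; default 200,
#'   shrunk to 40% of the half-box when the box is smaller.
#' @return A `scalar_map2d`; `reference_level` records the subtracted
#'   far-field mean.
#' @export
midplane_deflection <- function(frames, spacing = 5,
                                far_field_radius = NULL) {
  stopifnot(length(frames) >= 1)
  box <- frames[[1]]$box
  if (is.null(far_field_radius))
    far_field_radius <- min(200, 0.4 * min(box[1:2]))
  if (far_field_radius >= 0.5 * min(box[1:2]) * sqrt(2))
    stop("far_field_radius lies outside the box")
  n <- map_dims(box, spacing)
  per_frame <- lapply(frames, function(fr) {
    up <- leaflet_cell_mean(fr, spacing, "upper", n)
    lo <- leaflet_cell_mean(fr, spacing, "lower", n)
    list(vals = (up$mean + lo$mean) / 2, counts = up$count + lo$count)
  })
  acc <- accumulate_maps(lapply(per_frame, `[[`, "vals"),
                         lapply(per_frame, `[[`, "counts"))
  dist <- cell_center_dist(n, spacing, c(0, 0), map_center(frames, box), box)
  far <- dist > far_field_radius & !is.na(acc$mean)
  if (!any(far)) stop("no occupied far-field cells beyond far_field_radius; cannot set zero level")
  ref <- mean(acc$mean[far])
  scalar_map2d(acc$mean - ref, acc$counts, acc$stderr, spacing,
               reference_level = ref, units = "A")
}

#' Bilayer thickness map (or single-leaflet head-height map)
#'
#' Per-cell mean vertical distance between the upper and lower head
#' surfaces. Cells missing either leaflet are empty. With
#' `leaflet = "upper"` or `"lower"` the map is that leaflet's mean head
#' height instead.
#'
#' @param frames List of `membrane_frame`.
#' @param spacing Cell size, Angstrom.
#' @param leaflet "both" (thickness), "upper" or "lower".
#' @return A `scalar_map2d`.
#' @export
thickness_map <- function(frames, spacing = 5,
                          leaflet = c("both", "upper", "lower")) {
  leaflet <- match.arg(leaflet)
  box <- frames[[1]]$box
  n <- map_dims(box, spacing)
  per_frame <- lapply(frames, function(fr) {
    up <- leaflet_cell_mean(fr, spacing, "upper", n)
    lo <- leaflet_cell_mean(fr, spacing, "lower", n)
    if (leaflet == "both")
      list(vals = up$mean - lo$mean, counts = up$count + lo$count)
    else if (leaflet == "upper") list(vals = up$mean, counts = up$count)
    else list(vals = lo$mean, counts = lo$count)
  })
  acc <- accumulate_maps(lapply(per_frame, `[[`, "vals"),
                         lapply(per_frame, `[[`, "counts"))
  scalar_map2d(acc$mean, acc$counts, acc$stderr, spacing, units = "A")
}

# per-lipid tail vector: head -> farthest tail particle; NULL if degenerate
lipid_tail_vectors <- function(frame) {
  p <- frame$particles
  heads <- p[p$role == "head", c("lipid_id", "leaflet", "x", "y", "z")]
  tails <- p[p$role == "tail", c("lipid_id", "x", "y", "z")]
  if (!nrow(tails)) stop("order parameter needs tail particles")
  hz <- heads[match(tails$lipid_id, heads$lipid_id), ]
  d2 <- (tails$x - hz$x)^2 + (tails$y - hz$y)^2 + (tails$z - hz$z)^2
  ord <- order(tails$lipid_id, -d2)
  tails <- tails[ord, ]; d2 <- d2[ord]
  keep <- !duplicated(tails$lipid_id)
  te <- tails[keep, ]
  h <- heads[match(te$lipid_id, heads$lipid_id), ]
  v <- cbind(te$x - h$x, te$y - h$y, te$z - h$z)
  len <- sqrt(rowSums(v^2))
  ok <- len > 1e-9
  if (!all(ok)) message(sum(!ok), " zero-length tail vector(s) skipped")
  data.frame(lipid_id = te$lipid_id[ok], leaflet = h$leaflet[ok],
             x = h$x[ok], y = h$y[ok],
             cos2 = (v[ok, 3] / len[ok])^2)
}

#' Second-rank order-parameter map of lipid tails
#'
#' Per-cell \eqn{P_2 = (3\langle\cos^2\theta\rangle - 1)/2} with theta the
#' angle between each lipid's head-to-tail-end vector and the global
#' membrane normal (z). P2 is 1 for tails along z, -0.5 in-plane, 0
#' isotropic. Computed per leaflet, since tilt responds to curvature
#' differently on the two sides.
#'
#' @param frames List of `membrane_frame`; lipids need >= 1 tail particle.
#' @param spacing Cell size, Angstrom.
#' @return Named list with `scalar_map2d` elements `upper` and `lower`.
#' @export
order_parameter_map <- function(frames, spacing = 5) {
  box <- frames[[1]]$box
  n <- map_dims(box, spacing)
  one_leaflet <- function(lf) {
    per_frame <- lapply(frames, function(fr) {
      tv <- lipid_tail_vectors(fr)
      tv <- tv[tv$leaflet == lf, ]
      m <- matrix(NA_real_, n[1], n[2]); cm <- matrix(0, n[1], n[2])
      if (nrow(tv)) {
        lin <- cell_index(tv$x, spacing, n[1]) +
          (cell_index(tv$y, spacing, n[2]) - 1L) * n[1]
        s <- rowsum(tv$cos2, lin); cnt <- rowsum(rep(1, length(lin)), lin)
        idx <- as.integer(rownames(s))
        m[idx] <- (3 * (s / cnt) - 1) / 2
        cm[idx] <- cnt
      }
      list(vals = m, counts = cm)
    })
    acc <- accumulate_maps(lapply(per_frame, `[[`, "vals"),
                           lapply(per_frame, `[[`, "counts"))
    scalar_map2d(acc$mean, acc$counts, acc$stderr, spacing, units = "P2")
  }
  list(upper = one_leaflet("upper"), lower = one_leaflet("lower"))
}

#' Alkyl-tail density near the protein surface
#'
#' Time-averaged number density of tail particles on a 3D voxel grid,
#' restricted to voxels whose centre lies within `cutoff` of any protein
#' particle; everything farther is reported as 0. Units particles/A^3.
#'
#' @param frames List of `membrane_frame`.
#' @param protein Protein particle data.frame; defaults to the first
#'   frame's.
#' @param cutoff Shell radius, Angstrom (default 10).
#' @param voxel Voxel edge, Angstrom.
#' @return List with `density` (3D array), `within_cutoff` (logical array),
#'   `voxel`, `origin`.
#' @export
alkyl_density <- function(frames, protein = frames[[1]]$protein,
                          cutoff = 10, voxel = 5) {
  if (is.null(protein) || !nrow(protein))
    stop("alkyl_density requires protein particles")
  box <- frames[[1]]$box
  n <- pmax(1L, as.integer(round(box / voxel)))
  counts <- array(0, n)
  for (fr in frames) {
    p <- fr$particles
    t <- p[p$role == "tail", ]
    if (!nrow(t)) next
    ix <- cell_index(t$x, voxel, n[1])
    iy <- cell_index(t$y, voxel, n[2])
    iz <- pmin(pmax(as.integer(floor(t$z / voxel) + n[3] %/% 2 + 1L), 1L), n[3])
    lin <- ix + (iy - 1L) * n[1] + (iz - 1L) * n[1] * n[2]
    tab <- tabulate(lin, nbins = prod(n))
    counts <- counts + array(tab, n)
  }
  xs <- (seq_len(n[1]) - 0.5) * voxel
  ys <- (seq_len(n[2]) - 0.5) * voxel
  zs <- (seq_len(n[3]) - 0.5 - n[3] / 2) * voxel
  centers <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  pro <- as.matrix(protein[, c("x", "y", "z")])
  mind2 <- rep(Inf, nrow(centers))
  for (i in seq_len(nrow(pro))) {
    dx <- centers[, 1] - pro[i, 1]; dx <- dx - box[1] * round(dx / box[1])
    dy <- centers[, 2] - pro[i, 2]; dy <- dy - box[2] * round(dy / box[2])
    dzc <- centers[, 3] - pro[i, 3]
    mind2 <- pmin(mind2, dx^2 + dy^2 + dzc^2)
  }
  within <- array(mind2 <= cutoff^2, n)
  dens <- counts / (length(frames) * voxel^3)
  dens[!within] <- 0
  list(density = dens, within_cutoff = within, voxel = voxel,
       origin = c(0, 0, -n[3] / 2 * voxel))
}

#' Radial cross-section of a scalar map
#'
#' Bins map cells by their minimum in-plane distance to a mask of origin
#' cells (e.g. the protein footprint) or to a point, optionally restricted
#' to an angular sector measured from the mask centroid.
#'
#' @param map A `scalar_map2d`.
#' @param origin Either a logical matrix matching the map (mask of origin
#'   cells) or a length-2 point (x, y) in Angstrom.
#' @param sector Optional angular window `c(theta_min, theta_max)` radians
#'   in (-pi, pi].
#' @param bin_width Distance bin width, Angstrom (default the map spacing).
#' @return Object of class `profile1d`: data.frame with `bins` (bin-centre
#'   distance), `mean`, `stderr`, `n`.
#' @export
radial_profile <- function(map, origin, sector = NULL,
                           bin_width = map$spacing) {
  d <- dim(map$values)
  box <- d * map$spacing
  xs <- map$origin[1] + (seq_len(d[1]) - 0.5) * map$spacing
  ys <- map$origin[2] + (seq_len(d[2]) - 0.5) * map$spacing
  cx <- rep(xs, times = d[2]); cy <- rep(ys, each = d[1])
  if (is.matrix(origin) || is.array(origin)) {
    if (!identical(dim(origin), d)) stop("origin mask must match the map grid")
    if (!any(origin)) stop("origin mask is empty")
    ox <- cx[as.vector(origin)]; oy <- cy[as.vector(origin)]
    centroid <- c(mean(ox), mean(oy))
    dist <- rep(Inf, length(cx))
    for (i in seq_along(ox)) {
      dx <- cx - ox[i]; dx <- dx - box[1] * round(dx / box[1])
      dy <- cy - oy[i]; dy <- dy - box[2] * round(dy / box[2])
      dist <- pmin(dist, sqrt(dx^2 + dy^2))
    }
  } else {
    centroid <- origin
    dx <- cx - origin[1]; dx <- dx - box[1] * round(dx / box[1])
    dy <- cy - origin[2]; dy <- dy - box[2] * round(dy / box[2])
    dist <- sqrt(dx^2 + dy^2)
  }
  keep <- map$counts > 0 & !is.na(map$values)
  if (!is.null(sector)) {
    dx <- cx - centroid[1]; dx <- dx - box[1] * round(dx / box[1])
    dy <- cy - centroid[2]; dy <- dy - box[2] * round(dy / box[2])
    ang <- atan2(dy, dx)
    keep <- keep & ang >= sector[1] & ang <= sector[2]
    if (!any(keep)) stop("sector contains no occupied cells")
  }
  dist <- as.vector(dist)[as.vector(keep)]
  vals <- map$values[keep]
  bins <- floor(dist / bin_width)
  agg_m <- tapply(vals, bins, mean)
  agg_s <- tapply(vals, bins, stats::sd)
  agg_n <- tapply(vals, bins, length)
  b <- as.numeric(names(agg_m))
  out <- data.frame(bins = (b + 0.5) * bin_width,
                    mean = as.numeric(agg_m),
                    stderr = as.numeric(agg_s) / sqrt(as.numeric(agg_n)),
                    n = as.numeric(agg_n))
  out <- out[order(out$bins), ]
  rownames(out) <- NULL
  class(out) <- c("profile1d", "data.frame")
  out
}

#' Lipid shell residence and exchange counting
#'
#' A lipid is "in shell" in a frame when any of its particles lies within
#' `cutoff` (3D, periodic in-plane) of any protein particle; an exchange is
#' an in/out transition between consecutive frames.
#'
#' @param frames List of `membrane_frame` (time-ordered).
#' @param protein Protein particles; defaults to the first frame's.
#' @param cutoff Shell radius, Angstrom.
#' @return List with `in_shell` (lipids x frames logical matrix),
#'   `segments` (data.frame lipid_id, start, end, state), and `exchanges`
#'   (total transition count).
#' @export
shell_exchange <- function(frames, protein = frames[[1]]$protein,
                           cutoff = 10) {
  if (is.null(protein) || !nrow(protein)) stop("protein particles required")
  box <- frames[[1]]$box
  lipids <- sort(unique(frames[[1]]$particles$lipid_id))
  pro <- as.matrix(protein[, c("x", "y", "z")])
  inshell <- matrix(FALSE, length(lipids), length(frames),
                    dimnames = list(lipids, NULL))
  for (f in seq_along(frames)) {
    p <- frames[[f]]$particles
    mind2 <- rep(Inf, nrow(p))
    for (i in seq_len(nrow(pro))) {
      dx <- p$x - pro[i, 1]; dx <- dx - box[1] * round(dx / box[1])
      dy <- p$y - pro[i, 2]; dy <- dy - box[2] * round(dy / box[2])
      dz <- p$z - pro[i, 3]
      mind2 <- pmin(mind2, dx^2 + dy^2 + dz^2)
    }
    hit <- tapply(mind2 <= cutoff^2, p$lipid_id, any)
    inshell[match(names(hit), rownames(inshell)), f] <- as.logical(hit)
  }
  segs <- do.call(rbind, lapply(seq_along(lipids), function(li) {
    r <- rle(inshell[li, ])
    ends <- cumsum(r$lengths)
    data.frame(lipid_id = lipids[li], start = c(1, utils::head(ends, -1) + 1),
               end = ends, state = ifelse(r$values, "in", "out"))
  }))
  rownames(segs) <- NULL
  exch <- sum(apply(inshell, 1, function(v) sum(diff(v) != 0)))
  list(in_shell = inshell, segments = segs, exchanges = exch)
}

#' Domain centre-of-mass height relative to the far-field mid-plane
#'
#' Time-averaged centre-of-mass z per protein domain tag, referenced to the
#' same far-field zero level as [midplane_deflection()].
#'
#' @param frames List of `membrane_frame` with protein particles.
#' @param spacing,far_field_radius Passed to the deflection zero-level
#'   computation.
#' @return data.frame with `domain`, `offset` (A), `stderr` (across
#'   frames), `n_frames`.
#' @export
domain_z_offset <- function(frames, spacing = 5, far_field_radius = NULL) {
  if (is.null(frames[[1]]$protein)) stop("frames carry no protein particles")
  defl <- midplane_deflection(frames, spacing, far_field_radius)
  ref <- defl$reference_level
  per_frame <- lapply(frames, function(fr) {
    tapply(fr$protein$z, fr$protein$domain, mean)
  })
  doms <- sort(unique(unlist(lapply(per_frame, names))))
  out <- do.call(rbind, lapply(doms, function(dm) {
    zs <- vapply(per_frame, function(v) if (dm %in% names(v)) v[[dm]] else NA_real_,
                 numeric(1))
    zs <- zs[!is.na(zs)]
    data.frame(domain = dm, offset = mean(zs) - ref,
               stderr = if (length(zs) > 1) stats::sd(zs) / sqrt(length(zs)) else NA_real_,
               n_frames = length(zs))
  }))
  rownames(out) <- NULL
  out
}

#' Mean and standard error over replicate maps
#'
#' Per-cell mean and standard error across N >= 2 replicate maps of the
#' same observable; the map-wide average standard error (the usual summary
#' statistic of such replicate analyses) is attached as attribute
#' `"mean_stderr"`.
#'
#' @param maps List of >= 2 `scalar_map2d` on identical grids.
#' @return A `scalar_map2d` of the replicate mean; `stderr` holds the
#'   replicate standard error.
#' @export
replicate_stderr <- function(maps) {
  stopifnot(length(maps) >= 2)
  d <- dim(maps[[1]]$values)
  for (m in maps) if (!identical(dim(m$values), d))
    stop("replicate maps must share one grid")
  stack <- simplify2array(lapply(maps, `[[`, "values"))
  nrep <- apply(!is.na(stack), c(1, 2), sum)
  mean_m <- apply(stack, c(1, 2), function(v) mean(v, na.rm = TRUE))
  mean_m[nrep == 0] <- NA_real_
  se_m <- apply(stack, c(1, 2), function(v) stats::sd(v, na.rm = TRUE)) /
    sqrt(pmax(nrep, 1))
  se_m[nrep < 2] <- NA_real_
  counts <- Reduce(`+`, lapply(maps, `[[`, "counts"))
  out <- scalar_map2d(mean_m, counts, se_m, maps[[1]]$spacing,
                      origin = maps[[1]]$origin, units = maps[[1]]$units)
  attr(out, "mean_stderr") <- mean(se_m[nrep >= 2], na.rm = TRUE)
  out
}
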