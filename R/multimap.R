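#' Labeled density-map set defining the Multi-Map variable
#'
#' K scalar density grids \eqn{\phi_k \ge 0} on a shared 3D lattice, each
#' labeled with a deformation amplitude \eqn{\xi_k}. The Multi-Map collective
#' variable scores how similar an instantaneous membrane configuration is to
#' each map; biased sampling of it drives the membrane through the family of
#' target shapes.
#'
#' @param maps List of K (>= 2) non-negative 3D arrays of identical dim
#'   (nx, ny, nz).
#' @param labels Numeric length K, strictly monotone.
#' @param spacing In-plane grid spacing, Angstrom.
#' @param origin In-plane (x0, y0) of node [1, 1].
#' @param z0,dz Vertical grid origin and spacing, Angstrom.
#' @return An object of class `density_map_set`.
#' @export
density_map_set <- function(maps, labels, spacing, origin = c(0, 0), z0, dz) {
  if (length(maps) < 2) stop("a density_map_set needs K >= 2 maps")
  d <- dim(maps[[1]])
  if (length(d) != 3) stop("maps must be 3D arrays")
  for (mp in maps) {
    if (!identical(dim(mp), d)) stop("all maps must share one grid")
    if (any(mp < 0)) stop("map densities must be >= 0")
  }
  dl <- diff(labels)
  if (length(labels) != length(maps) || !(all(dl > 0) || all(dl < 0)))
    stop("labels must be strictly monotone, one per map")
  structure(list(maps = maps, labels = as.numeric(labels),
                 spacing = spacing, origin = as.numeric(origin),
                 z0 = z0, dz = dz),
            class = "density_map_set")
}

#' @export
print.density_map_set <- function(x, ...) {
  d <- dim(x$maps[[1]])
  cat(sprintf("<density_map_set> K = %d maps on %d x %d x %d grid (xy %.3g A, z %.3g A)\n",
              length(x$maps), d[1], d[2], d[3], x$spacing, x$dz))
  cat("  labels:", paste(signif(x$labels, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Build target density maps from a base deformation shape
#'
#' Map k is a Gaussian-smeared occupancy of the surface
#' \eqn{z = a_k\,h_{base}(x, y)}:
#' \eqn{\phi_k(x,y,z) = \exp[-(z - a_k h(x,y))^2 / (2 s^2)]}, with label
#' \eqn{\xi_k = a_k}. All maps share the in-plane grid of the base shape and
#' integrate to the same mass (the vertical Gaussian mass is
#' amplitude-independent).
#'
#' The maps are restricted to the region where the deformation is
#' appreciable: grid columns where `|h_base|` falls below
#' `support_threshold` times its maximum are zeroed in every map, so the
#' undeformed far field (where all target surfaces coincide) does not
#' dilute the similarity scores.
#'
#' @param base_shape A `height_field`: the unit-amplitude deformation.
#' @param amplitudes Strictly monotone numeric vector of scale factors
#'   \eqn{a_k} (length >= 2); amplitude 0 is a flat sheet.
#' @param nz Vertical grid nodes.
#' @param z_pad Vertical padding beyond the extreme surfaces, Angstrom.
#' @param smoothing_sd Gaussian smearing sd s, Angstrom. The default scales
#'   with the vertical separation of adjacent target surfaces
#'   (0.6 x mean amplitude step x max |h_base|), which keeps neighbouring
#'   maps overlapping without washing out their contrast.
#' @param support_threshold Relative `|h_base|` cut defining the map
#'   support (0 keeps the whole box).
#' @return A [density_map_set()]; the base shape is kept as element
#'   `base` for samplers that want an initial surface.
#' @export
build_target_maps <- function(base_shape, amplitudes, nz = 48, z_pad = 10,
                              smoothing_sd = NULL, support_threshold = 0.5) {
  stopifnot(length(amplitudes) >= 2, nz >= 8,
            support_threshold >= 0, support_threshold < 1)
  h <- base_shape$values
  if (is.null(smoothing_sd))
    smoothing_sd <- max(0.6 * mean(abs(diff(amplitudes))) * max(abs(h)), 1e-6)
  stopifnot(smoothing_sd > 0)
  zr <- range(outer(as.vector(h), amplitudes))
  z0 <- zr[1] - z_pad
  z1 <- zr[2] + z_pad
  dz <- (z1 - z0) / (nz - 1)
  zs <- z0 + (seq_len(nz) - 1) * dz
  d <- dim(h)
  support <- abs(as.vector(h)) >= support_threshold * max(abs(h))
  maps <- lapply(amplitudes, function(a) {
    target <- a * as.vector(h)                       # length nx*ny
    dev <- outer(target, zs, function(t, z) z - t)   # (nx*ny) x nz
    phi <- exp(-dev^2 / (2 * smoothing_sd^2))
    phi[!support, ] <- 0
    array(phi, dim = c(d[1], d[2], nz))
  })
  out <- density_map_set(maps, labels = amplitudes,
                         spacing = base_shape$spacing,
                         origin = base_shape$origin, z0 = z0, dz = dz)
  out$base <- base_shape
  out
}

# Trilinear interpolation of one map at arbitrary points; periodic in xy,
# zero outside the vertical extent.
interp_map <- function(arr, x, y, z, spacing, origin, z0, dz) {
  d <- dim(arr)
  fx <- ((x - origin[1]) / spacing) %% d[1]
  fy <- ((y - origin[2]) / spacing) %% d[2]
  tz <- (z - z0) / dz
  out <- numeric(length(x))
  inb <- tz >= 0 & tz <= d[3] - 1
  if (!any(inb)) return(out)
  fx <- fx[inb]; fy <- fy[inb]; tz <- tz[inb]
  i0 <- floor(fx); j0 <- floor(fy); k0 <- pmin(floor(tz), d[3] - 2)
  ax <- fx - i0; ay <- fy - j0; az <- tz - k0
  i0 <- as.integer(i0 %% d[1]); j0 <- as.integer(j0 %% d[2])
  i1 <- (i0 + 1L) %% d[1]; j1 <- (j0 + 1L) %% d[2]
  k0 <- as.integer(k0); k1 <- k0 + 1L
  g <- function(ii, jj, kk) arr[cbind(ii + 1L, jj + 1L, kk + 1L)]
  val <-
    g(i0, j0, k0) * (1 - ax) * (1 - ay) * (1 - az) +
    g(i1, j0, k0) * ax       * (1 - ay) * (1 - az) +
    g(i0, j1, k0) * (1 - ax) * ay       * (1 - az) +
    g(i1, j1, k0) * ax       * ay       * (1 - az) +
    g(i0, j0, k1) * (1 - ax) * (1 - ay) * az +
    g(i1, j0, k1) * ax       * (1 - ay) * az +
    g(i0, j1, k1) * (1 - ax) * ay       * az +
    g(i1, j1, k1) * ax       * ay       * az
  out[inb] <- val
  out
}

# Extract the (x, y, z) points a configuration contributes to xi.
multimap_points <- function(config, selection = "head") {
  if (inherits(config, "height_field")) {
    d <- dim(config$values)
    xs <- config$origin[1] + (seq_len(d[1]) - 1) * config$spacing
    ys <- config$origin[2] + (seq_len(d[2]) - 1) * config$spacing
    cbind(x = rep(xs, times = d[2]), y = rep(ys, each = d[1]),
          z = as.vector(config$values))
  } else if (inherits(config, "membrane_frame")) {
    p <- config$particles[config$particles$role %in% selection, ]
    cbind(x = p$x, y = p$y, z = p$z)
  } else if (is.matrix(config) && ncol(config) == 3) {
    config
  } else stop("config must be a height_field, membrane_frame, or 3-column matrix")
}

#' Multi-Map collective variable
#'
#' \deqn{\xi = \sum_k \xi_k S_k / \sum_k S_k,\qquad
#'       S_k = \sum_i \phi_k(r_i)}
#' with \eqn{\phi_k} evaluated by trilinear interpolation at each
#' contributing point. For a `height_field` the contributing points are the
#' surface sample points at the grid nodes; for a `membrane_frame` they are
#' the particles whose role is in `selection` (default head beads, the
#' mid-plane carriers). The value lies in [min label, max label] and is
#' smooth in the point positions. The functional form is isolated here so an
#' alternative similarity kernel can be swapped in one place.
#'
#' @param config `height_field`, `membrane_frame`, or n x 3 matrix of points.
#' @param maps A [density_map_set()].
#' @param selection Particle roles contributing when `config` is a frame.
#' @return The scalar xi.
#' @export
multimap_xi <- function(config, maps, selection = "head") {
  pts <- multimap_points(config, selection)
  S <- vapply(maps$maps, function(arr)
    sum(interp_map(arr, pts[, 1], pts[, 2], pts[, 3],
                   maps$spacing, maps$origin, maps$z0, maps$dz)),
    numeric(1))
  if (all(S <= 0))
    stop("configuration lies outside the support of every map; xi undefined")
  sum(maps$labels * S) / sum(S)
}

# --- fast path used by the sampler: height samples on the map's own grid ---

check_maps_grid <- function(maps, grid_n, box_l) {
  d <- dim(maps$maps[[1]])
  if (d[1] != grid_n || d[2] != grid_n ||
      abs(maps$spacing * grid_n - box_l) > 1e-6 * box_l)
    stop("density maps are not defined on the sampler grid")
  invisible(TRUE)
}

# Flatten each map to a (nx*ny) x nz matrix of vertical profiles per column.
map_column_profiles <- function(maps) {
  d <- dim(maps$maps[[1]])
  lapply(maps$maps, function(arr) matrix(arr, d[1] * d[2], d[3]))
}

# xi for grid-node surface samples h (flattened column-major, x fastest),
# using precomputed column profiles. Returns NA-free scalar or stops.
xi_from_profiles <- function(prof, maps, h) {
  nz <- ncol(prof[[1]])
  t <- (h - maps$z0) / maps$dz
  inb <- which(t >= 0 & t <= nz - 1)
  if (!length(inb))
    stop("surface lies outside the vertical extent of the maps")
  tt <- t[inb]
  i0 <- pmin(floor(tt), nz - 2)
  f <- tt - i0
  i0 <- as.integer(i0)
  S <- vapply(prof, function(P)
    sum(P[cbind(inb, i0 + 1L)] * (1 - f) + P[cbind(inb, i0 + 2L)] * f),
    numeric(1))
  if (all(S <= 0)) stop("configuration outside the support of every map")
  sum(maps$labels * S) / sum(S)
}

#' Harmonic umbrella bias on the Multi-Map variable
#'
#' @param maps A [density_map_set()].
#' @param center Bias centre \eqn{\xi_0}.
#' @param force_constant k in kcal/mol per xi^2 (> 0).
#' @return An object of class `umbrella_bias`.
#' @export
umbrella_bias <- function(maps, center, force_constant) {
  stopifnot(inherits(maps, "density_map_set"), force_constant > 0)
  structure(list(maps = maps, center = center,
                 force_constant = force_constant),
            class = "umbrella_bias")
}

#' Umbrella bias energy and its height-field gradient
#'
#' \eqn{U = \tfrac12 k(\xi - \xi_0)^2}. For a `height_field` configuration
#' the gradient with respect to the grid-node heights is attached as
#' attribute `"gradient"` (an N x N matrix); gradients with respect to
#' Fourier mode amplitudes follow by linearity of the DFT.
#'
#' @param config `height_field`, `membrane_frame` or point matrix.
#' @param maps A [density_map_set()].
#' @param center Bias centre.
#' @param force_constant k, kcal/mol per xi^2.
#' @param selection Roles used for frame configs.
#' @return Energy (kcal/mol); attribute "xi" always, "gradient" for
#'   height fields.
#' @export
bias_energy <- function(config, maps, center, force_constant,
                        selection = "head") {
  xi <- multimap_xi(config, maps, selection)
  u <- 0.5 * force_constant * (xi - center)^2
  attr(u, "xi") <- xi
  if (inherits(config, "height_field")) {
    d <- dim(config$values)
    check_ok <- d[1] == dim(maps$maps[[1]])[1] && d[2] == dim(maps$maps[[1]])[2]
    if (check_ok) {
      prof <- map_column_profiles(maps)
      h <- as.vector(config$values)
      nz <- ncol(prof[[1]])
      t <- (h - maps$z0) / maps$dz
      inb <- which(t >= 0 & t <= nz - 1)
      tt <- t[inb]
      i0 <- as.integer(pmin(floor(tt), nz - 2))
      f <- tt - i0
      S <- numeric(length(prof))
      dS <- matrix(0, length(h), length(prof))
      for (k in seq_along(prof)) {
        P <- prof[[k]]
        lo <- P[cbind(inb, i0 + 1L)]
        hi <- P[cbind(inb, i0 + 2L)]
        S[k] <- sum(lo * (1 - f) + hi * f)
        dS[inb, k] <- (hi - lo) / maps$dz
      }
      Ssum <- sum(S)
      dxi <- as.vector(dS %*% (maps$labels - xi)) / Ssum
      grad <- force_constant * (xi - center) * matrix(dxi, d[1], d[2])
      attr(u, "gradient") <- grad
    }
  }
  u
}

#' Run umbrella-sampling windows against the Helfrich surrogate
#'
#' For each window centre, runs the biased sampler and records the xi time
#' series plus the window-mean surface (used for the Helfrich-energy
#' cross-check of the reconstructed PMF). Warns when the sampled xi ranges
#' of adjacent windows overlap on fewer than 1% of samples.
#'
#' @param params A [helfrich_params()]; `n_sweeps` sets samples per window.
#' @param maps A [density_map_set()] on the sampler grid.
#' @param centers Window centres in xi.
#' @param force_constant Umbrella force constant, kcal/mol per xi^2.
#' @param burn_in Discarded sweeps per window.
#' @param seed Base seed; window w uses seed + w.
#' @param low_mode_max Passed to [sample_helfrich()].
#' @return List of `umbrella_window` objects, each with elements `center`,
#'   `force_constant`, `series`, `temperature`, `mean_field`,
#'   `accept_rate`.
#' @export
run_umbrella <- function(params, maps, centers, force_constant,
                         burn_in = 50L, seed = params$seed,
                         low_mode_max = 3L) {
  stopifnot(length(centers) >= 1, force_constant > 0)
  windows <- vector("list", length(centers))
  for (w in seq_along(centers)) {
    pw <- params
    pw$seed <- as.integer(seed + w)
    bias <- umbrella_bias(maps, centers[w], force_constant)
    fields <- sample_helfrich(pw, bias, burn_in = burn_in,
                              low_mode_max = low_mode_max)
    mean_vals <- Reduce(`+`, lapply(fields, `[[`, "values")) / length(fields)
    nb <- 4L
    blk <- split(seq_along(fields), cut(seq_along(fields), nb, labels = FALSE))
    blocks <- lapply(blk, function(ix) height_field(
      Reduce(`+`, lapply(fields[ix], `[[`, "values")) / length(ix),
      fields[[1]]$spacing))
    win <- umbrella_window(
      center = centers[w], force_constant = force_constant,
      series = attr(fields, "xi"), temperature = params$temperature,
      mean_field = height_field(mean_vals, fields[[1]]$spacing),
      accept_rate = attr(fields, "accept_rate"))
    win$mean_field_blocks <- blocks
    windows[[w]] <- win
  }
  check_window_overlap(windows)
  windows
}

#' Umbrella-window record
#'
#' @param center Window centre in xi.
#' @param force_constant Bias force constant (>= 0; 0 = unbiased window).
#' @param series Sampled xi values (non-empty).
#' @param temperature Kelvin.
#' @param mean_field Optional mean `height_field` of the window.
#' @param accept_rate Optional sampler acceptance rate.
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant, series, temperature,
                            mean_field = NULL, accept_rate = NA_real_) {
  if (force_constant < 0) stop("force_constant must be >= 0")
  if (!length(series)) stop("window series must be non-empty")
  structure(list(center = center, force_constant = force_constant,
                 series = as.numeric(series), temperature = temperature,
                 mean_field = mean_field, accept_rate = accept_rate),
            class = "umbrella_window")
}

check_window_overlap <- function(windows) {
  if (length(windows) < 2) return(invisible(TRUE))
  ord <- order(vapply(windows, `[[`, 0, "center"))
  for (a in seq_len(length(ord) - 1)) {
    s1 <- windows[[ord[a]]]$series
    s2 <- windows[[ord[a + 1]]]$series
    ov1 <- mean(s1 >= min(s2) & s1 <= max(s2))
    ov2 <- mean(s2 >= min(s1) & s2 <= max(s1))
    if (min(ov1, ov2) < 0.01)
      warning(sprintf(
        "adjacent windows %d and %d overlap on < 1%% of samples; PMF may be unreliable",
        ord[a], ord[a + 1]))
  }
  invisible(TRUE)
}

#' Window plan mirroring the production-scale setup
#'
#' The production configuration divides the target xi range into 61 umbrella
#' windows over K = 10 target maps; both numbers are configuration, not
#' hard-coded behaviour.
#'
#' @param xi_min,xi_max Range of the Multi-Map variable to cover.
#' @param n_windows Number of windows (default 61).
#' @return Numeric vector of window centres.
#' @export
default_window_plan <- function(xi_min, xi_max, n_windows = 61L) {
  stopifnot(n_windows >= 1, xi_max > xi_min)
  seq(xi_min, xi_max, length.out = n_windows)
}
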