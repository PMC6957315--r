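# Shared fixture builders. Everything is generated in code; no files.

flat_frame <- function(n = 200, box = 100, z_offset = 0, noise = 0, seed = 1) {
  spec <- bilayer_spec(n, box, vertical_noise_sd = noise, seed = seed)
  fr <- generate_bilayer(spec)
  fr$particles$z <- fr$particles$z + z_offset
  fr
}

bump_frames <- function(n_frames = 3, n = 900, box = 160, amplitude = 10,
                        width = 25, noise = 1, seed = 1) {
  surf <- gaussian_bump_field(32, box, amplitude = amplitude, width = width)
  spec <- bilayer_spec(n, box, vertical_noise_sd = noise, seed = seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    s <- spec; s$seed <- as.integer(seed + f)
    generate_bilayer(s, surf)
  })
  list(frames = frames, surface = surf)
}

# hand-built 3-map set with spatially disjoint supports (one empty column
# between them so interpolation never mixes maps), labels 1, 2, 3
disjoint_mapset <- function() {
  arr <- function(xr) {
    a <- array(0, c(12, 12, 10))
    a[xr, , ] <- 1
    a
  }
  density_map_set(list(arr(1:3), arr(5:7), arr(9:11)),
                  labels = c(1, 2, 3), spacing = 5, origin = c(0, 0),
                  z0 = -10, dz = 2)
}

# independent trilinear interpolation oracle (nested loops, periodic xy,
# zero outside z) - deliberately shares no code with the package
oracle_interp <- function(arr, pt, spacing, origin, z0, dz) {
  d <- dim(arr)
  fx <- ((pt[1] - origin[1]) / spacing) %% d[1]
  fy <- ((pt[2] - origin[2]) / spacing) %% d[2]
  tz <- (pt[3] - z0) / dz
  if (tz < 0 || tz > d[3] - 1) return(0)
  i0 <- floor(fx); j0 <- floor(fy); k0 <- min(floor(tz), d[3] - 2)
  acc <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wi <- if (di == 0) 1 - (fx - i0) else fx - i0
    wj <- if (dj == 0) 1 - (fy - j0) else fy - j0
    wk <- if (dk == 0) 1 - (tz - k0) else tz - k0
    ii <- (i0 + di) %% d[1]; jj <- (j0 + dj) %% d[2]
    acc <- acc + wi * wj * wk * arr[ii + 1, jj + 1, k0 + dk + 1]
  }
  acc
}

oracle_xi <- function(pts, maps) {
  S <- sapply(seq_along(maps$maps), function(k)
    sum(apply(pts, 1, function(p)
      oracle_interp(maps$maps[[k]], p, maps$spacing, maps$origin,
                    maps$z0, maps$dz))))
  sum(maps$labels * S) / sum(S)
}

# analytic exposed area of sphere 1 (radius R1) occluded by sphere 2
# (radius R2) at centre distance d: exposed = 4 pi R1^2 - cap area
two_sphere_exposed <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d + R1 <= R2) return(0)
  # cos of half-angle of the buried cap on sphere 1
  ca <- (d^2 + R1^2 - R2^2) / (2 * d * R1)
  cap <- 2 * pi * R1^2 * (1 - ca)
  4 * pi * R1^2 - cap
}

# random-point SASA oracle (independent of the Fibonacci engine)
mc_sasa <- function(structure, probe, n_mc = 20000, seed = 99) {
  st <- as.data.frame(structure)
  xyz <- as.matrix(st[, c("x", "y", "z")])
  rext <- st$radius + probe
  set.seed(seed)
  vapply(seq_len(nrow(st)), function(i) {
    z <- runif(n_mc, -1, 1)
    th <- runif(n_mc, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    p <- cbind(r * cos(th), r * sin(th), z) * rext[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    ok <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(st))[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      ok <- ok & d2 > rext[j]^2
    }
    4 * pi * rext[i]^2 * mean(ok)
  }, numeric(1))
}
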