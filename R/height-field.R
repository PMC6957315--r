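#' Periodic height field h(x, y)
#'
#' A height field describes the membrane mid-plane as a single-valued surface
#' z = h(x, y) on an N x N periodic grid (Monge gauge). It is the exchange
#' currency between the synthetic generators, the Helfrich sampler, the
#' Multi-Map machinery and the membrane-occlusion model.
#'
#' @param values Numeric N x N matrix of heights in Angstrom; rows index x,
#'   columns index y. All values must be finite.
#' @param spacing Grid spacing in Angstrom (one number; square cells).
#' @param origin Length-2 numeric, the (x0, y0) of grid node [1, 1].
#' @return An object of class `height_field`.
#' @export
height_field <- function(values, spacing, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("height field values must be finite numerics")
  stopifnot(length(spacing) == 1, spacing > 0, length(origin) == 2)
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<height_field> %d x %d grid, spacing %.3g A, box %.4g x %.4g A\n",
              d[1], d[2], x$spacing, d[1] * x$spacing, d[2] * x$spacing))
  cat(sprintf("  h range [%.3g, %.3g] A, rms %.3g A\n",
              min(x$values), max(x$values), sqrt(mean(x$values^2))))
  invisible(x)
}

#' Box side lengths of a height field
#' @param field A `height_field`.
#' @return Length-2 numeric (Lx, Ly) in Angstrom.
#' @export
field_box <- function(field) {
  dim(field$values) * field$spacing
}

#' Evaluate a height field at arbitrary (x, y)
#'
#' Bilinear interpolation with periodic wrapping in both axes.
#'
#' @param field A `height_field`.
#' @param x,y Coordinates in Angstrom (vectors of equal length).
#' @return Heights in Angstrom.
#' @export
eval_height <- function(field, x, y) {
  stopifnot(length(x) == length(y))
  n <- dim(field$values)
  # fractional grid coordinates, periodic
  fx <- ((x - field$origin[1]) / field$spacing) %% n[1]
  fy <- ((y - field$origin[2]) / field$spacing) %% n[2]
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0;  ty <- fy - j0
  i0 <- as.integer(i0 %% n[1]); j0 <- as.integer(j0 %% n[2])
  i1 <- (i0 + 1L) %% n[1];      j1 <- (j0 + 1L) %% n[2]
  v <- field$values
  v00 <- v[cbind(i0 + 1L, j0 + 1L)]
  v10 <- v[cbind(i1 + 1L, j0 + 1L)]
  v01 <- v[cbind(i0 + 1L, j1 + 1L)]
  v11 <- v[cbind(i1 + 1L, j1 + 1L)]
  v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
    v01 * (1 - tx) * ty + v11 * tx * ty
}

#' Gaussian-bump height field
#'
#' Convenience constructor for the radially symmetric test surface
#' h(r) = amplitude * exp(-r^2 / (2 * width^2)) centred in the box. With a
#' negative amplitude this mimics the inward membrane depression a transport
#' domain causes; the default width gives a deformation extending well beyond
#' the bump centre.
#'
#' @param grid_n Grid nodes per axis.
#' @param box_l Box side length, Angstrom.
#' @param amplitude Peak height, Angstrom (negative = depression).
#' @param width Gaussian sigma, Angstrom.
#' @param center Bump centre (x, y); default box centre.
#' @return A `height_field`.
#' @export
gaussian_bump_field <- function(grid_n, box_l, amplitude = 10, width = 40,
                                center = c(box_l / 2, box_l / 2)) {
  spacing <- box_l / grid_n
  xs <- (seq_len(grid_n) - 1) * spacing
  # minimum-image radial distance so the bump is periodic-consistent
  dx <- outer(xs - center[1], rep(1, grid_n))
  dy <- outer(rep(1, grid_n), xs - center[2])
  dx <- dx - box_l * round(dx / box_l)
  dy <- dy - box_l * round(dy / box_l)
  r2 <- dx^2 + dy^2
  height_field(amplitude * exp(-r2 / (2 * width^2)), spacing)
}

#' Write a height field as CSV (x, y, h)
#' @param field A `height_field`.
#' @param path Output file.
#' @export
write_height_csv <- function(field, path) {
  n <- dim(field$values)
  xs <- field$origin[1] + (seq_len(n[1]) - 1) * field$spacing
  ys <- field$origin[2] + (seq_len(n[2]) - 1) * field$spacing
  df <- data.frame(x = rep(xs, times = n[2]),
                   y = rep(ys, each = n[1]),
                   h = as.vector(field$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a height field from CSV (x, y, h)
#' @param path CSV file written by [write_height_csv()].
#' @return A `height_field`.
#' @export
read_height_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "h") %in% names(df)))
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  spacing <- if (length(xs) > 1) xs[2] - xs[1] else 1
  v <- matrix(NA_real_, length(xs), length(ys))
  v[cbind(match(df$x, xs), match(df$y, ys))] <- df$h
  height_field(v, spacing, origin = c(xs[1], ys[1]))
}
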