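#' Parameters of the Helfrich-Canham surrogate sampler
#'
#' The surrogate models the membrane mid-plane as a periodic height field
#' h(x, y) with energy (small-gradient Monge form)
#' \deqn{E[h] = \sum_q (A/2)\,(\kappa q^4 + \sigma q^2)\,|h_q|^2}
#' where A is the projected box area, \eqn{\kappa} the bending modulus and
#' \eqn{\sigma} the lateral tension. Sampling this energy replaces
#' molecular dynamics as the configuration source for the biased-sampling
#' machinery.
#'
#' @param kappa Bending modulus, kcal/mol (> 0).
#' @param sigma Membrane tension, mN/m (>= 0); converted internally via
#'   [tension_to_kcal()].
#' @param temperature Kelvin.
#' @param grid_n Grid nodes per axis (>= 8).
#' @param box_l Box side length, Angstrom.
#' @param n_sweeps Number of fields a sampler run returns.
#' @param seed Integer seed.
#' @return An object of class `helfrich_params`.
#' @export
helfrich_params <- function(kappa, sigma = 0, temperature = 298.15,
                            grid_n = 24, box_l = 240, n_sweeps = 200,
                            seed = 1L) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (grid_n < 8) stop("grid_n must be >= 8")
  stopifnot(box_l > 0, temperature >= 0, n_sweeps >= 1)
  structure(list(kappa = kappa, sigma = sigma, temperature = temperature,
                 grid_n = as.integer(grid_n), box_l = box_l,
                 n_sweeps = as.integer(n_sweeps), seed = as.integer(seed)),
            class = "helfrich_params")
}

# Mode bookkeeping for an N x N periodic grid. Returns, per grid entry, the
# continuum wavevector magnitude q and a classification into: the zero mode,
# self-conjugate (real) modes, and one canonical representative per +/-q pair.
helfrich_modes <- function(grid_n, box_l) {
  n <- grid_n
  idx <- 0:(n - 1)
  n_signed <- ifelse(idx > n / 2, idx - n, idx)
  qx <- 2 * pi * n_signed / box_l
  q2 <- outer(qx^2, qx^2, `+`)
  k1 <- rep(idx, times = n); k2 <- rep(idx, each = n)
  c1 <- (n - k1) %% n; c2 <- (n - k2) %% n
  lin <- k1 + n * k2; clin <- c1 + n * c2
  list(q2 = as.vector(q2),
       k1 = k1, k2 = k2, conj1 = c1, conj2 = c2,
       is_zero = lin == 0,
       is_self = lin == clin & lin != 0,
       is_rep = lin < clin)
}

# Per-mode energy coefficient c_q = kappa q^4 + sigma q^2 (sigma already in
# kcal/mol/A^2). Vector over the flattened grid.
helfrich_cq <- function(params) {
  m <- helfrich_modes(params$grid_n, params$box_l)
  sig <- tension_to_kcal(params$sigma)
  params$kappa * m$q2^2 + sig * m$q2
}

#' Helfrich-Canham bending energy of a height field
#'
#' Evaluates \eqn{E = \sum_q (A/2)(\kappa q^4 + \sigma q^2)|h_q|^2} with
#' \eqn{h_q} the discrete Fourier amplitudes of the field (convention
#' \eqn{h(r) = \sum_q h_q e^{iqr}}) and continuum wavevectors
#' \eqn{q = 2\pi n/L}. A flat field has zero energy; a single mode
#' \eqn{h = a\sin(qx)} has \eqn{E = (A a^2/4)(\kappa q^4 + \sigma q^2)}.
#'
#' @param field A `height_field` (square grid).
#' @param params A [helfrich_params()] whose grid matches the field.
#' @return Energy in kcal/mol.
#' @export
helfrich_energy <- function(field, params) {
  v <- field$values
  n <- nrow(v)
  if (ncol(v) != n) stop("helfrich_energy requires a square grid")
  if (n != params$grid_n || abs(n * field$spacing - params$box_l) >
        1e-6 * params$box_l)
    stop("field grid does not match the sampler parameters")
  hq <- stats::fft(v) / n^2
  cq <- helfrich_cq(params)
  area <- params$box_l^2
  sum((area / 2) * cq * as.vector(Mod(hq)^2))
}

#' Sample height fields from the Helfrich-Canham surrogate
#'
#' Operates on Fourier amplitudes. Without a bias the stationary density is
#' a product of independent Gaussians (equipartition:
#' \eqn{\langle|h_q|^2\rangle = k_BT/[A(\kappa q^4+\sigma q^2)]}), and the
#' sampler draws exact independent fields. With a Multi-Map umbrella bias,
#' each sweep proposes mode amplitudes from those same Gaussians and accepts
#' on the bias-energy change only (independence-Metropolis; the Gaussian
#' factor cancels exactly, so detailed balance holds for the full biased
#' density). Low-|q| modes, which carry the large-scale shape the bias acts
#' on, are updated one at a time; all remaining modes are refreshed jointly
#' in one block proposal per sweep.
#'
#' @param params A [helfrich_params()].
#' @param bias Optional [umbrella_bias()] built on maps whose xy grid
#'   matches the sampler grid.
#' @param burn_in Sweeps discarded before recording (default 0 unbiased,
#'   50 biased).
#' @param low_mode_max Largest |n| (per axis) treated as an individually
#'   updated low mode when biased.
#' @param rw_step Random-walk step for low modes, in units of each mode's
#'   thermal standard deviation.
#' @param shape_step Step of the collective shape move along the target
#'   base deformation, in amplitude units (Angstrom).
#' @return List of `height_field` (length `params$n_sweeps`). When biased,
#'   attributes `xi` (sampled collective-variable series) and
#'   `accept_rate` are attached.
#' @export
sample_helfrich <- function(params, bias = NULL,
                            burn_in = if (is.null(bias)) 0L else 50L,
                            low_mode_max = 3L, rw_step = 1, shape_step = 0.3) {
  n <- params$grid_n
  kT <- if (params$temperature > 0) kBT(params$temperature) else 0
  cq <- helfrich_cq(params)
  m <- helfrich_modes(n, params$box_l)
  area <- params$box_l^2
  # sd of the real/imaginary parts of each mode amplitude
  sd_pair <- ifelse(cq > 0, sqrt(kT / (2 * area * cq)), 0)  # x,y of a +/-q pair
  sd_self <- ifelse(cq > 0, sqrt(kT / (area * cq)), 0)      # real self-conj

  draw_modes <- function(which_rep, which_self) {
    H <- matrix(0i, n, n)
    if (any(which_rep)) {
      xr <- stats::rnorm(sum(which_rep), 0, sd_pair[which_rep])
      xi <- stats::rnorm(sum(which_rep), 0, sd_pair[which_rep])
      amp <- complex(real = xr, imaginary = xi)
      H[cbind(m$k1[which_rep] + 1L, m$k2[which_rep] + 1L)] <- amp
      H[cbind(m$conj1[which_rep] + 1L, m$conj2[which_rep] + 1L)] <- Conj(amp)
    }
    if (any(which_self)) {
      xr <- stats::rnorm(sum(which_self), 0, sd_self[which_self])
      H[cbind(m$k1[which_self] + 1L, m$k2[which_self] + 1L)] <- xr
    }
    H
  }
  to_field <- function(H) {
    height_field(Re(stats::fft(H, inverse = TRUE)), params$box_l / n)
  }

  if (is.null(bias)) {
    return(with_seed(params$seed, {
      lapply(seq_len(params$n_sweeps), function(s)
        to_field(draw_modes(m$is_rep, m$is_self)))
    }))
  }

  # --- biased sampling -------------------------------------------------
  # Moves per sweep:
  #   (a) one collective move along the target base deformation, which lets
  #       the field reach amplitudes far outside the unbiased thermal range;
  #   (b) Gaussian random-walk updates of each low-|q| mode (the carriers of
  #       the large-scale shape), accepted on the full Helfrich + bias
  #       energy change, with the Helfrich part evaluated analytically;
  #   (c) one joint refresh of all high modes drawn from their unbiased
  #       Gaussians, accepted on the bias change only (the Gaussian factor
  #       cancels, so the move is exact).
  if (kT <= 0) stop("biased sampling requires temperature > 0")
  maps <- bias$maps
  check_maps_grid(maps, n, params$box_l)
  prof <- map_column_profiles(maps)
  xi_of <- function(h) xi_from_profiles(prof, maps, as.vector(h))
  bias_u <- function(xi) 0.5 * bias$force_constant * (xi - bias$center)^2
  helf_e <- function(H) (area / 2) * sum(cq * as.vector(Mod(H)^2))

  nsig <- pmax(abs(m$k1 - ifelse(m$k1 > n / 2, n, 0)),
               abs(m$k2 - ifelse(m$k2 > n / 2, n, 0)))
  low <- nsig <= low_mode_max
  low_idx <- which((m$is_rep | m$is_self) & low)
  high_rep <- m$is_rep & !low
  high_self <- m$is_self & !low

  Bshape <- NULL
  if (!is.null(maps$base)) {
    if (all(dim(maps$base$values) == n))
      Bshape <- stats::fft(maps$base$values) / n^2
  }

  with_seed(params$seed, {
    H <- draw_modes(m$is_rep, m$is_self)
    if (!is.null(Bshape)) H <- H + bias$center * Bshape
    h <- Re(stats::fft(H, inverse = TRUE))
    xi <- xi_of(h)
    u <- bias_u(xi)
    e <- helf_e(H)
    out <- vector("list", params$n_sweeps)
    xis <- numeric(params$n_sweeps)
    acc <- 0L; tot <- 0L
    total_sweeps <- params$n_sweeps + burn_in
    for (s in seq_len(total_sweeps)) {
      # (a) collective shape move
      if (!is.null(Bshape)) {
        delta <- stats::rnorm(1, 0, shape_step)
        Hp <- H + delta * Bshape
        hp <- Re(stats::fft(Hp, inverse = TRUE))
        xip <- xi_of(hp)
        up <- bias_u(xip)
        ep <- helf_e(Hp)
        tot <- tot + 1L
        if (stats::runif(1) < exp(pmin(0, -((ep + up) - (e + u)) / kT))) {
          H <- Hp; h <- hp; xi <- xip; u <- up; e <- ep; acc <- acc + 1L
        }
      }
      # (b) low-mode random walks
      for (k in sample(low_idx)) {
        Hp <- H
        if (m$is_self[k]) {
          old <- Re(Hp[m$k1[k] + 1L, m$k2[k] + 1L])
          new <- old + stats::rnorm(1, 0, rw_step * sd_self[k])
          Hp[m$k1[k] + 1L, m$k2[k] + 1L] <- new
          dE <- (area / 2) * cq[k] * (new^2 - old^2)
        } else {
          old <- Hp[m$k1[k] + 1L, m$k2[k] + 1L]
          new <- old + complex(real = stats::rnorm(1, 0, rw_step * sd_pair[k]),
                               imaginary = stats::rnorm(1, 0, rw_step * sd_pair[k]))
          Hp[m$k1[k] + 1L, m$k2[k] + 1L] <- new
          Hp[m$conj1[k] + 1L, m$conj2[k] + 1L] <- Conj(new)
          dE <- area * cq[k] * (Mod(new)^2 - Mod(old)^2)
        }
        hp <- Re(stats::fft(Hp, inverse = TRUE))
        xip <- xi_of(hp)
        up <- bias_u(xip)
        tot <- tot + 1L
        if (stats::runif(1) < exp(pmin(0, -(dE + up - u) / kT))) {
          H <- Hp; h <- hp; xi <- xip; u <- up; e <- e + dE; acc <- acc + 1L
        }
      }
      # (c) block refresh of all high modes
      Hh <- draw_modes(high_rep, high_self)
      Hp <- H
      Hp[high_rep | high_self] <- 0i
      Hp[cbind(m$conj1[high_rep] + 1L, m$conj2[high_rep] + 1L)] <- 0i
      Hp <- Hp + Hh
      hp <- Re(stats::fft(Hp, inverse = TRUE))
      xip <- xi_of(hp)
      up <- bias_u(xip)
      tot <- tot + 1L
      if (stats::runif(1) < exp(pmin(0, -(up - u) / kT))) {
        H <- Hp; h <- hp; xi <- xip; u <- up; e <- helf_e(H); acc <- acc + 1L
      }
      if (s > burn_in) {
        out[[s - burn_in]] <- to_field(H)
        xis[s - burn_in] <- xi
      }
    }
    attr(out, "xi") <- xis
    attr(out, "accept_rate") <- acc / tot
    out
  })
}
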