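#' WHAM reconstruction of a potential of mean force
#'
#' Combines umbrella-window xi time series into one free-energy profile by
#' direct self-consistent iteration of the weighted-histogram equations,
#' stabilized with log-sum-exp:
#' \deqn{p_b \propto \frac{\sum_w N_{wb}}{\sum_w n_w e^{(f_w - U_w(\xi_b))/k_BT}},
#'       \qquad e^{-f_w/k_BT} = \sum_b p_b e^{-U_w(\xi_b)/k_BT}}
#' The PMF is \eqn{-k_BT\ln p_b}, anchored to 0 at its minimum. A single
#' unbiased window (force constant 0) reduces to
#' \eqn{-k_BT\ln(\mathrm{histogram})}. Standard errors come from a block
#' bootstrap over each window's series.
#'
#' Bins are half-open \code{[lo, hi)}; a sample on an edge belongs to the
#' lower bin boundary's bin. Bins no window populates are masked (NA). If
#' adjacent windows fail to overlap the iteration may stall; a convergence
#' warning reports the residual.
#'
#' @param windows List of [umbrella_window()] objects (same temperature).
#' @param bins Number of bins (scalar) or explicit break points covering the
#'   sampled range.
#' @param tol Convergence tolerance on the free-energy shifts, kcal/mol.
#' @param max_iter Maximum self-consistency iterations.
#' @param n_boot Bootstrap replicates for the stderr (0 disables).
#' @param n_blocks Blocks per window series in the bootstrap.
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `pmf_curve`: data.frame with columns `xi`
#'   (bin centres), `free_energy`, `stderr`, `n` (pooled counts); attributes
#'   `f_shifts` (per-window free energies, kcal/mol), `converged`,
#'   `iterations`.
#' @export
wham_pmf <- function(windows, bins = 40, tol = 1e-7, max_iter = 10000L,
                     n_boot = 20L, n_blocks = 5L, seed = 1L) {
  stopifnot(length(windows) >= 1)
  temps <- vapply(windows, `[[`, 0, "temperature")
  if (diff(range(temps)) > 1e-9)
    stop("all windows must share one temperature")
  kT <- kBT(temps[1])
  series <- lapply(windows, `[[`, "series")
  pooled <- unlist(series)
  if (length(bins) == 1) {
    rng <- range(pooled)
    pad <- 1e-9 * max(1, diff(rng))
    breaks <- seq(rng[1] - pad, rng[2] + pad, length.out = bins + 1)
  } else {
    breaks <- sort(bins)
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  W <- length(windows); B <- length(centers)
  k_w <- vapply(windows, `[[`, 0, "force_constant")
  c_w <- vapply(windows, `[[`, 0, "center")
  # bias energy of each window at each bin centre, in kT units
  Umat <- outer(seq_len(W), seq_len(B), function(w, b)
    0.5 * k_w[w] * (centers[b] - c_w[w])^2) / kT

  bin_of <- function(x) {
    ix <- findInterval(x, breaks, rightmost.closed = FALSE, left.open = FALSE)
    ix[ix < 1 | ix > B] <- NA_integer_
    ix
  }
  counts_of <- function(series_list) {
    t(vapply(series_list, function(s) {
      tab <- tabulate(bin_of(s), nbins = B)
      as.numeric(tab)
    }, numeric(B)))
  }

  lse <- function(v) { m <- max(v); if (!is.finite(m)) -Inf else m + log(sum(exp(v - m))) }

  solve_wham <- function(Nmat, f0 = rep(0, W)) {
    n_w <- rowSums(Nmat)
    tot_b <- colSums(Nmat)
    occ <- tot_b > 0
    log_num <- ifelse(occ, log(tot_b), -Inf)
    f <- f0   # in kT units
    it <- 0L; delta <- Inf
    while (it < max_iter) {
      it <- it + 1L
      # log denominator per bin: logsumexp_w [ log n_w + f_w - U_wb ]
      M <- log(n_w) + f - Umat          # W x B (recycles by column)
      mx <- apply(M, 2, max)
      log_den <- mx + log(colSums(exp(sweep(M, 2, mx))))
      log_p <- log_num - log_den
      # new shifts
      fnew <- vapply(seq_len(W), function(w)
        -lse(log_p[occ] - Umat[w, occ]), numeric(1))
      fnew <- fnew - fnew[1]
      delta <- max(abs(fnew - f)) * kT
      f <- fnew
      if (delta < tol) break
    }
    M <- log(n_w) + f - Umat
    mx <- apply(M, 2, max)
    log_p <- log_num - (mx + log(colSums(exp(sweep(M, 2, mx)))))
    pmf <- -kT * log_p
    pmf[!occ] <- NA_real_
    pmf <- pmf - min(pmf, na.rm = TRUE)
    list(pmf = pmf, f = f * kT, converged = delta < tol, iterations = it,
         delta = delta, occ = occ)
  }

  Nmat <- counts_of(series)
  main <- solve_wham(Nmat)
  if (!main$converged)
    warning(sprintf(
      "WHAM did not reach tol = %g within %d iterations (residual %.3g); check window overlap",
      tol, max_iter, main$delta))

  stderr <- rep(NA_real_, B)
  if (n_boot > 0) {
    anchor <- which.min(main$pmf)
    boots <- matrix(NA_real_, n_boot, B)
    with_seed(seed, {
      for (bt in seq_len(n_boot)) {
        res <- lapply(series, function(s) {
          nb <- min(n_blocks, length(s))
          blk <- split(s, cut(seq_along(s), nb, labels = FALSE))
          unlist(blk[sample.int(nb, nb, replace = TRUE)], use.names = FALSE)
        })
        sol <- solve_wham(counts_of(res), f0 = main$f / kT)
        p <- sol$pmf
        if (is.finite(p[anchor])) p <- p - p[anchor]
        boots[bt, ] <- p
      }
    })
    stderr <- apply(boots, 2, stats::sd, na.rm = TRUE)
  }

  out <- data.frame(xi = centers, free_energy = main$pmf, stderr = stderr,
                    n = colSums(Nmat))
  class(out) <- c("pmf_curve", "data.frame")
  attr(out, "f_shifts") <- main$f
  attr(out, "converged") <- main$converged
  attr(out, "iterations") <- main$iterations
  attr(out, "kT") <- kT
  out
}

#' @export
print.pmf_curve <- function(x, ...) {
  fin <- is.finite(x$free_energy)
  cat(sprintf("<pmf_curve> %d bins over xi in [%.4g, %.4g]\n",
              nrow(x), min(x$xi), max(x$xi)))
  cat(sprintf("  max free energy %.3g kcal/mol; mean stderr %.3g kcal/mol; converged: %s\n",
              max(x$free_energy[fin]),
              mean(x$stderr[fin], na.rm = TRUE),
              isTRUE(attr(x, "converged"))))
  invisible(x)
}

#' @export
plot.pmf_curve <- function(x, ...) {
  fin <- is.finite(x$free_energy)
  graphics::plot(x$xi[fin], x$free_energy[fin], type = "l",
                 xlab = expression(xi), ylab = "PMF (kcal/mol)", ...)
  if (any(is.finite(x$stderr[fin])))
    graphics::arrows(x$xi[fin], x$free_energy[fin] - x$stderr[fin],
                     x$xi[fin], x$free_energy[fin] + x$stderr[fin],
                     angle = 90, code = 3, length = 0.02,
                     col = "grey50")
  invisible(x)
}

#' Interpolate a PMF curve at given xi values
#' @param pmf A `pmf_curve`.
#' @param xi Values at which to interpolate (inside the binned range).
#' @return Free energies, kcal/mol.
#' @export
pmf_at <- function(pmf, xi) {
  fin <- is.finite(pmf$free_energy)
  stats::approx(pmf$xi[fin], pmf$free_energy[fin], xout = xi, rule = 2)$y
}
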