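# Independent oracles, deliberately naive: a fixed-grid classical RK4
# integrator for the drop shape system, a brute-force window scan for the
# inhibition rule, and plain trapezoid quadrature. They share no code with
# the implementation paths they check.

# Fixed-step RK4 integration of the drop shape system on a prescribed s grid.
rk4_profile <- function(gamma, delta_rho, R0, s_grid, g = 9.81) {
  kappa <- delta_rho * g / gamma * 1e-3  # 1/mm^2
  rhs <- function(y) {
    phi <- y[1]; r <- y[2]; z <- y[3]
    curv <- if (r > 1e-12) 2 / R0 + kappa * z - sin(phi) / r
            else 1 / R0 + kappa * z
    c(curv, cos(phi), sin(phi))
  }
  s0 <- s_grid[1]
  y <- c(s0 / R0, s0 - s0^3 / (6 * R0^2), s0^2 / (2 * R0))
  out <- matrix(NA_real_, length(s_grid), 3)
  out[1, ] <- y
  for (i in seq_len(length(s_grid) - 1)) {
    h <- s_grid[i + 1] - s_grid[i]
    k1 <- rhs(y)
    k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2)
    k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- y
  }
  data.frame(s = s_grid, phi = out[, 1], r = out[, 2], z = out[, 3])
}

# Exhaustive window scan for the inhibition rule: is there any window of
# >= len consecutive minima all at or above thr, and where does the earliest
# such window start?
brute_force_inhibition <- function(minima, thr = 10, len = 3) {
  n <- length(minima)
  for (start in seq_len(n - len + 1)) {
    if (all(minima[start:(start + len - 1)] >= thr)) {
      # extend check is unnecessary: a window of exactly len suffices
      return(list(inhibited = TRUE, onset = start))
    }
  }
  list(inhibited = FALSE, onset = NA_integer_)
}

# Random per-cycle minima series that often contains boundary values (exactly
# at the threshold) and near-qualifying runs of length 2.
random_minima_series <- function(n) {
  pool <- c(2, 3, 4, 9.9, 9.99, 10, 10, 10.5, 11, 12, 25)
  sample(pool, n, replace = TRUE)
}
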