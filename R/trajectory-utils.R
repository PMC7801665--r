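# Shared trajectory helpers: Gaussian series smoothing and speed estimation.

# Gaussian smoothing of a regularly sampled series, kernel truncated at 4
# sigma, renormalized at the edges so flat series stay flat.
gauss_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_samples))
  k <- exp(-0.5 * ((-half:half) / sigma_samples)^2)
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
}

#' Running speed from a trajectory
#'
#' Positions are smoothed with a Gaussian kernel (default sigma 0.1 s) and
#' speed taken as the magnitude of central-difference velocity.
#'
#' @param traj A [trajectory()].
#' @param smooth_sigma Position smoothing sigma in seconds.
#' @return Numeric vector of speeds (m/s), one per trajectory sample.
#' @export
traj_speed <- function(traj, smooth_sigma = 0.1) {
  xs <- gauss_smooth(traj$x, smooth_sigma * traj$fs)
  ys <- gauss_smooth(traj$y, smooth_sigma * traj$fs)
  n <- length(xs)
  if (n < 3) return(rep(0, n))
  vx <- c(xs[2] - xs[1], (xs[3:n] - xs[1:(n - 2)]) / 2, xs[n] - xs[n - 1])
  vy <- c(ys[2] - ys[1], (ys[3:n] - ys[1:(n - 2)]) / 2, ys[n] - ys[n - 1])
  sqrt(vx^2 + vy^2) * traj$fs
}

# Linear interpolation of trajectory coordinates at arbitrary times.
# Exploits the regular tracking clock (spacing 1/fs) instead of approx(),
# which re-validates the knot grid on every call.
traj_interp <- function(traj, at) {
  n <- length(traj$t)
  pos <- (at - traj$t[1]) * traj$fs + 1
  i0 <- pmin(pmax(floor(pos), 1), n - 1L)
  f <- pmin(pmax(pos - i0, 0), 1)
  list(x = traj$x[i0] * (1 - f) + traj$x[i0 + 1L] * f,
       y = traj$y[i0] * (1 - f) + traj$y[i0 + 1L] * f)
}

# von Mises sampler (Best & Fisher 1979); base R has no circular RNG.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}
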