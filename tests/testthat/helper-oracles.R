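# Independent oracles used across the suite. These deliberately avoid
# the package's own evaluation paths.

# HN loss by direct complex arithmetic, written out step by step
oracle_hn_loss <- function(delta_eps, tau, a, b, f) {
  w <- 2 * pi * f
  # (i w tau)^a = (w tau)^a * exp(i a pi / 2)
  mod_a <- (w * tau)^a
  re <- 1 + mod_a * cos(a * pi / 2)
  im <- mod_a * sin(a * pi / 2)
  r <- sqrt(re^2 + im^2)
  phi <- atan2(im, re)
  denom_re <- r^b * cos(b * phi)
  denom_im <- r^b * sin(b * phi)
  d2 <- denom_re^2 + denom_im^2
  delta_eps * denom_im / d2
}

# one-sided sine transform of -dphi/dt for the KWW function, integrated
# in half-period chunks of the sine with adaptive quadrature per chunk
oracle_kww_loss <- function(beta, tau, delta_eps, f) {
  vapply(f, function(fr) {
    w <- 2 * pi * fr
    g <- function(t) (beta / tau) * (t / tau)^(beta - 1) *
      exp(-(t / tau)^beta) * sin(w * t)
    total <- 0
    t_end <- tau * 60^(1 / beta)
    k <- 0
    repeat {
      t1 <- k * pi / w
      t2 <- (k + 1) * pi / w
      if (t1 >= t_end) break
      piece <- integrate(g, max(t1, 1e-300), min(t2, t_end),
                         rel.tol = 1e-10, subdivisions = 200L)$value
      total <- total + piece
      k <- k + 1
      if (k > 20 && abs(piece) < 1e-12 * abs(total)) break
      if (k > 2e5) break
    }
    delta_eps * total
  }, numeric(1))
}

# brute-force loss-peak time: dense log-grid search + parabolic refinement
oracle_tau_peak <- function(delta_eps, tau, a, b) {
  lf <- seq(log10(1 / (2 * pi * tau)) - 6, log10(1 / (2 * pi * tau)) + 6,
            length.out = 12001)
  y <- oracle_hn_loss(delta_eps, tau, a, b, 10^lf)
  i <- which.max(y)
  h <- lf[2] - lf[1]
  # three-point parabolic vertex around the discrete maximum
  lf_pk <- lf[i] + h * (y[i - 1] - y[i + 1]) /
    (2 * (y[i - 1] - 2 * y[i] + y[i + 1]))
  1 / (2 * pi * 10^lf_pk)
}

# numerical tangent-onset construction on a sampled Gaussian peak
oracle_gaussian_onset <- function(center, sigma) {
  Tg <- seq(center - 6 * sigma, center + 2 * sigma, length.out = 20001)
  y <- exp(-(Tg - center)^2 / (2 * sigma^2))
  slope <- diff(y) / diff(Tg)
  j <- which.max(slope)
  Tt <- (Tg[j] + Tg[j + 1]) / 2
  yt <- (y[j] + y[j + 1]) / 2
  Tt - yt / slope[j]
}
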