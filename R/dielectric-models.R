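# vacuum permittivity, F/m
.EPS0 <- 8.8541878128e-12

#' Define a dielectric relaxation process
#'
#' A single relaxation process described by the empirical Havriliak-Negami
#' (HN) function, or its symmetric Cole-Cole (CC) special case (`b = 1`).
#' The complex permittivity contribution is
#' \deqn{\varepsilon^*(\omega) = \frac{\Delta\varepsilon}{(1 + (i\omega\tau_{HN})^a)^b}}
#' with \eqn{\omega = 2\pi f}. Structural (alpha) relaxations are
#' asymmetric and fitted as HN; secondary (beta, gamma) relaxations are
#' symmetric and fitted as CC.
#'
#' @param label process label, one of `"alpha"`, `"alpha_prime"`, `"beta"`,
#'   `"gamma"`.
#' @param delta_eps dielectric strength (dimensionless, > 0), proportional
#'   to the number density of actively reorienting dipoles.
#' @param tau_hn HN relaxation time in seconds (> 0). Note this is not the
#'   peak time; see [tau_max()].
#' @param a symmetric broadening exponent, 0 < a <= 1.
#' @param b asymmetric broadening exponent, 0 < b <= 1.
#' @param model `"HN"` or `"CC"`. For `"CC"`, `b` is forced to 1.
#' @return An object of class `relaxation_process`.
#' @seealso [hn_loss()], [tau_max()], [composite_loss()]
#' @export
relaxation_process <- function(label = c("alpha", "alpha_prime", "beta", "gamma"),
                               delta_eps, tau_hn, a, b = 1,
                               model = c("HN", "CC")) {
  label <- match.arg(label)
  model <- match.arg(model)
  if (model == "CC") b <- 1
  stopifnot(is.finite(delta_eps), delta_eps > 0,
            is.finite(tau_hn), tau_hn > 0,
            is.finite(a), a > 0, a <= 1,
            is.finite(b), b > 0, b <= 1)
  structure(list(label = label, model = model,
                 delta_eps = delta_eps, tau_hn = tau_hn, a = a, b = b),
            class = "relaxation_process")
}

#' Define a DC conductivity term
#'
#' Loss contribution of translational motion of residual ionic impurities:
#' \eqn{\varepsilon''_{dc}(\omega) = \sigma_{dc} / (\varepsilon_0 \omega^s)}.
#' The exponent defaults to 1 (ohmic conduction).
#'
#' @param sigma_dc DC conductivity in S/m (>= 0).
#' @param s_exp frequency exponent, in (0, 1.2]; default 1.
#' @return An object of class `conductivity_term`.
#' @export
conductivity_term <- function(sigma_dc = 0, s_exp = 1) {
  stopifnot(is.finite(sigma_dc), sigma_dc >= 0,
            is.finite(s_exp), s_exp > 0, s_exp <= 1.2)
  structure(list(sigma_dc = sigma_dc, s_exp = s_exp, eps0 = .EPS0),
            class = "conductivity_term")
}

#' Construct a dielectric loss spectrum
#'
#' One temperature's dielectric loss \eqn{\varepsilon''} versus frequency.
#'
#' @param temperature temperature in K (> 0).
#' @param frequencies frequency grid in Hz, strictly increasing.
#' @param loss dielectric loss values, same length as `frequencies`.
#' @param sample_id sample identifier.
#' @param silica_wt_pct silica weight percent of the composite, in
#'   \[0, 100\].
#' @return An object of class `loss_spectrum`.
#' @export
loss_spectrum <- function(temperature, frequencies, loss,
                          sample_id = "sample", silica_wt_pct = 0) {
  stopifnot(is.finite(temperature), temperature > 0,
            length(frequencies) == length(loss),
            all(is.finite(frequencies)), all(frequencies > 0),
            all(diff(frequencies) > 0),
            silica_wt_pct >= 0, silica_wt_pct < 100 + 1e-9)
  structure(list(temperature = temperature,
                 frequencies = as.numeric(frequencies),
                 loss = as.numeric(loss),
                 sample_id = as.character(sample_id),
                 silica_wt_pct = silica_wt_pct),
            class = "loss_spectrum")
}

#' @export
print.loss_spectrum <- function(x, ...) {
  cat(sprintf("<loss_spectrum> %s (%g wt%% silica), T = %.1f K, %d frequencies [%.3g, %.3g] Hz\n",
              x$sample_id, x$silica_wt_pct, x$temperature,
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Define a KWW (stretched-exponential) loss shape
#'
#' Parameters of the Kohlrausch-Williams-Watts relaxation function
#' \eqn{\phi(t) = \exp[-(t/\tau)^{\beta}]}; `beta_kww` in (0, 1] controls
#' peak breadth (1 = narrow symmetric Debye peak, smaller values broaden
#' and skew the loss peak).
#'
#' @param beta_kww stretching exponent, in (0, 1].
#' @param tau_kww characteristic time in s (> 0).
#' @param delta_eps dielectric strength (> 0).
#' @return An object of class `kww_shape`.
#' @export
kww_shape <- function(beta_kww, tau_kww, delta_eps = 1) {
  stopifnot(is.finite(beta_kww), beta_kww > 0, beta_kww <= 1,
            is.finite(tau_kww), tau_kww > 0,
            is.finite(delta_eps), delta_eps > 0)
  structure(list(beta_kww = beta_kww, tau_kww = tau_kww,
                 delta_eps = delta_eps),
            class = "kww_shape")
}

#' Havriliak-Negami dielectric loss
#'
#' Evaluates \eqn{\varepsilon''(\omega) = -\mathrm{Im}[\Delta\varepsilon /
#' (1 + (i\omega\tau_{HN})^a)^b]} on a frequency grid (\eqn{\omega = 2\pi f}).
#'
#' @param process a [relaxation_process()].
#' @param frequencies frequencies in Hz (> 0).
#' @return Numeric vector of loss values, non-negative.
#' @export
hn_loss <- function(process, frequencies) {
  stopifnot(inherits(process, "relaxation_process"),
            all(is.finite(frequencies)))
  if (any(frequencies <= 0))
    stop("frequencies must be positive")
  omega <- 2 * pi * frequencies
  z <- (1 + (1i * omega * process$tau_hn)^process$a)^process$b
  -Im(process$delta_eps / z)
}

#' Composite dielectric loss of several processes plus conductivity
#'
#' Elementwise sum of the HN/CC losses of each process plus the DC
#' conductivity contribution \eqn{\sigma_{dc}/(\varepsilon_0 \omega^s)}.
#'
#' @param processes list of [relaxation_process()] objects (may be empty).
#' @param conductivity a [conductivity_term()], or `NULL` for none.
#' @param frequencies frequencies in Hz.
#' @return Numeric vector of total loss.
#' @export
composite_loss <- function(processes, conductivity = NULL, frequencies) {
  total <- numeric(length(frequencies))
  for (p in processes) total <- total + hn_loss(p, frequencies)
  if (!is.null(conductivity) && conductivity$sigma_dc > 0) {
    omega <- 2 * pi * frequencies
    total <- total + conductivity$sigma_dc /
      (conductivity$eps0 * omega^conductivity$s_exp)
  }
  total
}

#' Peak relaxation time of an HN process
#'
#' Converts the HN fit time \eqn{\tau_{HN}} to the loss-peak time
#' \deqn{\tau_{max} = \tau_{HN}\,
#'   \left[\sin\frac{a\pi}{2(1+b)}\right]^{-1/a}
#'   \left[\sin\frac{ab\pi}{2(1+b)}\right]^{1/a}.}
#' For a Cole-Cole process (`b = 1`) this reduces to \eqn{\tau_{HN}}.
#'
#' @param process a [relaxation_process()], or a list with `tau_hn`, `a`, `b`.
#' @return Peak relaxation time in seconds.
#' @export
tau_max <- function(process) {
  a <- process$a; b <- process$b
  process$tau_hn * sin(a * pi / (2 * (1 + b)))^(-1 / a) *
    sin(a * b * pi / (2 * (1 + b)))^(1 / a)
}

#' Invert the peak-time conversion
#'
#' Given a target loss-peak time, returns the HN time that [tau_max()]
#' maps onto it. Used by the synthetic generator so that simulated peaks
#' land exactly on a prescribed relaxation-time law.
#'
#' @param tau_peak target peak time in s.
#' @param a,b HN broadening exponents.
#' @return HN relaxation time in s.
#' @export
tau_hn_from_max <- function(tau_peak, a, b) {
  tau_peak * sin(a * pi / (2 * (1 + b)))^(1 / a) *
    sin(a * b * pi / (2 * (1 + b)))^(-1 / a)
}

#' Frequency-domain KWW loss
#'
#' Dielectric loss of the stretched-exponential relaxation function,
#' \deqn{\varepsilon''(\omega) = \Delta\varepsilon \int_0^\infty
#'   \left(-\frac{d\phi}{dt}\right)\sin(\omega t)\,dt, \qquad
#'   \phi(t) = e^{-(t/\tau)^\beta},}
#' which has no closed form for \eqn{\beta < 1} and is computed by
#' piecewise-analytic (Filon-type) integration of the sine transform:
#' \eqn{-d\phi/dt} is sampled on a log-spaced time grid dense enough for
#' about 1e-4 relative accuracy at the default density, each segment is
#' replaced by its linear interpolant, and the oscillatory integral of a
#' linear function is evaluated in closed form with series-stabilized
#' kernels. The grid spans from well below \eqn{1/\omega_{max}} to where
#' \eqn{\phi} has decayed below 1e-22, so both flanks of the peak are
#' resolved. At \eqn{\beta = 1} the result reduces to the Debye loss.
#'
#' @param shape a [kww_shape()].
#' @param frequencies frequencies in Hz (> 0).
#' @param n_per_decade time-grid density; increase (e.g. 2500) for
#'   stringent (~1e-6) accuracy at extra cost.
#' @return Numeric loss vector.
#' @export
kww_loss <- function(shape, frequencies, n_per_decade = 250) {
  stopifnot(inherits(shape, "kww_shape"),
            all(is.finite(frequencies)), all(frequencies > 0))
  beta <- shape$beta_kww
  tau <- shape$tau_kww
  omega <- 2 * pi * frequencies

  # grid limits: resolve the fastest oscillation and the full decay of phi
  t_lo <- min(1e-6 * tau, 1e-4 / max(omega))
  t_hi <- tau * 50^(1 / beta)
  decades <- log10(t_hi / t_lo)
  n <- max(64L, ceiling(decades * n_per_decade))
  tt <- exp(seq(log(t_lo), log(t_hi), length.out = n + 1L))

  # -dphi/dt = (beta/tau) (t/tau)^(beta-1) exp(-(t/tau)^beta)
  x <- tt / tau
  f <- (beta / tau) * x^(beta - 1) * exp(-x^beta)
  if (!all(is.finite(f)))
    stop("KWW quadrature failed: non-finite integrand (beta = ", beta,
         ", tau = ", tau, ")")

  t1 <- tt[-length(tt)]; t2 <- tt[-1L]
  h <- t2 - t1
  cmid <- (t1 + t2) / 2
  fbar <- (f[-length(f)] + f[-1L]) / 2
  slope <- diff(f) / h

  # per segment: int (fbar + slope*(t-c)) sin(w t) dt
  #   = fbar*h*A(u)*sin(w c) + slope*(w h^3/4)*B(u)*cos(w c),  u = w h / 2
  # A(u) = sin(u)/u, B(u) = (sin u - u cos u)/u^3, series for small u.
  out <- numeric(length(omega))
  for (k in seq_along(omega)) {
    w <- omega[k]
    u <- w * h / 2
    A <- ifelse(u < 1e-3, 1 - u^2 / 6, sin(u) / u)
    B <- ifelse(u < 1e-3, 1 / 3 - u^2 / 30, (sin(u) - u * cos(u)) / u^3)
    seg <- fbar * h * A * sin(w * cmid) + slope * (w * h^3 / 4) * B * cos(w * cmid)
    out[k] <- sum(seg)
  }
  shape$delta_eps * out
}
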