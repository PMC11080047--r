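# Temperature dependence of relaxation times: VFT and Arrhenius fits,
# kinetic glass transition, fragility, and the coupling-model
# classification of secondary relaxations.

.R_GAS <- 8.314462618  # J/(mol K)
.LN10 <- log(10)

#' VFT parameter set
#'
#' Parameters of the Vogel-Fulcher-Tammann law
#' \eqn{\tau(T) = \tau_\infty \exp[D/(T - T_0)]} with the activation
#' parameter `D` in kelvin.
#'
#' @param log10_tau_inf log10 of the pre-exponential time in s (< 0 for
#'   physical glass-formers).
#' @param T0 Vogel temperature in K (> 0).
#' @param D activation parameter in K (> 0).
#' @param se optional named vector of asymptotic standard errors.
#' @return Object of class `vft_params`.
#' @export
vft_params <- function(log10_tau_inf, T0, D, se = NULL) {
  stopifnot(is.finite(log10_tau_inf), is.finite(T0), T0 > 0,
            is.finite(D), D > 0)
  if (log10_tau_inf >= 0)
    warning("log10(tau_inf) >= 0: pre-exponential time is unphysically slow")
  structure(list(log10_tau_inf = log10_tau_inf, T0 = T0, D = D, se = se),
            class = "vft_params")
}

#' @export
print.vft_params <- function(x, ...) {
  cat(sprintf("<vft_params> log10(tau_inf/s) = %.3f, T0 = %.2f K, D = %.1f K\n",
              x$log10_tau_inf, x$T0, x$D))
  invisible(x)
}

#' Evaluate the VFT law
#'
#' @param params a [vft_params()].
#' @param T_K temperatures in K (> T0).
#' @return Relaxation times in s.
#' @export
vft_tau <- function(params, T_K) {
  stopifnot(all(T_K > params$T0))
  10^(params$log10_tau_inf + params$D / (.LN10 * (T_K - params$T0)))
}

#' Arrhenius parameter set
#'
#' Parameters of \eqn{\tau(T) = \tau_\infty \exp[E_a/(RT)]} describing
#' thermally activated secondary relaxations in the glassy state.
#'
#' @param log10_tau_inf log10 of the pre-exponential time in s.
#' @param Ea activation energy in kJ/mol (> 0).
#' @param se optional named vector of standard errors.
#' @return Object of class `arrhenius_params`.
#' @export
arrhenius_params <- function(log10_tau_inf, Ea, se = NULL) {
  stopifnot(is.finite(log10_tau_inf), is.finite(Ea), Ea > 0)
  structure(list(log10_tau_inf = log10_tau_inf, Ea = Ea, R = .R_GAS, se = se),
            class = "arrhenius_params")
}

#' @export
print.arrhenius_params <- function(x, ...) {
  cat(sprintf("<arrhenius_params> log10(tau_inf/s) = %.3f, Ea = %.2f kJ/mol\n",
              x$log10_tau_inf, x$Ea))
  invisible(x)
}

#' Evaluate the Arrhenius law
#'
#' @param params an [arrhenius_params()].
#' @param T_K temperatures in K.
#' @return Relaxation times in s.
#' @export
arrhenius_tau <- function(params, T_K) {
  10^(params$log10_tau_inf + params$Ea * 1000 / (.LN10 * params$R * T_K))
}

#' Fit the VFT law to structural relaxation times
#'
#' Least squares on \eqn{\log_{10}\tau = \log_{10}\tau_\infty +
#' D/(\ln 10 \,(T - T_0))}. For fixed `T0` the model is linear in the
#' other two parameters, so the fit profiles the residual sum of squares
#' over `T0` (golden-section search on (0, min(T) - 1)), which is
#' deterministic and immune to poor nonlinear starts; asymptotic standard
#' errors come from the Jacobian at the optimum.
#'
#' @param T_K temperatures in K (>= 4 points).
#' @param tau_s relaxation times in s, spanning at least 2 decades.
#' @return A [vft_params()] with standard errors in `$se`.
#' @export
fit_vft <- function(T_K, tau_s) {
  stopifnot(length(T_K) == length(tau_s), length(T_K) >= 4,
            all(tau_s > 0))
  if (diff(range(log10(tau_s))) < 2)
    warning("relaxation times span fewer than 2 decades; VFT fit ill-conditioned")
  y <- log10(tau_s)
  rss <- function(T0) {
    x <- 1 / (.LN10 * (T_K - T0))
    sum(lm(y ~ x)$residuals^2)
  }
  upper <- min(T_K) - 1e-3
  opt <- optimize(rss, interval = c(1, upper), tol = 1e-8)
  T0 <- opt$minimum
  # refine near the boundary if needed
  if (upper - T0 < 1e-2) {
    warning("fitted T0 within 0.01 K of the lowest data temperature")
  }
  x <- 1 / (.LN10 * (T_K - T0))
  lf <- lm(y ~ x)
  cf <- coef(lf)
  pars <- c(cf[[1]], T0, cf[[2]])
  # asymptotic covariance from the full 3-parameter Jacobian
  J <- cbind(1, pars[3] / (.LN10 * (T_K - pars[2])^2),
             1 / (.LN10 * (T_K - pars[2])))
  r <- y - (pars[1] + pars[3] / (.LN10 * (T_K - pars[2])))
  dof <- max(length(T_K) - 3, 1)
  s2 <- sum(r^2) / dof
  cv <- try(s2 * solve(crossprod(J)), silent = TRUE)
  se <- if (inherits(cv, "try-error")) NULL else
    setNames(sqrt(pmax(diag(cv), 0)), c("log10_tau_inf", "T0", "D"))
  vft_params(pars[1], pars[2], pars[3], se = se)
}

#' Kinetic glass transition temperature from a VFT fit
#'
#' Inverts the VFT law in closed form for a target relaxation time
#' (convention: \eqn{T_g = T(\tau_\alpha = 100\,\mathrm{s})}):
#' \deqn{T_g = T_0 + \frac{D}{\ln 10\,(\log_{10}\tau_g - \log_{10}\tau_\infty)}.}
#'
#' @param params a [vft_params()].
#' @param tau_g target relaxation time in s (default 100).
#' @return Temperature in K.
#' @export
tg_from_tau <- function(params, tau_g = 100) {
  lt <- log10(tau_g)
  if (lt <= params$log10_tau_inf)
    stop("tau_g must exceed the pre-exponential time")
  params$T0 + params$D / (.LN10 * (lt - params$log10_tau_inf))
}

#' Fragility (steepness index) of a glass-former
#'
#' The steepness index is the slope of \eqn{\log_{10}\tau_\alpha} versus
#' \eqn{T_g/T} at \eqn{T = T_g}; for the VFT law in the kelvin-D
#' parameterization,
#' \deqn{m_p = \frac{D}{\ln 10}\frac{T_g}{(T_g - T_0)^2}.}
#' Physical glass-formers fall between about 16 (strong) and 200
#' (fragile); a warning is emitted outside that range.
#'
#' @param params a [vft_params()].
#' @param Tg glass transition temperature in K (> T0), e.g. from
#'   [tg_from_tau()].
#' @return Object of class `fragility_result`: list with `m_p`, `Tg_used`.
#' @export
fragility <- function(params, Tg) {
  if (Tg <= params$T0) stop("Tg must exceed the Vogel temperature T0")
  m_p <- (params$D / .LN10) * Tg / (Tg - params$T0)^2
  if (m_p < 16 || m_p > 200)
    warning(sprintf("steepness index %.1f outside the typical 16-200 range", m_p))
  structure(list(m_p = m_p, Tg_used = Tg), class = "fragility_result")
}

#' Fit the Arrhenius law to secondary relaxation times
#'
#' Linear least squares of \eqn{\log_{10}\tau} versus \eqn{1/T}; the
#' activation energy is `slope * ln(10) * R`, reported in kJ/mol.
#'
#' @param T_K temperatures in K (>= 3 points with spread).
#' @param tau_s relaxation times in s.
#' @return An [arrhenius_params()] with standard errors in `$se`.
#' @export
fit_arrhenius <- function(T_K, tau_s) {
  stopifnot(length(T_K) == length(tau_s), length(T_K) >= 2,
            all(tau_s > 0))
  if (diff(range(T_K)) < 1e-6) stop("degenerate temperature spread")
  invT <- 1 / T_K
  fit <- lm(log10(tau_s) ~ invT)
  cf <- coef(fit)
  Ea_kJ <- cf[[2]] * .LN10 * .R_GAS / 1000
  se <- if (length(T_K) > 2) {
    sm <- suppressWarnings(sqrt(diag(vcov(fit))))
    setNames(c(sm[1], sm[2] * .LN10 * .R_GAS / 1000), c("log10_tau_inf", "Ea"))
  } else NULL
  arrhenius_params(cf[[1]], Ea_kJ, se = se)
}

#' Coupling-model primitive relaxation time
#'
#' The coupling model relates the Johari-Goldstein secondary relaxation
#' to the structural one through the primitive relaxation time
#' \deqn{\tau_0 = t_c^{\,n}\,\tau_\alpha^{\,1-n}, \qquad n = 1 - \beta_{KWW},}
#' with the crossover time \eqn{t_c = 2\,\mathrm{ps}} for small organic
#' molecules.
#'
#' @param tau_alpha structural relaxation time(s) in s (> 0).
#' @param beta_kww stretching exponent in (0, 1].
#' @param t_c onset time of intermolecular coupling in s (default 2e-12).
#' @return Primitive relaxation time(s) in s.
#' @export
primitive_relaxation_time <- function(tau_alpha, beta_kww, t_c = 2e-12) {
  stopifnot(all(tau_alpha > 0), beta_kww > 0, beta_kww <= 1)
  n <- 1 - beta_kww
  t_c^n * tau_alpha^beta_kww
}

#' Classify a secondary relaxation as Johari-Goldstein or not
#'
#' Compares the coupling-model prediction \eqn{\tau_0(T)} (computed from
#' the structural relaxation times above Tg) with the Arrhenius
#' extrapolation of the secondary process measured in the glass: if the
#' mean absolute log10 distance over the structural-point temperatures is
#' within `tolerance_decades`, the secondary relaxation is the
#' continuation of the primitive relaxation and is classified JG
#' (a whole-molecule precursor of structural relaxation); otherwise
#' non-JG (intramolecular).
#'
#' @param secondary_fit [arrhenius_params()] of the secondary process.
#' @param alpha_T,alpha_tau temperatures (K) and structural relaxation
#'   times (s) above Tg.
#' @param beta_kww stretching exponent of the structural peak.
#' @param tolerance_decades decision threshold (default 1.0).
#' @param t_c coupling crossover time in s.
#' @return Object of class `coupling_result`: list with `n`, `t_c`,
#'   `tau_0` (per temperature), `mean_abs_dlog10`, `classification`
#'   (`"JG"` or `"non_JG"`).
#' @export
classify_secondary <- function(secondary_fit, alpha_T, alpha_tau, beta_kww,
                               tolerance_decades = 1.0, t_c = 2e-12) {
  stopifnot(inherits(secondary_fit, "arrhenius_params"),
            length(alpha_T) == length(alpha_tau))
  if (length(alpha_T) == 0) stop("no structural relaxation points supplied")
  tau0 <- primitive_relaxation_time(alpha_tau, beta_kww, t_c)
  tau_sec <- arrhenius_tau(secondary_fit, alpha_T)
  d <- mean(abs(log10(tau0) - log10(tau_sec)))
  structure(list(n = 1 - beta_kww, t_c = t_c,
                 tau_0 = setNames(tau0, alpha_T),
                 mean_abs_dlog10 = d,
                 classification = if (d <= tolerance_decades) "JG" else "non_JG"),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> n = %.3f, mean |dlog10 tau| = %.2f -> %s\n",
              x$n, x$mean_abs_dlog10, x$classification))
  invisible(x)
}

#' Assemble a relaxation-map report
#'
#' Convenience aggregator: fits VFT to the structural process, Arrhenius
#' to each secondary process, derives Tg and fragility, and classifies
#' the secondary processes with the coupling model.
#'
#' @param points `data.frame` with columns `label`, `T_K`, `tau_s` (e.g.
#'   from [extract_relaxation_points()]).
#' @param beta_kww stretching exponent of the structural peak (used for
#'   the coupling model).
#' @param tau_g Tg convention in s (default 100).
#' @param t_c coupling crossover time in s.
#' @param tolerance_decades JG classification threshold.
#' @param n_coupling number of structural points, counted from the
#'   lowest temperature, used in the coupling-model comparison: the
#'   continuity of the primitive relaxation with a measured secondary
#'   process is meaningful where the structural and secondary branches
#'   meet (just above Tg), not deep in the liquid where all fast
#'   processes crowd together on a log scale.
#' @return Object of class `relaxation_map`: list with `vft`, `Tg`,
#'   `fragility`, `arrhenius` (named list), `coupling` (named list),
#'   `points`.
#' @export
relaxation_map <- function(points, beta_kww = NULL, tau_g = 100,
                           t_c = 2e-12, tolerance_decades = 1.0,
                           n_coupling = 5) {
  stopifnot(all(c("label", "T_K", "tau_s") %in% names(points)))
  alpha <- points[points$label == "alpha", ]
  if (nrow(alpha) < 4) stop("need >= 4 structural (alpha) points")
  alpha <- alpha[order(alpha$T_K), ]
  vft <- fit_vft(alpha$T_K, alpha$tau_s)
  Tg <- tg_from_tau(vft, tau_g)
  frag <- fragility(vft, Tg)
  cmp <- alpha[seq_len(min(n_coupling, nrow(alpha))), ]
  arr <- list(); cpl <- list()
  for (lab in intersect(unique(points$label), c("beta", "gamma"))) {
    sub <- points[points$label == lab, ]
    arr[[lab]] <- fit_arrhenius(sub$T_K, sub$tau_s)
    if (!is.null(beta_kww))
      cpl[[lab]] <- classify_secondary(arr[[lab]], cmp$T_K, cmp$tau_s,
                                       beta_kww, tolerance_decades, t_c)
  }
  structure(list(vft = vft, Tg = Tg, fragility = frag,
                 arrhenius = arr, coupling = cpl, points = points),
            class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  print(x$vft)
  cat(sprintf("  Tg(tau = 100 s) = %.1f K, m_p = %.1f\n",
              x$Tg, x$fragility$m_p))
  for (lab in names(x$arrhenius)) {
    cat(sprintf("  %s: Ea = %.1f kJ/mol", lab, x$arrhenius[[lab]]$Ea))
    if (!is.null(x$coupling[[lab]]))
      cat(sprintf(" [%s]", x$coupling[[lab]]$classification))
    cat("\n")
  }
  invisible(x)
}
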