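# Deconvolution of measured loss spectra into conductivity + HN/CC
# processes, extraction of per-process (T, tau, delta_eps), dielectric
# strength normalization and recrystallization onset detection.

#' Describe which processes to fit in a loss spectrum
#'
#' A fit plan names the active relaxation processes, fixes their model
#' class (alpha and alpha_prime are asymmetric HN, beta and gamma are
#' symmetric CC), and optionally supplies starting values, bounds or
#' frozen shape parameters.
#'
#' @param processes character vector of process labels in order of
#'   decreasing relaxation time (slowest first), from
#'   `c("alpha", "alpha_prime", "beta", "gamma")`.
#' @param conductivity logical; include a DC conductivity term?
#' @param init optional named list of per-process starting values, each a
#'   list with any of `delta_eps`, `tau_hn`, `a`, `b` (e.g.
#'   `list(alpha = list(tau_hn = 1e-3))`). Unspecified values are
#'   initialized from the data.
#' @param fixed optional named list, same layout as `init`, of parameters
#'   to hold fixed during the fit (used e.g. to pin the alpha-prime shape
#'   to the last pre-crystallization alpha fit).
#' @param s_exp conductivity exponent (fixed during the fit).
#' @return An object of class `fit_plan`.
#' @export
fit_plan <- function(processes = "alpha", conductivity = FALSE,
                     init = list(), fixed = list(), s_exp = 1) {
  processes <- match.arg(processes,
                         c("alpha", "alpha_prime", "beta", "gamma"),
                         several.ok = TRUE)
  if (anyDuplicated(processes)) stop("duplicate process labels in plan")
  structure(list(processes = processes, conductivity = conductivity,
                 init = init, fixed = fixed, s_exp = s_exp),
            class = "fit_plan")
}

# model class per label: alpha-type are HN (b free), secondary are CC
.model_for_label <- function(label) {
  if (label %in% c("alpha", "alpha_prime")) "HN" else "CC"
}

# deterministic data-driven starts: local maxima of the lightly smoothed
# log-loss, assigned slowest-process-first; fall back to log-spaced
# positions when fewer maxima than processes are found.
.init_guesses <- function(spectrum, plan) {
  f <- spectrum$frequencies
  y <- spectrum$loss
  if (isTRUE(plan$conductivity)) {
    # remove an ohmic-slope conductivity estimate anchored at the lowest
    # frequency before peak finding, so buried relaxation peaks surface
    cond_est <- 0.95 * y[1] * (f / f[1])^(-plan$s_exp)
    y <- pmax(y - cond_est, 1e-6 * max(y))
  }
  ok <- y > 0
  logy <- log10(pmax(y, 1e-300))
  n <- length(f)
  sm <- stats::filter(logy, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- logy[is.na(sm)]
  maxima <- which(diff(sign(diff(sm))) < 0) + 1L
  maxima <- maxima[ok[maxima]]
  maxima <- maxima[order(f[maxima])]         # slowest first
  np <- length(plan$processes)

  # candidate (tau, delta_eps) starts, slowest first: every resolved
  # local maximum; a below-window candidate when the low-frequency edge
  # falls before the first maximum (a slower process entering from the
  # left); an above-window candidate as the fastest filler.
  # processes whose tau is supplied by the user (or pinned) do not
  # consume data-driven candidates
  has_user_tau <- vapply(plan$processes, function(lab)
    !is.null(plan$init[[lab]]$tau_hn) || !is.null(plan$fixed[[lab]]$tau_hn),
    logical(1))
  n_need <- sum(!has_user_tau)
  cand <- lapply(maxima, function(j)
    list(tau_hn = 1 / (2 * pi * f[j]), delta_eps = max(2 * y[j], 1e-6)))
  if (length(cand) < n_need) {
    first_max <- if (length(maxima)) maxima[1] else n
    falling_edge <- all(diff(sm[seq_len(min(5L, n))]) < 0) && first_max > 5L
    if (falling_edge)
      cand <- c(list(list(tau_hn = 3 / (2 * pi * f[1]),
                          delta_eps = max(2 * y[1], 1e-6))), cand)
  }
  if (length(cand) < n_need) {
    # fast shoulders hidden under a flank: spread the missing guesses in
    # log frequency between the last resolved maximum and the window top
    k <- n_need - length(cand)
    lo_lf <- if (length(maxima)) log10(f[max(maxima)]) else log10(f[1])
    fill_lf <- lo_lf + seq_len(k) / (k + 1) * (log10(f[n]) - lo_lf)
    for (lf in fill_lf) {
      yy <- approx(log10(f), y, xout = lf)$y
      cand <- c(cand, list(list(tau_hn = 1 / (2 * pi * 10^lf),
                                delta_eps = max(2 * yy, 1e-6))))
    }
  }
  # keep candidate order slowest-first
  cand <- cand[order(-vapply(cand, function(g) g$tau_hn, numeric(1)))]

  out <- list()
  k <- 0L
  for (i in seq_len(np)) {
    lab <- plan$processes[i]
    if (has_user_tau[[lab]]) {
      tau_known <- if (!is.null(plan$init[[lab]]$tau_hn))
        plan$init[[lab]]$tau_hn else plan$fixed[[lab]]$tau_hn
      f_pk <- min(max(1 / (2 * pi * tau_known), f[1]), f[n])
      g <- list(tau_hn = tau_known,
                delta_eps = max(2 * approx(f, y, xout = f_pk)$y, 1e-6))
    } else {
      k <- k + 1L
      g <- cand[[k]]
    }
    g$a <- 0.8
    g$b <- if (.model_for_label(lab) == "HN") 0.8 else 1
    usr <- plan$init[[lab]]
    if (!is.null(usr)) g[names(usr)] <- usr
    out[[lab]] <- g
  }
  out
}

#' Fit a loss spectrum with HN/CC processes plus conductivity
#'
#' Weighted least squares in log10 loss versus log frequency (uniform
#' weights; points with non-positive measured loss are masked).
#' Structural processes are fitted as HN with `b` free; secondary
#' processes as CC (`b = 1`). Positivity is enforced by fitting
#' log-transformed `delta_eps`, `tau_hn` and `sigma_dc`; `a` and `b` are
#' bounded in (0, 1]. Starting values are deterministic and data-driven
#' (peak positions of the smoothed spectrum) unless overridden in the
#' plan.
#'
#' @param spectrum a [loss_spectrum()].
#' @param plan a [fit_plan()].
#' @return An object of class `spectrum_fit`: list with `temperature`,
#'   `components` (named list of fitted [relaxation_process()] objects),
#'   `conductivity`, `eps_inf` (carried metadata, not fitted),
#'   `residual_rms` (in log10 loss), `converged`, `sample_id`,
#'   `silica_wt_pct`.
#' @export
fit_loss_spectrum <- function(spectrum, plan) {
  stopifnot(inherits(spectrum, "loss_spectrum"), inherits(plan, "fit_plan"))
  if (length(plan$processes) < 1) stop("plan names no process")
  mask <- spectrum$loss > 0
  f <- spectrum$frequencies[mask]
  y <- log10(spectrum$loss[mask])
  guesses <- .init_guesses(spectrum, plan)

  # build parameter vector: per process log10(delta_eps), log10(tau), a, (b)
  par <- c(); lower <- c(); upper <- c(); names_par <- c()
  for (lab in plan$processes) {
    g <- guesses[[lab]]
    fx <- plan$fixed[[lab]]
    for (nm in c("delta_eps", "tau_hn", "a", "b")) {
      if (nm == "b" && .model_for_label(lab) == "CC") next
      if (!is.null(fx) && nm %in% names(fx)) next
      pname <- paste(lab, nm, sep = ".")
      if (nm %in% c("delta_eps", "tau_hn")) {
        par <- c(par, log10(g[[nm]])); lower <- c(lower, -30); upper <- c(upper, 30)
      } else {
        par <- c(par, g[[nm]]); lower <- c(lower, 0.05); upper <- c(upper, 1)
      }
      names_par <- c(names_par, pname)
    }
  }
  if (plan$conductivity) {
    # init sigma from the lowest-frequency point
    sig0 <- max(spectrum$loss[1], 1e-8) * .EPS0 * (2 * pi * f[1])^plan$s_exp
    par <- c(par, log10(sig0)); lower <- c(lower, -30); upper <- c(upper, 5)
    names_par <- c(names_par, "sigma.log10")
  }
  names(par) <- names_par
  if (length(f) < length(par) + 1)
    stop("fewer usable frequency points than free parameters")
  if (length(f) < 8) stop("need at least 8 frequency points")

  build <- function(p) {
    comps <- list()
    for (lab in plan$processes) {
      g <- guesses[[lab]]; fx <- plan$fixed[[lab]]
      get1 <- function(nm, log10scale = FALSE) {
        pname <- paste(lab, nm, sep = ".")
        if (!is.null(fx) && nm %in% names(fx)) return(fx[[nm]])
        v <- p[[pname]]
        if (log10scale) 10^v else v
      }
      mdl <- .model_for_label(lab)
      comps[[lab]] <- relaxation_process(
        lab,
        delta_eps = get1("delta_eps", TRUE),
        tau_hn = get1("tau_hn", TRUE),
        a = get1("a"),
        b = if (mdl == "CC") 1 else get1("b"),
        model = mdl)
    }
    cond <- if (plan$conductivity)
      conductivity_term(10^p[["sigma.log10"]], plan$s_exp)
    else conductivity_term(0)
    list(components = comps, conductivity = cond)
  }
  resid_fn <- function(p) {
    m <- build(as.list(p))
    mod <- composite_loss(m$components, m$conductivity, f)
    log10(pmax(mod, 1e-300)) - y
  }
  fit <- try(minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                                fn = resid_fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
             silent = TRUE)
  converged <- !inherits(fit, "try-error") && fit$info %in% 1:4
  p_hat <- if (inherits(fit, "try-error")) as.list(par) else as.list(coef(fit))
  m <- build(p_hat)
  res <- resid_fn(unlist(p_hat))
  structure(list(temperature = spectrum$temperature,
                 components = m$components,
                 conductivity = m$conductivity,
                 eps_inf = NA_real_,
                 residual_rms = sqrt(mean(res^2)),
                 converged = converged,
                 sample_id = spectrum$sample_id,
                 silica_wt_pct = spectrum$silica_wt_pct),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("<spectrum_fit> T = %.1f K, %s, rms(log10) = %.3g%s\n",
              x$temperature, paste(names(x$components), collapse = "+"),
              x$residual_rms, if (x$converged) "" else " [NOT CONVERGED]"))
  for (lab in names(x$components)) {
    p <- x$components[[lab]]
    cat(sprintf("  %-11s %s  d_eps=%.4g tau_HN=%.4g s a=%.3f b=%.3f (tau_max=%.4g s)\n",
                lab, p$model, p$delta_eps, p$tau_hn, p$a, p$b, tau_max(p)))
  }
  if (x$conductivity$sigma_dc > 0)
    cat(sprintf("  conductivity sigma_dc=%.4g S/m\n", x$conductivity$sigma_dc))
  invisible(x)
}

#' Tabulate relaxation times and strengths from spectrum fits
#'
#' Applies the peak-time conversion ([tau_max()]) to every fitted
#' component and returns a per-process table sorted by temperature.
#' Unconverged fits are excluded with a warning.
#'
#' @param fits list of [fit_loss_spectrum()] results.
#' @return `data.frame` with columns `label`, `T_K`, `tau_s`,
#'   `delta_eps`, `a`, `b`, `residual_rms`.
#' @export
extract_relaxation_points <- function(fits) {
  keep <- vapply(fits, function(x) isTRUE(x$converged), logical(1))
  if (any(!keep))
    warning(sum(!keep), " unconverged fit(s) excluded")
  fits <- fits[keep]
  rows <- do.call(rbind, lapply(fits, function(x) {
    do.call(rbind, lapply(x$components, function(p) {
      data.frame(label = p$label, T_K = x$temperature,
                 tau_s = tau_max(p), delta_eps = p$delta_eps,
                 a = p$a, b = p$b, residual_rms = x$residual_rms,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(rows))
    return(data.frame(label = character(), T_K = numeric(),
                      tau_s = numeric(), delta_eps = numeric(),
                      a = numeric(), b = numeric(),
                      residual_rms = numeric()))
  rows <- rows[order(rows$label, rows$T_K), ]
  rownames(rows) <- NULL
  rows
}

#' Construct a dielectric-strength series
#'
#' @param label process label.
#' @param T_K temperatures in K.
#' @param delta_eps dielectric strengths (> 0), same length.
#' @param T_ref normalization reference temperature in K (default 312).
#' @return An object of class `delta_eps_series`.
#' @export
delta_eps_series <- function(label, T_K, delta_eps, T_ref = 312) {
  stopifnot(length(T_K) == length(delta_eps), all(delta_eps > 0))
  o <- order(T_K)
  structure(list(label = label, T_K = as.numeric(T_K[o]),
                 delta_eps = as.numeric(delta_eps[o]),
                 normalized = NULL, T_ref = T_ref),
            class = "delta_eps_series")
}

#' Normalize a dielectric-strength series to a reference temperature
#'
#' Computes \eqn{\Delta\varepsilon_N(T) =
#' \Delta\varepsilon(T)/\Delta\varepsilon(T_{ref})}; the reference value
#' is linearly interpolated when `T_ref` is not a grid point. The
#' temperature dependence of the normalized strength tracks the amorphous
#' fraction, so its drop marks recrystallization.
#'
#' @param series a [delta_eps_series()].
#' @param T_ref reference temperature in K; defaults to the series'
#'   stored reference (312 K unless set otherwise).
#' @return The series with the `normalized` field filled in.
#' @export
normalize_delta_eps <- function(series, T_ref = series$T_ref) {
  stopifnot(inherits(series, "delta_eps_series"))
  if (T_ref < min(series$T_K) || T_ref > max(series$T_K))
    stop("T_ref = ", T_ref, " K outside the series temperature range")
  ref <- approx(series$T_K, series$delta_eps, xout = T_ref)$y
  series$normalized <- series$delta_eps / ref
  series$T_ref <- T_ref
  series
}

#' Detect a recrystallization onset from a dielectric-strength series
#'
#' Recrystallization removes reorienting dipoles and shows up as a drop
#' of \eqn{\Delta\varepsilon_N} below its plateau. The plateau level is
#' estimated iteratively as the median of the points that stay within
#' `drop_threshold` of it; the onset is the first temperature at which
#' the series crosses below `(1 - drop_threshold) * plateau`, refined by
#' linear interpolation between the bracketing grid points. The detector
#' is invariant to a positive rescaling of the whole series.
#'
#' @param series a [delta_eps_series()] (normalized or not; raw strengths
#'   are normalized internally by the plateau).
#' @param drop_threshold fractional drop defining the onset (default 0.05).
#' @return Onset temperature in K, or `NA` (with a warning) if no drop is
#'   found.
#' @export
detect_recrystallization_onset <- function(series, drop_threshold = 0.05) {
  stopifnot(inherits(series, "delta_eps_series"))
  y <- if (!is.null(series$normalized)) series$normalized else series$delta_eps
  Tv <- series$T_K
  if (length(y) < 5) stop("need at least 5 points")
  plateau <- median(y)
  for (i in 1:20) {
    keep <- y >= (1 - drop_threshold) * plateau
    new_plateau <- median(y[keep])
    if (isTRUE(all.equal(new_plateau, plateau))) break
    plateau <- new_plateau
  }
  level <- (1 - drop_threshold) * plateau
  below <- which(y < level)
  if (length(below) == 0) {
    warning("no drop below the plateau detected")
    return(NA_real_)
  }
  j <- below[1]
  if (j == 1) return(Tv[1])
  # linear interpolation of the crossing
  Tv[j - 1] + (Tv[j] - Tv[j - 1]) * (y[j - 1] - level) / (y[j - 1] - y[j])
}
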