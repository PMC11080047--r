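# Time-temperature superposition of alpha-relaxation peaks and KWW shape
# analysis of the resulting master curve.

# parabolic (log10 f, loss) refinement of a discrete peak using the 5
# points around the maximum; returns c(log10_f_peak, height) or NULL when
# the maximum sits too close to the window edge.
.refine_peak <- function(frequencies, loss, halfwidth = 2L) {
  i <- which.max(loss)
  n <- length(loss)
  if (i <= halfwidth || i > n - halfwidth) return(NULL)
  idx <- (i - halfwidth):(i + halfwidth)
  x <- log10(frequencies[idx]) - log10(frequencies[i])  # centered abscissa
  fit <- lm(loss[idx] ~ x + I(x^2))
  cf <- coef(fit)
  if (!is.finite(cf[3]) || cf[3] >= 0)
    return(c(log10(frequencies[i]), loss[i]))
  xp <- unname(-cf[2] / (2 * cf[3]))
  c(log10(frequencies[i]) + xp,
    unname(cf[1] + cf[2] * xp + cf[3] * xp^2))
}

#' Build a master curve by horizontal shifting of loss spectra
#'
#' Superimposes structural-relaxation peaks measured at different
#' temperatures onto the spectrum at `T_ref` by horizontal shifts in
#' log10 frequency; each spectrum's peak position (parabolic fit through
#' the five points around the discrete maximum) is aligned with the
#' reference peak and amplitudes are normalized to unit peak height.
#' Only horizontal shifts are applied, so collapse of the curves tests
#' whether the peak shape is temperature-invariant.
#'
#' @param spectra list of [loss_spectrum()] objects, each with a
#'   resolvable loss maximum inside its frequency window. Spectra whose
#'   maximum sits at the window edge are excluded with a warning.
#' @param T_ref reference temperature in K (default 312); must match one
#'   spectrum's temperature.
#' @return An object of class `master_curve`: list with `T_ref`, `shifts`
#'   (`data.frame` of `T_K`, `log10_shift`), and `merged` (`data.frame`
#'   of `log10_f_reduced`, `eps_norm`, `T_K`, sorted by reduced
#'   frequency).
#' @export
build_masterplot <- function(spectra, T_ref = 312) {
  temps <- vapply(spectra, function(s) s$temperature, numeric(1))
  iref <- which(abs(temps - T_ref) < 1e-6)
  if (length(iref) != 1)
    stop("exactly one spectrum must be at T_ref = ", T_ref, " K")
  ref_peak <- .refine_peak(spectra[[iref]]$frequencies, spectra[[iref]]$loss)
  if (is.null(ref_peak)) stop("reference spectrum peak is at the window edge")

  shifts <- data.frame(T_K = numeric(), log10_shift = numeric())
  merged <- NULL
  for (s in spectra) {
    pk <- .refine_peak(s$frequencies, s$loss)
    if (is.null(pk)) {
      warning(sprintf("spectrum at %.1f K excluded: peak at window edge",
                      s$temperature))
      next
    }
    shift <- ref_peak[1] - pk[1]
    shifts <- rbind(shifts, data.frame(T_K = s$temperature,
                                       log10_shift = shift))
    merged <- rbind(merged, data.frame(
      log10_f_reduced = log10(s$frequencies) + shift,
      eps_norm = s$loss / pk[2],
      T_K = s$temperature))
  }
  merged <- merged[order(merged$log10_f_reduced), ]
  rownames(merged) <- NULL
  structure(list(T_ref = T_ref, shifts = shifts, merged = merged),
            class = "master_curve")
}

#' @export
print.master_curve <- function(x, ...) {
  cat(sprintf("<master_curve> T_ref = %g K, %d spectra, %d merged points\n",
              x$T_ref, nrow(x$shifts), nrow(x$merged)))
  invisible(x)
}

#' Fit the KWW loss shape to a master curve
#'
#' Least-squares fit of the peak-normalized frequency-domain KWW loss
#' ([kww_loss()]) to the merged master curve, with the stretching
#' exponent and characteristic time free. Points more than
#' `downweight_decades` above the peak get weight `flank_weight`
#' (default 0.25), since the high-frequency flank of structural peaks is
#' typically contaminated by a secondary process.
#'
#' @param curve a [master_curve()], or any `data.frame` with columns
#'   `log10_f_reduced` and `eps_norm` spanning at least two decades
#'   around the peak.
#' @param beta_init starting stretching exponent.
#' @param downweight_decades,flank_weight high-frequency flank weighting
#'   (set `flank_weight = 1` to disable).
#' @param n_per_decade grid density passed to [kww_loss()].
#' @return An object of class `kww_fit`: list with `beta_kww`,
#'   `tau_reduced` (s), `residual_rms`, `converged`.
#' @export
fit_kww <- function(curve, beta_init = 0.6,
                    downweight_decades = 2, flank_weight = 0.25,
                    n_per_decade = 250) {
  merged <- if (inherits(curve, "master_curve")) curve$merged else curve
  lf <- merged$log10_f_reduced
  yy <- merged$eps_norm
  if (diff(range(lf)) < 2) stop("master curve must span at least 2 decades")
  fgrid <- 10^lf
  lpk <- lf[which.max(yy)]
  w <- ifelse(lf > lpk + downweight_decades, flank_weight, 1)

  shape_at <- function(beta, ltau) {
    sh <- kww_shape(beta, 10^ltau)
    val <- kww_loss(sh, fgrid, n_per_decade = n_per_decade)
    val / max(val)
  }
  obj <- function(p) {
    v <- try(shape_at(p[1], p[2]), silent = TRUE)
    if (inherits(v, "try-error")) return(1e10)
    sum(w * (v - yy)^2)
  }
  tau0 <- 1 / (2 * pi * 10^lpk)
  opt <- optim(c(beta_init, log10(tau0)), obj, method = "L-BFGS-B",
               lower = c(0.05, log10(tau0) - 3),
               upper = c(1, log10(tau0) + 3),
               control = list(factr = 1e4, maxit = 500))
  res <- shape_at(opt$par[1], opt$par[2]) - yy
  structure(list(beta_kww = opt$par[1], tau_reduced = 10^opt$par[2],
                 residual_rms = sqrt(mean(res^2)),
                 converged = opt$convergence == 0),
            class = "kww_fit")
}

#' @export
print.kww_fit <- function(x, ...) {
  cat(sprintf("<kww_fit> beta_KWW = %.3f, tau = %.3g s, rms = %.3g%s\n",
              x$beta_kww, x$tau_reduced, x$residual_rms,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}
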