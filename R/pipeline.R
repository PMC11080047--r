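# End-to-end analysis of a nonisothermal BDS temperature series for one
# composition: staged deconvolution with mutually constrained processes,
# relaxation-time extraction, and the dielectric-strength series.

#' Analyze a BDS temperature series for one sample
#'
#' Staged deconvolution of a heating series of loss spectra, mirroring
#' the manual analysis practice for glass-forming liquids:
#'
#' 1. **Secondary processes in the glass.** Spectra inside `beta_window`
#'    (where the slow secondary process peaks within the frequency
#'    window) are fitted with two free Cole-Cole processes; the beta
#'    relaxation points define an Arrhenius law. Spectra inside
#'    `gamma_window` (lower temperatures, where only the fast secondary
#'    process peaks in-window) are fitted with gamma free and the beta
#'    flank pinned to its Arrhenius extrapolation (strength free),
#'    yielding the gamma Arrhenius law.
#' 2. **Structural relaxation in the supercooled liquid.** Spectra at and
#'    above `supercooled_min` are fitted with a free Havriliak-Negami
#'    structural process, DC conductivity, and both secondary processes
#'    pinned to their Arrhenius extrapolations with only strengths free
#'    (secondary peaks are barely visible above Tg, so their shape
#'    cannot be refitted there).
#'
#' Fits whose residual RMS exceeds `rms_factor` times the stage median
#' (stuck local minima) are excluded, as are relaxation times outside
#' the resolvable window widened by `tau_margin` decades.
#'
#' @param spectra list of [loss_spectrum()] objects for one sample
#'   (one heating series).
#' @param beta_window,gamma_window,supercooled_min temperature ranges
#'   (K) of the three stages; defaults match a 0.1 Hz - 1 MHz window and
#'   the glassy/supercooled measurement grids used for these composites.
#' @param conductivity include a DC conductivity term above Tg?
#' @param rms_factor quality-filter multiplier on the stage median
#'   residual RMS.
#' @param tau_margin extra decades beyond the frequency window inside
#'   which an extracted relaxation time is still trusted.
#' @return Object of class `bds_analysis`: list with `arr_beta`,
#'   `arr_gamma` ([arrhenius_params()]), `points` (per-process
#'   `data.frame` as from [extract_relaxation_points()]),
#'   `alpha_strength` (a [delta_eps_series()] of the structural
#'   process), and `fits` (all retained spectrum fits).
#' @export
analyze_bds <- function(spectra,
                        beta_window = c(236, 308),
                        gamma_window = c(153, 218),
                        supercooled_min = 310,
                        conductivity = TRUE,
                        rms_factor = 3,
                        tau_margin = 0.5) {
  temps <- vapply(spectra, function(s) s$temperature, numeric(1))
  spectra <- spectra[order(temps)]
  temps <- sort(temps)
  f_all <- spectra[[1]]$frequencies
  tau_lim <- c(10^(-tau_margin) / (2 * pi * max(f_all)),
               10^(tau_margin) / (2 * pi * min(f_all)))

  rms_keep <- function(fits) {
    r <- vapply(fits, function(x) x$residual_rms, numeric(1))
    keep <- vapply(fits, function(x) isTRUE(x$converged), logical(1)) &
      r <= rms_factor * median(r) + 1e-12
    fits[keep]
  }
  in_window <- function(tab)
    tab[tab$tau_s >= tau_lim[1] & tab$tau_s <= tau_lim[2], , drop = FALSE]
  # Arrhenius fit with iterative rejection of stray points (fits stuck
  # in a secondary minimum leave isolated large residuals)
  arr_robust <- function(T_K, tau_s) {
    keep <- rep(TRUE, length(T_K))
    fit <- fit_arrhenius(T_K, tau_s)
    for (i in 1:3) {
      r <- log10(tau_s[keep]) - log10(arrhenius_tau(fit, T_K[keep]))
      thr <- max(3 * stats::mad(r), 0.1)
      new_keep <- keep
      new_keep[keep] <- abs(r) <= thr
      if (identical(new_keep, keep) || sum(new_keep) < 3) break
      keep <- new_keep
      fit <- fit_arrhenius(T_K[keep], tau_s[keep])
    }
    fit
  }

  # stage 1: both secondaries free where the beta peak is resolvable
  st1 <- Filter(function(s) s$temperature >= beta_window[1] &
                  s$temperature <= beta_window[2], spectra)
  if (length(st1) < 3) stop("too few spectra in beta_window")
  f1 <- rms_keep(lapply(st1, function(s)
    fit_loss_spectrum(s, fit_plan(c("beta", "gamma")))))
  p1 <- extract_relaxation_points(f1)
  bpts <- in_window(p1[p1$label == "beta", ])
  arr_beta <- arr_robust(bpts$T_K, bpts$tau_s)
  a_beta <- median(bpts$a)

  # stage 2: gamma free, beta flank pinned by downward extrapolation
  st2 <- Filter(function(s) s$temperature >= gamma_window[1] &
                  s$temperature <= gamma_window[2], spectra)
  if (length(st2) < 3) stop("too few spectra in gamma_window")
  f2 <- rms_keep(lapply(st2, function(s)
    fit_loss_spectrum(s, fit_plan(
      c("beta", "gamma"),
      fixed = list(beta = list(tau_hn = arrhenius_tau(arr_beta, s$temperature),
                               a = a_beta, b = 1))))))
  p2 <- extract_relaxation_points(f2)
  gpts <- in_window(p2[p2$label == "gamma", ])
  arr_gamma <- arr_robust(gpts$T_K, gpts$tau_s)
  a_gamma <- median(gpts$a)

  # stage 3: structural relaxation with pinned secondaries
  st3 <- Filter(function(s) s$temperature >= supercooled_min, spectra)
  if (length(st3) < 4) stop("too few supercooled spectra")
  f3 <- rms_keep(lapply(st3, function(s)
    fit_loss_spectrum(s, fit_plan(
      c("alpha", "beta", "gamma"), conductivity = conductivity,
      fixed = list(
        beta = list(tau_hn = arrhenius_tau(arr_beta, s$temperature),
                    a = a_beta, b = 1),
        gamma = list(tau_hn = arrhenius_tau(arr_gamma, s$temperature),
                     a = a_gamma, b = 1))))))
  p3 <- extract_relaxation_points(f3)
  apts <- in_window(p3[p3$label == "alpha", ])

  points <- rbind(apts,
                  cbind(bpts[setdiff(names(bpts), NULL)]),
                  gpts)
  rownames(points) <- NULL
  strength <- delta_eps_series("alpha", apts$T_K, apts$delta_eps)
  structure(list(arr_beta = arr_beta, arr_gamma = arr_gamma,
                 points = points, alpha_strength = strength,
                 fits = c(f2, f1, f3)),
            class = "bds_analysis")
}

#' @export
print.bds_analysis <- function(x, ...) {
  n <- table(x$points$label)
  cat("<bds_analysis>", paste(names(n), n, sep = ": ", collapse = ", "),
      "points\n")
  print(x$arr_beta); print(x$arr_gamma)
  invisible(x)
}
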