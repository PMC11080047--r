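# Composition-series analyses: monomolecular loading capacity (MLC)
# extrapolation, crystallization-onset trend with critical concentration,
# drug-mass normalization and polymorph area fractions.

#' Monomolecular loading capacity from a heat-capacity-step series
#'
#' The heat-capacity step at the glass transition is proportional to the
#' mobile amorphous drug fraction; drug molecules immobilized on the
#' silica surface do not contribute, so \eqn{\Delta C_p} decreases
#' linearly with silica loading and extrapolates to zero at the
#' monomolecular loading capacity (MLC) - the composition at which the
#' drug just covers the silica surface. Fits an ordinary least-squares
#' line and reports the zero-crossing with a delta-method standard
#' error.
#'
#' @param silica_wt_pct silica weight percents (>= 3 distinct values).
#' @param delta_cp heat-capacity steps in J/(g K), per total sample mass.
#' @return Object of class `mlc_fit`: list with `slope`, `intercept`,
#'   `w_mlc` (wt %), `w_mlc_se`, `flagged` (TRUE when the slope is
#'   non-negative and no physical MLC exists).
#' @export
fit_mlc <- function(silica_wt_pct, delta_cp) {
  stopifnot(length(silica_wt_pct) == length(delta_cp),
            length(silica_wt_pct) >= 3)
  fit <- lm(delta_cp ~ silica_wt_pct)
  cf <- coef(fit)
  slope <- cf[[2]]; intercept <- cf[[1]]
  # slope must be negative beyond numerical noise on the data's scale
  slope_floor <- 1e-10 * (mean(abs(delta_cp)) + 1e-300) /
    diff(range(silica_wt_pct))
  flagged <- slope >= -slope_floor
  if (flagged) {
    warning("non-negative slope: no physical MLC extrapolation")
    w <- NA_real_; w_se <- NA_real_
  } else {
    w <- -intercept / slope
    V <- suppressWarnings(vcov(fit))
    # delta method for w = -b0/b1
    grad <- c(-1 / slope, intercept / slope^2)
    w_se <- sqrt(drop(t(grad) %*% V %*% grad))
  }
  structure(list(slope = slope, intercept = intercept,
                 w_mlc = w, w_mlc_se = w_se, flagged = flagged),
            class = "mlc_fit")
}

#' @export
print.mlc_fit <- function(x, ...) {
  if (x$flagged) cat("<mlc_fit> flagged: no physical MLC (slope >= 0)\n")
  else cat(sprintf("<mlc_fit> w_MLC = %.1f +/- %.1f wt%% (slope %.4g, intercept %.4g)\n",
                   x$w_mlc, x$w_mlc_se, x$slope, x$intercept))
  invisible(x)
}

#' Crystallization-onset trend versus silica loading
#'
#' Low silica loadings accelerate drug recrystallization (onset moves
#' down) while higher loadings suppress it (onset moves back up); the
#' trend is modeled as a continuous two-segment piecewise-linear fit of
#' onset temperature versus loading, with the breakpoint - the critical
#' concentration - chosen by least total squared error on a grid over
#' the interior data range (default resolution 0.1 wt %).
#'
#' @param silica_wt_pct silica weight percents (>= 4 points).
#' @param Tc_K crystallization onset temperatures in K.
#' @param grid_step breakpoint grid resolution in wt %.
#' @return Object of class `crystallization_trend`: list with
#'   `w_critical` (wt %), `segments` (coefficients of
#'   `Tc ~ 1 + w + (w - w_critical)_+`), `rss`, `boundary` (TRUE when the
#'   best breakpoint sits at the edge of the data range, i.e. the data
#'   show no interior minimum).
#' @export
fit_crystallization_trend <- function(silica_wt_pct, Tc_K, grid_step = 0.1) {
  stopifnot(length(silica_wt_pct) == length(Tc_K),
            length(silica_wt_pct) >= 4)
  w <- silica_wt_pct; y <- Tc_K
  lo <- min(w); hi <- max(w)
  bps <- seq(lo, hi, by = grid_step)
  best <- NULL
  for (b in bps) {
    hinge <- pmax(w - b, 0)
    fit <- lm(y ~ w + hinge)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(b = b, rss = rss, coef = coef(fit))
  }
  boundary <- best$b <= lo + grid_step / 2 || best$b >= hi - grid_step / 2
  if (boundary)
    warning("no interior minimum: breakpoint at the data-range boundary")
  structure(list(w_critical = best$b,
                 segments = best$coef, rss = best$rss,
                 boundary = boundary),
            class = "crystallization_trend")
}

#' @export
print.crystallization_trend <- function(x, ...) {
  cat(sprintf("<crystallization_trend> w_critical = %.1f wt%%%s\n",
              x$w_critical, if (x$boundary) " [boundary, flagged]" else ""))
  invisible(x)
}

#' Normalize a DSC trace to the drug mass
#'
#' Divides the heat flow by the drug mass fraction so that traces of
#' different compositions are comparable per gram of drug (the silica
#' contributes no thermal events).
#'
#' @param trace a [dsc_trace()].
#' @return The trace with rescaled heat flow and `drug_normalized = TRUE`.
#' @export
normalize_to_drug <- function(trace) {
  stopifnot(inherits(trace, "dsc_trace"))
  if (trace$drug_mass_fraction <= 0) stop("zero drug mass fraction")
  trace$heat_flow <- trace$heat_flow / trace$drug_mass_fraction
  trace$drug_normalized <- TRUE
  trace
}

#' Polymorph area fractions from deconvolved melting components
#'
#' Fractional contribution of each polymorphic form to the total melting
#' enthalpy, computed from absolute component areas; fractions sum to 1.
#'
#' @param components list of `gaussian_component` objects (or a
#'   `melting_deconvolution`).
#' @return Named numeric vector of fractions.
#' @export
polymorph_fractions <- function(components) {
  if (inherits(components, "melting_deconvolution"))
    components <- components$components
  stopifnot(length(components) >= 1)
  areas <- abs(vapply(components, function(g) g$area, numeric(1)))
  tot <- sum(areas)
  if (tot <= 0) stop("zero total melting area")
  labs <- vapply(components, function(g) as.character(g$label), character(1))
  setNames(areas / tot, labs)
}

#' Assign polymorph labels from reference melting windows
#'
#' Relabels deconvolved melting components by comparing their centers
#' against reference peak-temperature windows for the known polymorphic
#' forms; components falling outside every window are labeled `"X"`
#' (an unassigned form).
#'
#' @param components list of `gaussian_component` objects (or a
#'   `melting_deconvolution`).
#' @param windows named list of `c(lo, hi)` windows in K; defaults span
#'   the known forms IV (406-409.5), III (409.5-414), II (414-417.5) and
#'   I (420-423.5).
#' @return The component list with labels replaced.
#' @export
label_polymorphs <- function(components,
                             windows = list(IV = c(406, 409.5),
                                            III = c(409.5, 414),
                                            II = c(414, 417.5),
                                            I = c(420, 423.5))) {
  wrapped <- inherits(components, "melting_deconvolution")
  comps <- if (wrapped) components$components else components
  for (i in seq_along(comps)) {
    ce <- comps[[i]]$center
    lab <- "X"
    for (nm in names(windows))
      if (ce >= windows[[nm]][1] && ce <= windows[[nm]][2]) { lab <- nm; break }
    comps[[i]]$label <- lab
  }
  if (wrapped) { components$components <- comps; components } else comps
}
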