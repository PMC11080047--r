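# DSC thermogram analysis: glass-transition step, crystallization
# exotherm onsets, Gaussian multi-peak melting deconvolution and the
# tangent-onset construction.

#' Construct a DSC trace
#'
#' Heat flow per unit sample mass versus temperature. The internal sign
#' convention is exothermic-positive: crystallization exotherms point up,
#' melting endotherms point down, and the glass transition appears as a
#' downward step. Readers accept an `exo_up` flag and normalize on input.
#'
#' @param temperatures strictly increasing temperatures in K.
#' @param heat_flow heat flow in W/g, exothermic-positive.
#' @param heating_rate heating rate in K/min (> 0).
#' @param sample_id sample identifier.
#' @param silica_wt_pct silica weight percent in \[0, 100).
#' @param drug_mass_fraction drug mass fraction in (0, 1].
#' @return Object of class `dsc_trace`.
#' @export
dsc_trace <- function(temperatures, heat_flow, heating_rate = 10,
                      sample_id = "sample", silica_wt_pct = 0,
                      drug_mass_fraction = 1 - silica_wt_pct / 100) {
  stopifnot(length(temperatures) == length(heat_flow),
            all(diff(temperatures) > 0), heating_rate > 0,
            drug_mass_fraction > 0, drug_mass_fraction <= 1)
  structure(list(temperatures = as.numeric(temperatures),
                 heat_flow = as.numeric(heat_flow),
                 heating_rate = heating_rate,
                 sample_id = as.character(sample_id),
                 silica_wt_pct = silica_wt_pct,
                 drug_mass_fraction = drug_mass_fraction,
                 drug_normalized = FALSE),
            class = "dsc_trace")
}

#' @export
print.dsc_trace <- function(x, ...) {
  cat(sprintf("<dsc_trace> %s (%g wt%% silica), %d points %.1f-%.1f K @ %g K/min%s\n",
              x$sample_id, x$silica_wt_pct, length(x$temperatures),
              min(x$temperatures), max(x$temperatures), x$heating_rate,
              if (x$drug_normalized) " [drug-normalized]" else ""))
  invisible(x)
}

# indices of trace inside [window[1], window[2]]
.window_idx <- function(trace, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  idx <- which(trace$temperatures >= window[1] & trace$temperatures <= window[2])
  if (length(idx) < 10) stop("fewer than 10 trace points inside the window")
  idx
}

# light running-mean smoothing that preserves endpoints
.smooth5 <- function(y) {
  s <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  s[is.na(s)] <- y[is.na(s)]
  as.numeric(s)
}

#' Detect the glass-transition step in a DSC trace
#'
#' Fits linear baselines to the outer thirds of the window (below and
#' above the step), finds the midpoint temperature `Tg_mid` where the
#' trace crosses halfway between the baselines, and the onset as the
#' intersection of the lower baseline with the steepest tangent of the
#' step. The heat-capacity step is the baseline separation at `Tg_mid`
#' converted from W/g to J/(g K) by the heating rate:
#' \eqn{\Delta C_p = |\Delta(\mathrm{heat\ flow})| / (\mathrm{rate\ in\ K/s})}.
#'
#' @param trace a [dsc_trace()].
#' @param window `c(lo, hi)` in K bracketing the step, free of other
#'   thermal events.
#' @param noise_floor minimum baseline separation (in units of the local
#'   heat-flow noise estimate) below which no step is reported.
#' @return Object of class `glass_transition_event`: list with
#'   `Tg_onset`, `Tg_mid` (K) and `delta_cp` (J/(g K)); or `NULL` with a
#'   warning when no step is found.
#' @export
detect_glass_transition <- function(trace, window, noise_floor = 5) {
  idx <- .window_idx(trace, window)
  Tw <- trace$temperatures[idx]
  yw <- trace$heat_flow[idx]
  n <- length(idx)
  k <- max(5L, n %/% 3L)
  lo <- seq_len(k); hi <- (n - k + 1L):n
  b_lo <- lm(yw[lo] ~ Tw[lo])
  b_hi <- lm(yw[hi] ~ Tw[hi])
  base_lo <- coef(b_lo)[[1]] + coef(b_lo)[[2]] * Tw
  base_hi <- coef(b_hi)[[1]] + coef(b_hi)[[2]] * Tw
  noise <- sd(c(resid(b_lo), resid(b_hi)))
  sep <- base_lo - base_hi  # exo-positive: endothermic step goes down
  if (max(abs(sep)) < noise_floor * max(noise, 1e-12)) {
    warning("no glass-transition step above the noise floor in the window")
    return(NULL)
  }
  mid <- (base_lo + base_hi) / 2
  # first crossing of the midpoint line going through the step
  sgn <- sign(yw - mid)
  cross <- which(diff(sgn) != 0)
  if (length(cross) == 0) {
    warning("trace never crosses the baseline midpoint inside the window")
    return(NULL)
  }
  j <- cross[ceiling(length(cross) / 2)]
  d1 <- yw[j] - mid[j]; d2 <- yw[j + 1] - mid[j + 1]
  Tg_mid <- Tw[j] + (Tw[j + 1] - Tw[j]) * d1 / (d1 - d2)
  delta_cp <- abs(approx(Tw, sep, xout = Tg_mid)$y) / (trace$heating_rate / 60)

  # onset: lower baseline vs steepest tangent of the (smoothed) step
  ys <- .smooth5(yw)
  slope <- diff(ys) / diff(Tw)
  js <- which.max(abs(slope))
  Tt <- (Tw[js] + Tw[js + 1]) / 2
  yt <- (ys[js] + ys[js + 1]) / 2
  st <- slope[js]
  # intersection with the lower baseline y = a + b T
  a <- coef(b_lo)[[1]]; b <- coef(b_lo)[[2]]
  Tg_onset <- (a - (yt - st * Tt)) / (st - b)
  structure(list(Tg_onset = Tg_onset, Tg_mid = Tg_mid, delta_cp = delta_cp),
            class = "glass_transition_event")
}

#' @export
print.glass_transition_event <- function(x, ...) {
  cat(sprintf("<glass_transition> Tg_onset = %.1f K, Tg_mid = %.1f K, dCp = %.3f J/(g K)\n",
              x$Tg_onset, x$Tg_mid, x$delta_cp))
  invisible(x)
}

# linear baseline over a window from its outer fractions
.edge_baseline <- function(Tw, yw, frac = 0.1) {
  n <- length(Tw)
  k <- max(3L, round(frac * n))
  idx <- c(seq_len(k), (n - k + 1L):n)
  fit <- lm(yw[idx] ~ Tw[idx])
  list(a = coef(fit)[[1]], b = coef(fit)[[2]],
       noise = sd(resid(fit)),
       value = function(Tq) coef(fit)[[1]] + coef(fit)[[2]] * Tq)
}

#' Detect a thermal event and its tangent onset in a DSC trace
#'
#' Finds the extremum of the baseline-corrected signal in the window
#' (maximum for exotherms, minimum for endotherms under the
#' exothermic-positive convention), constructs the steepest leading-edge
#' tangent on the lightly smoothed trace, and reports the onset as the
#' intersection of that tangent with the linear baseline fitted to the
#' window edges. The event area is the trapezoidal integral of the
#' baseline-corrected signal divided by the heating rate (J/g, signed:
#' positive for exotherms).
#'
#' @param trace a [dsc_trace()].
#' @param window `c(lo, hi)` in K containing the event.
#' @param kind `"exotherm"` or `"endotherm"`.
#' @param noise_floor peak amplitude threshold in noise units.
#' @return Object of class `thermal_event`: list with `kind`, `onset`,
#'   `peak` (K), `area` (J/g); or `NULL` with a warning when no peak
#'   rises above the noise.
#' @export
detect_thermal_event <- function(trace, window,
                                 kind = c("exotherm", "endotherm"),
                                 noise_floor = 5) {
  kind <- match.arg(kind)
  idx <- .window_idx(trace, window)
  Tw <- trace$temperatures[idx]
  yw <- trace$heat_flow[idx]
  bl <- .edge_baseline(Tw, yw)
  yc <- yw - bl$value(Tw)
  if (kind == "endotherm") yc <- -yc
  ip <- which.max(yc)
  if (yc[ip] < noise_floor * max(bl$noise, 1e-12)) {
    warning("no ", kind, " above the noise floor in the window")
    return(NULL)
  }
  ys <- .smooth5(yc)
  lead <- seq_len(ip)
  slope <- diff(ys[lead]) / diff(Tw[lead])
  if (length(slope) == 0) {
    warning(kind, " peak at the window edge")
    return(NULL)
  }
  js <- which.max(slope)
  Tt <- (Tw[js] + Tw[js + 1]) / 2
  yt <- (ys[js] + ys[js + 1]) / 2
  st <- slope[js]
  onset <- Tt - yt / st  # intersection with the zero line of yc
  rate_s <- trace$heating_rate / 60
  area <- sum(diff(Tw) * (yc[-1] + yc[-length(yc)]) / 2) / rate_s
  if (kind == "endotherm") area <- -area
  structure(list(kind = kind, onset = onset, peak = Tw[ip], area = area),
            class = "thermal_event")
}

#' @rdname detect_thermal_event
#' @export
detect_exotherm_onset <- function(trace, window, noise_floor = 5) {
  detect_thermal_event(trace, window, "exotherm", noise_floor)
}

#' Tangent onset of a Gaussian component
#'
#' For a Gaussian peak the steepest leading-edge tangent (through the
#' inflection point at `center - sigma`) intersects the baseline at
#' `center - 2 sigma`; this closed form is the onset construction used
#' for deconvolved melting components.
#'
#' @param component a `gaussian_component` (from [deconvolve_melting()])
#'   or any list with `center` and `sigma`.
#' @return Onset temperature in K.
#' @export
tangent_onset <- function(component) {
  component$center - 2 * component$sigma
}

#' Gaussian multi-peak deconvolution of melting endotherms
#'
#' Least-squares fit of a sum of `n_components` Gaussians plus a linear
#' baseline to the windowed trace. Under the exothermic-positive
#' convention melting endotherms are fitted with negative amplitudes;
#' areas are reported in J/g (signed, negative for endotherms).
#' Components are returned sorted by center, with polymorph labels
#' assigned by center order (lowest-melting form gets the highest
#' numeral), and can be refined against reference windows with
#' [label_polymorphs()].
#'
#' @param trace a [dsc_trace()].
#' @param n_components number of Gaussians (>= 1).
#' @param window `c(lo, hi)` in K containing the endotherms.
#' @param init optional numeric vector of starting centers (K); defaults
#'   to equally spaced centers over the window interior (deterministic).
#' @param kind `"endotherm"` (default) or `"exotherm"`.
#' @return List of class `melting_deconvolution`: `components` (list of
#'   `gaussian_component`: `center` K, `sigma` K, `area` J/g, `label`),
#'   `baseline` (intercept/slope), `residual_rms`, `converged`.
#' @export
deconvolve_melting <- function(trace, n_components, window, init = NULL,
                               kind = c("endotherm", "exotherm")) {
  kind <- match.arg(kind)
  stopifnot(n_components >= 1)
  idx <- .window_idx(trace, window)
  Tw <- trace$temperatures[idx]
  yw <- trace$heat_flow[idx]
  sgn <- if (kind == "endotherm") -1 else 1
  yx <- sgn * yw  # peaks point up in fitting space
  bl <- .edge_baseline(Tw, yx)
  yc0 <- .smooth5(yx - bl$value(Tw))
  sig_init <- min(2, diff(window) / (4 * n_components))

  run_lm <- function(par, m) {
    resid_fn <- function(p) {
      model <- p[3 * m + 1] + p[3 * m + 2] * Tw
      for (i in seq_len(m)) {
        A <- exp(p[3 * i - 2]); ce <- p[3 * i - 1]; sg <- exp(p[3 * i])
        model <- model + A * exp(-(Tw - ce)^2 / (2 * sg^2))
      }
      model - yx
    }
    lower <- c(rbind(rep(-30, m), rep(window[1], m), rep(log(1e-3), m)),
               -Inf, -Inf)
    upper <- c(rbind(rep(30, m), rep(window[2], m), rep(log(diff(window)), m)),
               Inf, Inf)
    fit <- try(minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                                  fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 1000, ftol = 1e-14, ptol = 1e-14)),
               silent = TRUE)
    list(ok = !inherits(fit, "try-error") && fit$info %in% 1:4,
         par = if (inherits(fit, "try-error")) par else coef(fit),
         resid = resid_fn)
  }
  model_of <- function(p, m) {
    model <- p[3 * m + 1] + p[3 * m + 2] * Tw
    for (i in seq_len(m)) {
      A <- exp(p[3 * i - 2]); ce <- p[3 * i - 1]; sg <- exp(p[3 * i])
      model <- model + A * exp(-(Tw - ce)^2 / (2 * sg^2))
    }
    model
  }

  if (!is.null(init)) {
    # user-supplied starting centers: one fit from those starts
    stopifnot(length(init) == n_components)
    amp0 <- pmax(approx(Tw, yc0, xout = init)$y, 1e-3 * max(yc0))
    par <- c(rbind(log(amp0), init, rep(log(sig_init), n_components)),
             bl$a, bl$b)
    fit <- run_lm(par, n_components)
  } else {
    # greedy deterministic initialization: add components one at a time
    # at the maximum of the current residual, refitting after each
    # addition -- resolves shoulders that are not local maxima
    par <- c(bl$a, bl$b)
    fit <- NULL
    for (m in seq_len(n_components)) {
      res <- yx - model_of(c(if (m > 1) par[seq_len(3 * (m - 1))],
                             par[c(length(par) - 1, length(par))]), m - 1)
      j <- which.max(.smooth5(res))
      newc <- c(log(max(res[j], 1e-3 * max(yc0))), Tw[j], log(sig_init))
      base <- par[c(length(par) - 1, length(par))]
      par <- c(if (m > 1) par[seq_len(3 * (m - 1))], newc, base)
      fit <- run_lm(par, m)
      par <- fit$par
    }
  }
  converged <- fit$ok
  p <- fit$par
  rate_s <- trace$heating_rate / 60
  comps <- lapply(seq_len(n_components), function(i) {
    A <- exp(p[3 * i - 2]); ce <- p[3 * i - 1]; sg <- exp(p[3 * i])
    structure(list(center = ce, sigma = sg,
                   area = sgn * A * sg * sqrt(2 * pi) / rate_s,
                   label = NA_character_),
              class = "gaussian_component")
  })
  o <- order(vapply(comps, function(g) g$center, numeric(1)))
  comps <- comps[o]
  if (any(vapply(comps, function(g) g$sigma < 2e-3, logical(1)))) {
    warning("component collapse (sigma -> 0) in melting deconvolution")
    converged <- FALSE
  }
  # center-order labels: lowest center = highest form numeral
  forms <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX")
  lab <- rev(forms[seq_len(min(n_components, length(forms)))])
  for (i in seq_along(comps)) comps[[i]]$label <- lab[i]
  res <- fit$resid(p)
  structure(list(components = comps,
                 baseline = c(intercept = sgn * p[3 * n_components + 1],
                              slope = sgn * p[3 * n_components + 2]),
                 residual_rms = sqrt(mean(res^2)),
                 converged = converged),
            class = "melting_deconvolution")
}

#' @export
print.melting_deconvolution <- function(x, ...) {
  cat(sprintf("<melting_deconvolution> %d components, rms = %.3g%s\n",
              length(x$components), x$residual_rms,
              if (x$converged) "" else " [NOT CONVERGED]"))
  for (g in x$components)
    cat(sprintf("  form %-4s center = %.2f K, sigma = %.2f K, onset = %.2f K, area = %.3g J/g\n",
                g$label, g$center, g$sigma, tangent_onset(g), g$area))
  invisible(x)
}
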