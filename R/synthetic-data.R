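# Seeded generators for dielectric loss surfaces and DSC traces with the
# statistical structure the analysis pipeline assumes. Defaults encode
# the measured dynamics of amorphous aripiprazole (ARP) in Syloid 244FP
# composites: VFT structural relaxation, Arrhenius secondary processes,
# alpha-peak broadening and dielectric-strength reduction with silica
# loading, incomplete recrystallization above a loading-dependent onset,
# a Tg step whose height extrapolates to zero at the monomolecular
# loading capacity, a V-shaped crystallization-onset trend and
# overlapping Gaussian melting endotherms of polymorph forms I-IV.

#' Scenario for synthetic broadband dielectric spectra
#'
#' Defaults are the published dynamics of amorphous aripiprazole:
#' VFT parameters (log10 tau_inf = -15.73, T0 = 248.0 K, D = 2257 K),
#' Arrhenius secondary processes (beta: -17.57 / 80.4 kJ/mol; gamma:
#' -12.39 / 23.8 kJ/mol), a stretching exponent falling linearly from
#' 0.55 (pure drug) to 0.40 at 50 wt % silica, recrystallization onsets
#' of 338 K (pure), 333/327/325/337 K at 10/20/30/40 wt % and none at
#' 50 wt %, measurement grids of 153-308 K (5 K step, glassy) and
#' 310-342 K (2 K step, supercooled) over 0.1-1e6 Hz.
#'
#' @param vft [vft_params()] of the structural process.
#' @param arr_beta,arr_gamma [arrhenius_params()] of the secondary
#'   processes.
#' @param beta_kww_fun function of silica wt % returning the stretching
#'   exponent.
#' @param delta_eps0 base dielectric strength of the structural process
#'   for the pure drug (scaled by the drug mass fraction; absolute value
#'   is a placeholder, no analysis depends on it).
#' @param alpha_a,alpha_b HN shape of the structural peak.
#' @param recryst_onset named numeric vector, onset K by wt % (`NA` =
#'   no recrystallization).
#' @param residual_amorphous_fun function of wt % giving the amorphous
#'   fraction remaining after recrystallization (increases with loading).
#' @param sigma_dc_coef DC conductivity is `sigma_dc_coef / tau_alpha(T)`
#'   S/m above Tg (conductivity tied to structural dynamics).
#' @param compositions silica wt % values to simulate.
#' @param T_glassy,T_supercooled temperature grids in K.
#' @param frequencies frequency grid in Hz.
#' @param noise_rel relative SD of the multiplicative log-normal noise
#'   on the loss (0 = noiseless).
#' @return Object of class `bds_scenario`.
#' @export
bds_scenario <- function(vft = vft_params(-15.73, 248.0, 2257),
                         arr_beta = arrhenius_params(-17.57, 80.4),
                         arr_gamma = arrhenius_params(-12.39, 23.8),
                         beta_kww_fun = function(w) 0.55 - 0.15 * w / 50,
                         delta_eps0 = 4,
                         alpha_a = 0.82, alpha_b = 0.63,
                         recryst_onset = c("0" = 338, "10" = 333, "20" = 327,
                                           "30" = 325, "40" = 337, "50" = NA),
                         residual_amorphous_fun = function(w) 0.15 + 0.01 * w,
                         sigma_dc_coef = 2e-12,
                         compositions = c(0, 10, 20, 30, 40, 50),
                         T_glassy = seq(153, 308, by = 5),
                         T_supercooled = seq(310, 342, by = 2),
                         frequencies = 10^seq(-1, 6, by = 0.1),
                         noise_rel = 0.02) {
  structure(list(vft = vft, arr_beta = arr_beta, arr_gamma = arr_gamma,
                 beta_kww_fun = beta_kww_fun, delta_eps0 = delta_eps0,
                 alpha_a = alpha_a, alpha_b = alpha_b,
                 recryst_onset = recryst_onset,
                 residual_amorphous_fun = residual_amorphous_fun,
                 sigma_dc_coef = sigma_dc_coef,
                 compositions = compositions,
                 T_glassy = T_glassy, T_supercooled = T_supercooled,
                 frequencies = frequencies, noise_rel = noise_rel),
            class = "bds_scenario")
}

# sigmoid suppression of the structural strength above the
# recrystallization onset, decaying to the residual amorphous fraction
.recryst_factor <- function(T_K, onset, x_res, delta = 1) {
  if (is.na(onset)) return(rep(1, length(T_K)))
  x_res + (1 - x_res) / (1 + exp((T_K - onset - 2 * delta) / delta))
}

#' Simulate a set of dielectric loss spectra
#'
#' For each composition and temperature of the scenario, composes the
#' loss spectrum from its forward models: structural HN peak whose peak
#' time follows the VFT law (suppressed sigmoidally above the
#' recrystallization onset), Cole-Cole secondary peaks on their
#' Arrhenius laws, and DC conductivity above Tg. Output is deterministic
#' given the seed.
#'
#' @param scenario a [bds_scenario()].
#' @param seed integer seed for the multiplicative noise.
#' @return List of [loss_spectrum()] objects.
#' @export
simulate_bds <- function(scenario, seed = 42) {
  stopifnot(inherits(scenario, "bds_scenario"))
  set.seed(seed)
  sc <- scenario
  Tg_kin <- tg_from_tau(sc$vft, 100)
  out <- list()
  for (w in sc$compositions) {
    drug_frac <- 1 - w / 100
    x_res <- sc$residual_amorphous_fun(w)
    onset <- unname(sc$recryst_onset[as.character(w)])
    if (is.null(onset) || length(onset) == 0) onset <- NA_real_
    sid <- sprintf("ARP+%gSYL", w)
    for (T_K in sort(c(sc$T_glassy, sc$T_supercooled))) {
      procs <- list()
      # secondary processes always present (symmetric CC)
      tau_b <- arrhenius_tau(sc$arr_beta, T_K)
      procs$beta <- relaxation_process("beta", 0.30 * drug_frac, tau_b,
                                       a = 0.35, model = "CC")
      tau_g <- arrhenius_tau(sc$arr_gamma, T_K)
      procs$gamma <- relaxation_process("gamma", 0.20 * drug_frac, tau_g,
                                        a = 0.30, model = "CC")
      cond <- conductivity_term(0)
      if (T_K > sc$vft$T0 + 1 && T_K >= min(sc$T_supercooled)) {
        tau_a <- vft_tau(sc$vft, T_K)
        de <- sc$delta_eps0 * drug_frac *
          .recryst_factor(T_K, onset, x_res)
        procs$alpha <- relaxation_process(
          "alpha", de, tau_hn_from_max(tau_a, sc$alpha_a, sc$alpha_b),
          a = sc$alpha_a, b = sc$alpha_b, model = "HN")
        if (T_K > Tg_kin)
          cond <- conductivity_term(sc$sigma_dc_coef / tau_a)
      }
      loss <- composite_loss(procs, cond, sc$frequencies)
      if (sc$noise_rel > 0)
        loss <- loss * rlnorm(length(loss), meanlog = 0,
                              sdlog = sc$noise_rel)
      out[[length(out) + 1L]] <- loss_spectrum(
        T_K, sc$frequencies, loss, sample_id = sid, silica_wt_pct = w)
    }
  }
  out
}

#' Scenario for synthetic DSC traces
#'
#' Defaults encode the calorimetry of amorphous aripiprazole composites:
#' glass transition at 307 K with a 0.35 J/(g K) step for the pure drug,
#' step height falling linearly to zero at the 65 wt % monomolecular
#' loading capacity, a V-shaped crystallization-onset trend with vertex
#' at 27.3 wt % and pure-drug onset 357 K, and Gaussian melting
#' endotherms built from the measured onset/peak pairs of polymorph
#' forms I-IV (sigma = (peak - onset)/2, the tangent-onset identity).
#'
#' @param silica_wt_pct composition of the simulated sample.
#' @param Tg calorimetric glass transition in K.
#' @param delta_cp0 heat-capacity step of the pure drug, J/(g K).
#' @param w_mlc monomolecular loading capacity in wt %.
#' @param step_width 10-90 logistic width of the Tg step in K.
#' @param Tc_fun crystallization onset (K) as a function of wt %;
#'   default is the V with vertex 27.3 wt %, 357 K at 0 wt % and slopes
#'   -0.51 / +0.60 K per wt %.
#' @param exo_sigma exotherm width in K; the exotherm center sits
#'   `2 * exo_sigma` above the onset so its tangent onset equals
#'   `Tc_fun(w)`.
#' @param exo_area crystallization enthalpy of the pure drug in J/g
#'   (scaled by drug fraction).
#' @param melt table of melting components: `data.frame` with columns
#'   `form`, `onset`, `peak` (K) and `area` (J/g of drug, positive).
#' @param baseline `c(intercept, slope)` of the instrumental baseline in
#'   W/g and W/(g K).
#' @param T_range,T_step simulation grid in K.
#' @param heating_rate K/min.
#' @param noise_sd additive Gaussian noise SD in W/g (0 = noiseless).
#' @return Object of class `dsc_scenario`.
#' @export
dsc_scenario <- function(silica_wt_pct = 0,
                         Tg = 307, delta_cp0 = 0.35, w_mlc = 65,
                         step_width = 2,
                         Tc_fun = function(w)
                           ifelse(w <= 27.3, 357 - 0.51 * w,
                                  357 - 0.51 * 27.3 + 0.60 * (w - 27.3)),
                         exo_sigma = 4, exo_area = 60,
                         melt = data.frame(
                           form = c("IV", "III", "II", "I"),
                           onset = c(406.3, 410.3, 414.4, 420.5),
                           peak = c(408.1, 413.8, 416.5, 423.0),
                           area = c(30, 50, 12, 8)),
                         baseline = c(0, -5e-5),
                         T_range = c(280, 433), T_step = 0.1,
                         heating_rate = 10,
                         noise_sd = 0.005) {
  stopifnot(silica_wt_pct >= 0, silica_wt_pct < 100)
  structure(list(silica_wt_pct = silica_wt_pct, Tg = Tg,
                 delta_cp0 = delta_cp0, w_mlc = w_mlc,
                 step_width = step_width, Tc_fun = Tc_fun,
                 exo_sigma = exo_sigma, exo_area = exo_area,
                 melt = melt, baseline = baseline,
                 T_range = T_range, T_step = T_step,
                 heating_rate = heating_rate, noise_sd = noise_sd),
            class = "dsc_scenario")
}

#' Simulate a DSC heating trace
#'
#' Composes, on the scenario's temperature grid and in the
#' exothermic-positive convention: a logistic heat-capacity step at Tg
#' (downward, height `delta_cp(w) * heating rate`), a Gaussian
#' crystallization exotherm whose tangent onset equals the scenario's
#' onset law (suppressed above the loading capacity), Gaussian melting
#' endotherms (downward) from the scenario's component table, a linear
#' baseline and seeded additive noise. Deterministic given the seed.
#'
#' @param scenario a [dsc_scenario()].
#' @param seed integer seed for the additive noise.
#' @return A [dsc_trace()].
#' @export
simulate_dsc <- function(scenario, seed = 42) {
  stopifnot(inherits(scenario, "dsc_scenario"))
  set.seed(seed)
  sc <- scenario
  w <- sc$silica_wt_pct
  drug_frac <- 1 - w / 100
  rate_s <- sc$heating_rate / 60
  Tv <- seq(sc$T_range[1], sc$T_range[2], by = sc$T_step)
  hf <- sc$baseline[1] + sc$baseline[2] * Tv

  # glass-transition step (endothermic shift, downward when exo-positive)
  dcp <- max(sc$delta_cp0 * (1 - w / sc$w_mlc), 0)
  scale <- sc$step_width / 4   # slope-matched logistic scale
  hf <- hf - dcp * rate_s / (1 + exp(-(Tv - sc$Tg) / scale))

  if (w < sc$w_mlc) {
    # crystallization exotherm: center 2 sigma above the tangent onset
    Tc <- sc$Tc_fun(w)
    amp_exo <- sc$exo_area * drug_frac * rate_s /
      (sc$exo_sigma * sqrt(2 * pi))
    hf <- hf + amp_exo * exp(-(Tv - (Tc + 2 * sc$exo_sigma))^2 /
                               (2 * sc$exo_sigma^2))
    # melting endotherms (downward), per gram of sample
    for (i in seq_len(nrow(sc$melt))) {
      sg <- (sc$melt$peak[i] - sc$melt$onset[i]) / 2
      amp <- sc$melt$area[i] * drug_frac * rate_s / (sg * sqrt(2 * pi))
      hf <- hf - amp * exp(-(Tv - sc$melt$peak[i])^2 / (2 * sg^2))
    }
  }
  if (sc$noise_sd > 0) hf <- hf + rnorm(length(hf), sd = sc$noise_sd)
  dsc_trace(Tv, hf, heating_rate = sc$heating_rate,
            sample_id = sprintf("ARP+%gSYL", w),
            silica_wt_pct = w, drug_mass_fraction = drug_frac)
}
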