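# The published dynamics of amorphous aripiprazole used as fixture
# parameters throughout: VFT (log10 tau_inf = -15.73 s, T0 = 248.0 K,
# D = 2257 K), Arrhenius beta (-17.57, 80.4 kJ/mol) and gamma
# (-12.39, 23.8 kJ/mol).
VFT_ARP <- vft_params(-15.73, 248.0, 2257)

test_that("VFT refitting recovers the generating parameters", {
  # determined system: noiseless points give essentially exact recovery
  Ts <- seq(310, 342, by = 2)
  fit <- fit_vft(Ts, vft_tau(VFT_ARP, Ts))
  expect_equal(fit$T0, 248.0, tolerance = 1e-6)
  expect_equal(fit$D, 2257, tolerance = 1e-6)
  expect_equal(fit$log10_tau_inf, -15.73, tolerance = 1e-6)

  # 2% seeded noise on tau: Vogel temperature within 2 K
  set.seed(5)
  tau_noisy <- vft_tau(VFT_ARP, Ts) * rlnorm(length(Ts), 0, 0.02)
  fit2 <- fit_vft(Ts, tau_noisy)
  expect_lt(abs(fit2$T0 - 248.0), 2)
})

test_that("the kinetic glass transition follows from closed-form inversion", {
  # constructed inversion: D chosen so Tg - T0 = 50 exactly at tau_g = 100
  D <- 50 * log(10) * (2 + 12)
  p <- vft_params(-12, 200, D)
  expect_equal(tg_from_tau(p, 100), 250)

  # round trip: evaluating the VFT law at Tg returns tau_g
  Tg <- tg_from_tau(VFT_ARP, 100)
  expect_equal(vft_tau(VFT_ARP, Tg), 100, tolerance = 1e-9)

  expect_error(tg_from_tau(vft_params(-2, 200, 1000), tau_g = 1e-3),
               "exceed")
})

test_that("fragility matches a finite-difference slope of log10 tau vs Tg/T", {
  fd_mp <- function(p, Tg, h = 1e-5) {
    # d log10 tau / d(Tg/T) at T = Tg via central difference in x = Tg/T
    lt <- function(x) p$log10_tau_inf +
      p$D / (log(10) * (Tg / x - p$T0))
    (lt(1 + h) - lt(1 - h)) / (2 * h)
  }
  Tg <- tg_from_tau(VFT_ARP, 100)
  m <- fragility(VFT_ARP, Tg)
  expect_equal(m$m_p, fd_mp(VFT_ARP, Tg), tolerance = 1e-3)

  set.seed(13)
  for (i in 1:50) {
    p <- vft_params(runif(1, -18, -10), runif(1, 150, 260),
                    runif(1, 800, 4000))
    Tg <- tg_from_tau(p, 100)
    m <- suppressWarnings(fragility(p, Tg))
    expect_equal(m$m_p, fd_mp(p, Tg), tolerance = 1e-3)
  }
})

test_that("the steepness index from the published VFT triple lies in the high-90s", {
  # the Arrhenius (strong-glass) floor for this tau_g/tau_inf pair
  floor_mp <- log10(100) - (-15.73)
  expect_equal(floor_mp, 17.73)
  Tg <- tg_from_tau(VFT_ARP, 100)
  m <- fragility(VFT_ARP, Tg)
  expect_gt(m$m_p, 95); expect_lt(m$m_p, 100)
  # m_p grows as Tg approaches T0 at fixed D
  mp_at <- function(T0) fragility(vft_params(-15.73, T0, 2257),
                                  tg_from_tau(vft_params(-15.73, T0, 2257)))$m_p
  expect_true(all(diff(suppressWarnings(
    vapply(c(200, 230, 248, 260), mp_at, numeric(1)))) > 0))
})

test_that("Arrhenius refitting recovers the secondary-process activation energies", {
  Ts <- seq(153, 303, by = 10)
  beta_fit <- fit_arrhenius(Ts, arrhenius_tau(arrhenius_params(-17.57, 80.4), Ts))
  expect_equal(beta_fit$Ea, 80.4, tolerance = 1e-6)
  gamma_fit <- fit_arrhenius(Ts, arrhenius_tau(arrhenius_params(-12.39, 23.8), Ts))
  expect_equal(gamma_fit$Ea, 23.8, tolerance = 1e-6)

  # two exact points determine the line
  two <- fit_arrhenius(c(200, 250), arrhenius_tau(arrhenius_params(-15, 50),
                                                  c(200, 250)))
  expect_equal(two$Ea, 50, tolerance = 1e-9)
  expect_error(fit_arrhenius(c(200, 200), c(1, 1)), "degenerate")
})

test_that("the primitive relaxation time obeys the coupling-model identities", {
  expect_equal(primitive_relaxation_time(3.7, beta_kww = 1), 3.7)
  expect_equal(primitive_relaxation_time(2e-12, beta_kww = 0.4), 2e-12)
  expect_equal(primitive_relaxation_time(100, beta_kww = 0.55), 6.85e-5,
               tolerance = 1e-3)

  # tau_0 <= tau_alpha whenever tau_alpha >= t_c, equality iff beta = 1
  set.seed(21)
  for (i in 1:30) {
    ta <- 10^runif(1, -11, 2)
    b <- runif(1, 0.05, 0.999)
    expect_lt(primitive_relaxation_time(ta, b), ta * (1 + 1e-12))
  }
})

test_that("secondary processes are classified JG / non-JG by coupling-model continuity", {
  Ts <- seq(310, 342, by = 2)
  tau_a <- vft_tau(VFT_ARP, Ts)
  beta_kww <- 0.55
  tau0 <- primitive_relaxation_time(tau_a, beta_kww)

  # construct a secondary process lying exactly on tau_0(T): JG
  line <- fit_arrhenius(Ts, tau0)
  res_jg <- classify_secondary(line, Ts, tau_a, beta_kww)
  expect_equal(res_jg$classification, "JG")

  # a process 4 decades faster: non-JG
  fast <- arrhenius_params(line$log10_tau_inf - 4, line$Ea)
  res_non <- classify_secondary(fast, Ts, tau_a, beta_kww)
  expect_equal(res_non$classification, "non_JG")

  # classification flips monotonically with tolerance
  cls <- vapply(c(0.5, 2, 4, 6), function(tol)
    classify_secondary(fast, Ts, tau_a, beta_kww,
                       tolerance_decades = tol)$classification,
    character(1))
  expect_equal(cls, c("non_JG", "non_JG", "JG", "JG"))
})

test_that("near Tg the coupling prediction tracks the beta branch far better than gamma", {
  # with the measured laws the primitive relaxation runs 1-2 decades
  # below the beta extrapolation just above Tg (order-of-magnitude
  # agreement) but ~3 decades away from gamma: the ordering is what
  # distinguishes the whole-molecule precursor from the intramolecular
  # process
  Ts <- seq(310, 318, by = 2)
  tau_a <- vft_tau(VFT_ARP, Ts)
  beta_cls <- classify_secondary(arrhenius_params(-17.57, 80.4),
                                 Ts, tau_a, beta_kww = 0.55,
                                 tolerance_decades = 2)
  gamma_cls <- classify_secondary(arrhenius_params(-12.39, 23.8),
                                  Ts, tau_a, beta_kww = 0.55,
                                  tolerance_decades = 2)
  expect_equal(beta_cls$classification, "JG")
  expect_equal(gamma_cls$classification, "non_JG")
  expect_lt(beta_cls$mean_abs_dlog10, gamma_cls$mean_abs_dlog10 - 1)
})

test_that("relaxation_map aggregates VFT, Tg, fragility, Arrhenius and coupling", {
  Ts_sup <- seq(310, 342, by = 2)
  Ts_gl <- seq(153, 303, by = 10)
  pts <- rbind(
    data.frame(label = "alpha", T_K = Ts_sup, tau_s = vft_tau(VFT_ARP, Ts_sup)),
    data.frame(label = "beta", T_K = Ts_gl,
               tau_s = arrhenius_tau(arrhenius_params(-17.57, 80.4), Ts_gl)),
    data.frame(label = "gamma", T_K = Ts_gl,
               tau_s = arrhenius_tau(arrhenius_params(-12.39, 23.8), Ts_gl)))
  map <- relaxation_map(pts, beta_kww = 0.55, tolerance_decades = 2)
  expect_equal(round(map$Tg), 303)
  expect_equal(map$arrhenius$beta$Ea, 80.4, tolerance = 1e-6)
  expect_equal(map$arrhenius$gamma$Ea, 23.8, tolerance = 1e-6)
  expect_equal(map$coupling$beta$classification, "JG")
  expect_equal(map$coupling$gamma$classification, "non_JG")
})
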