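freq_grid <- 10^seq(-1, 6, by = 0.1)

test_that("a noiseless Debye spectrum is recovered to 0.1%", {
  truth <- relaxation_process("alpha", delta_eps = 3.2, tau_hn = 1e-3,
                              a = 1, b = 1)
  sp <- loss_spectrum(300, freq_grid, hn_loss(truth, freq_grid))
  ft <- fit_loss_spectrum(sp, fit_plan("alpha"))
  expect_true(ft$converged)
  expect_equal(ft$components$alpha$delta_eps, 3.2, tolerance = 1e-3)
  expect_equal(tau_max(ft$components$alpha), tau_max(truth), tolerance = 1e-3)
})

test_that("a noiseless HN + conductivity spectrum is recovered within 1%", {
  truth <- relaxation_process("alpha", delta_eps = 2, tau_hn = 1e-2,
                              a = 0.8, b = 0.6)
  y <- composite_loss(list(truth), conductivity_term(5e-12), freq_grid)
  ft <- fit_loss_spectrum(loss_spectrum(300, freq_grid, y),
                          fit_plan("alpha", conductivity = TRUE))
  expect_true(ft$converged)
  a <- ft$components$alpha
  expect_equal(a$delta_eps, 2, tolerance = 0.01)
  expect_equal(a$tau_hn, 1e-2, tolerance = 0.01)
  expect_equal(a$a, 0.8, tolerance = 0.01)
  expect_equal(a$b, 0.6, tolerance = 0.01)
  expect_equal(ft$conductivity$sigma_dc, 5e-12, tolerance = 0.01)
})

test_that("two processes four decades apart are both recovered within 2%", {
  pa <- relaxation_process("alpha", 4, 1e-1, 0.82, 0.63)
  pb <- relaxation_process("beta", 0.3, 1e-5, 0.35, model = "CC")
  y <- composite_loss(list(pa, pb), NULL, freq_grid)
  ft <- fit_loss_spectrum(loss_spectrum(300, freq_grid, y),
                          fit_plan(c("alpha", "beta")))
  expect_true(ft$converged)
  expect_equal(tau_max(ft$components$alpha), tau_max(pa), tolerance = 0.02)
  expect_equal(tau_max(ft$components$beta), tau_max(pb), tolerance = 0.02)
})

test_that("with 2% multiplicative noise every parameter is recovered within 5%", {
  set.seed(42)
  pa <- relaxation_process("alpha", 4, 1e-1, 0.82, 0.63)
  pb <- relaxation_process("beta", 0.3, 1e-5, 0.35, model = "CC")
  y <- composite_loss(list(pa, pb), NULL, freq_grid) *
    rlnorm(length(freq_grid), 0, 0.02)
  ft <- fit_loss_spectrum(loss_spectrum(300, freq_grid, y),
                          fit_plan(c("alpha", "beta")))
  expect_true(ft$converged)
  fa <- ft$components$alpha; fb <- ft$components$beta
  expect_equal(fa$delta_eps, 4, tolerance = 0.05)
  expect_equal(fa$tau_hn, 1e-1, tolerance = 0.05)
  expect_equal(fa$a, 0.82, tolerance = 0.05)
  expect_equal(fa$b, 0.63, tolerance = 0.05)
  expect_equal(fb$delta_eps, 0.3, tolerance = 0.05)
  expect_equal(fb$tau_hn, 1e-5, tolerance = 0.05)
  expect_equal(fb$a, 0.35, tolerance = 0.05)
})

test_that("too few points or no process in the plan are rejected", {
  sp <- loss_spectrum(300, 10^seq(0, 3, length.out = 6), rep(1, 6))
  expect_error(fit_loss_spectrum(sp, fit_plan("alpha")), "8 frequency points")
  expect_error(fit_plan(character(0)))
})

test_that("relaxation points are tabulated per process and exclude unconverged fits", {
  p <- relaxation_process("beta", 0.5, 2e-4, 0.5, model = "CC")
  sp <- loss_spectrum(250, freq_grid, hn_loss(p, freq_grid))
  ft <- fit_loss_spectrum(sp, fit_plan("beta"))
  # CC passthrough: tau_max equals tau_hn
  tab <- extract_relaxation_points(list(ft))
  expect_equal(tab$tau_s, ft$components$beta$tau_hn)

  bad <- ft; bad$converged <- FALSE
  expect_warning(tab2 <- extract_relaxation_points(list(ft, bad)),
                 "unconverged")
  expect_equal(nrow(tab2), 1)

  # alpha and alpha_prime stay distinct
  fta <- fit_loss_spectrum(
    loss_spectrum(330, freq_grid,
                  hn_loss(relaxation_process("alpha", 2, 1e-3, 0.8, 0.7),
                          freq_grid)),
    fit_plan("alpha"))
  ftap <- fit_loss_spectrum(
    loss_spectrum(334, freq_grid,
                  hn_loss(relaxation_process("alpha_prime", 1, 1e-4, 0.8, 0.7),
                          freq_grid)),
    fit_plan("alpha_prime"))
  tab3 <- extract_relaxation_points(list(fta, ftap))
  expect_setequal(tab3$label, c("alpha", "alpha_prime"))
})

test_that("extracted structural relaxation times follow the generating VFT law within 2%", {
  sc <- bds_scenario(compositions = 0, noise_rel = 0)
  spectra <- simulate_bds(sc, seed = 1)
  an <- suppressWarnings(analyze_bds(spectra))
  a <- an$points[an$points$label == "alpha", ]
  expect_gte(nrow(a), 15)
  tau_true <- vft_tau(sc$vft, a$T_K)
  expect_lt(max(abs(a$tau_s / tau_true - 1)), 0.02)
})

test_that("dielectric-strength normalization uses 312 K and is idempotent", {
  s <- delta_eps_series("alpha", T_K = seq(310, 342, 2),
                        delta_eps = rep(4, 17))
  n1 <- normalize_delta_eps(s)
  expect_equal(n1$T_ref, 312)
  expect_equal(n1$normalized, rep(1, 17))

  s2 <- delta_eps_series("alpha", c(312, 330), c(4, 1))
  n2 <- normalize_delta_eps(s2)
  expect_equal(n2$normalized[n2$T_K == 330], 0.25)

  # idempotence: normalizing the normalized series changes nothing
  n3 <- normalize_delta_eps(n2)
  expect_identical(n3$normalized, n2$normalized)

  expect_error(normalize_delta_eps(s2, T_ref = 400), "outside")
})

test_that("recrystallization onset is detected, scale-invariant, and robust to partial drops", {
  Tv <- seq(310, 342, by = 2)
  onset_true <- 333
  sigmoid <- function(x_res)
    x_res + (1 - x_res) / (1 + exp((Tv - onset_true - 2) / 1))

  for (x_res in c(0.0, 0.4)) {
    de <- 4 * sigmoid(x_res)
    s <- normalize_delta_eps(delta_eps_series("alpha", Tv, de))
    onset <- detect_recrystallization_onset(s)
    expect_lt(abs(onset - onset_true), 1)
    # invariance under positive rescaling (raw, unnormalized series)
    s2 <- delta_eps_series("alpha", Tv, 37.5 * de)
    expect_equal(detect_recrystallization_onset(s2), onset, tolerance = 1e-9)
  }

  flat <- delta_eps_series("alpha", Tv, rep(2, length(Tv)))
  expect_warning(res <- detect_recrystallization_onset(flat), "no drop")
  expect_true(is.na(res))
})
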