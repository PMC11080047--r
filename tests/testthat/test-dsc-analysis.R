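test_that("the glass-transition step is located with the right height", {
  sc <- dsc_scenario(0, noise_sd = 0)
  tr <- simulate_dsc(sc)
  gt <- detect_glass_transition(tr, c(295, 320))
  expect_equal(gt$Tg_mid, 307, tolerance = 0.5 / 307)
  expect_equal(gt$delta_cp, 0.35, tolerance = 0.02)
  expect_lte(gt$Tg_onset, gt$Tg_mid)

  # linearity: halving the step halves delta_cp, Tg unchanged
  sc2 <- dsc_scenario(0, delta_cp0 = 0.175, noise_sd = 0)
  gt2 <- detect_glass_transition(simulate_dsc(sc2), c(295, 320))
  expect_equal(gt2$delta_cp, gt$delta_cp / 2, tolerance = 1e-3)
  expect_equal(gt2$Tg_mid, gt$Tg_mid, tolerance = 1e-3)

  # vertical offset invariance
  tr3 <- tr; tr3$heat_flow <- tr3$heat_flow + 0.37
  gt3 <- detect_glass_transition(tr3, c(295, 320))
  expect_equal(gt3$Tg_mid, gt$Tg_mid, tolerance = 1e-6)
  expect_equal(gt3$delta_cp, gt$delta_cp, tolerance = 1e-6)
})

test_that("a flat trace yields no glass transition", {
  Tv <- seq(280, 340, by = 0.1)
  tr <- dsc_trace(Tv, rep(0.01, length(Tv)))
  expect_warning(res <- detect_glass_transition(tr, c(295, 320)),
                 "no glass-transition step")
  expect_null(res)
})

test_that("exotherm tangent onset reproduces the Gaussian closed form", {
  # Gaussian at 365 K with sigma 4 K on a zero baseline: onset 357 K
  Tv <- seq(330, 400, by = 0.05)
  hf <- 1.2 * exp(-(Tv - 365)^2 / (2 * 16))
  tr <- dsc_trace(Tv, hf, heating_rate = 10)
  ev <- detect_exotherm_onset(tr, c(335, 395))
  expect_equal(ev$onset, 357, tolerance = 0.5 / 357)
  expect_equal(ev$peak, 365, tolerance = 1e-3)
  # area = amplitude * sigma * sqrt(2 pi) / heating rate (J/g)
  expect_equal(ev$area, 1.2 * 4 * sqrt(2 * pi) / (10 / 60), tolerance = 5e-3)

  # onset invariant to an added shallow linear baseline
  tr2 <- dsc_trace(Tv, hf + 0.01 * (Tv - 330) / 70, heating_rate = 10)
  ev2 <- detect_exotherm_onset(tr2, c(335, 395))
  expect_equal(ev2$onset, ev$onset, tolerance = 1e-3)

  # pure noise floor: nothing detected
  set.seed(2)
  tr3 <- dsc_trace(Tv, rnorm(length(Tv), sd = 1e-4), heating_rate = 10)
  expect_warning(res <- detect_exotherm_onset(tr3, c(335, 395)), "no exotherm")
  expect_null(res)
})

test_that("Gaussian tangent onset equals center - 2 sigma and the numeric construction", {
  g <- list(center = 423.0, sigma = 1.25)
  expect_equal(tangent_onset(g), 420.5)
  expect_equal(tangent_onset(list(center = 400, sigma = 1e-9)), 400,
               tolerance = 1e-6)
  set.seed(9)
  for (i in 1:100) {
    ce <- runif(1, 380, 430); sg <- runif(1, 0.5, 5)
    expect_equal(tangent_onset(list(center = ce, sigma = sg)),
                 oracle_gaussian_onset(ce, sg), tolerance = 0.05 / 400)
  }
})

test_that("a single melting endotherm is deconvolved exactly", {
  sc <- dsc_scenario(0, noise_sd = 0,
                     melt = data.frame(form = "III", onset = 410.3,
                                       peak = 413.8, area = 50))
  tr <- simulate_dsc(sc)
  dc <- deconvolve_melting(tr, 1, c(402, 424))
  expect_true(dc$converged)
  g <- dc$components[[1]]
  expect_equal(g$center, 413.8, tolerance = 1e-3)
  expect_equal(g$sigma, 1.75, tolerance = 1e-3)
  expect_equal(abs(g$area), 50, tolerance = 1e-3)
})

test_that("overlapping forms II and III are separated with areas within 5%", {
  sc <- dsc_scenario(0, noise_sd = 0,
                     melt = data.frame(form = c("III", "II"),
                                       onset = c(410.3, 414.4),
                                       peak = c(413.8, 416.5),
                                       area = c(40, 20)))
  tr <- simulate_dsc(sc)
  dc <- deconvolve_melting(tr, 2, c(402, 426))
  expect_true(dc$converged)
  centers <- vapply(dc$components, function(g) g$center, numeric(1))
  areas <- abs(vapply(dc$components, function(g) g$area, numeric(1)))
  expect_equal(centers, c(413.8, 416.5), tolerance = 0.2 / 414)
  expect_equal(areas, c(40, 20), tolerance = 0.05)
})

test_that("the four-polymorph melt yields all onsets within 0.5 K", {
  tr <- simulate_dsc(dsc_scenario(0, noise_sd = 0))
  dc <- deconvolve_melting(tr, 4, c(398, 430))
  expect_true(dc$converged)
  onsets <- vapply(dc$components, tangent_onset, numeric(1))
  expect_equal(onsets, c(406.3, 410.3, 414.4, 420.5), tolerance = 0.5 / 410)
  expect_equal(vapply(dc$components, function(g) g$label, character(1)),
               c("IV", "III", "II", "I"))
})

test_that("deconvolution conserves the baseline-corrected melting area", {
  tr <- simulate_dsc(dsc_scenario(0, noise_sd = 0))
  window <- c(398, 430)
  dc <- deconvolve_melting(tr, 4, window)
  idx <- tr$temperatures >= window[1] & tr$temperatures <= window[2]
  Tw <- tr$temperatures[idx]; yw <- tr$heat_flow[idx]
  base <- dc$baseline["intercept"] + dc$baseline["slope"] * Tw
  integral <- sum(diff(Tw) * ((yw - base)[-1] + (yw - base)[-length(yw)]) / 2) /
    (tr$heating_rate / 60)
  expect_equal(sum(vapply(dc$components, function(g) g$area, numeric(1))),
               integral, tolerance = 0.01)
})
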