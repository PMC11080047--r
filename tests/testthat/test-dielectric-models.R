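test_that("HN loss reduces to the Debye peak and matches the complex-arithmetic oracle", {
  # Debye limit: height delta_eps/2 at omega tau = 1
  p <- relaxation_process("alpha", delta_eps = 1, tau_hn = 1 / (2 * pi),
                          a = 1, b = 1)
  expect_equal(hn_loss(p, 1), 0.5, tolerance = 1e-12)

  # general HN values against an independent complex evaluation
  f <- c(0.05, 0.5, 5, 50)
  p2 <- relaxation_process("alpha", delta_eps = 2, tau_hn = 1, a = 0.8, b = 0.6)
  expect_equal(hn_loss(p2, f), oracle_hn_loss(2, 1, 0.8, 0.6, f),
               tolerance = 1e-12)
})

test_that("Cole-Cole loss is symmetric about its maximum on a log-frequency grid", {
  p <- relaxation_process("beta", delta_eps = 0.5, tau_hn = 1e-3,
                          a = 0.4, model = "CC")
  k <- seq(-4, 4, by = 0.01)
  f0 <- 1 / (2 * pi * 1e-3)
  y_left <- hn_loss(p, f0 * 10^(-k))
  y_right <- hn_loss(p, f0 * 10^(k))
  expect_lt(max(abs(y_left - y_right)), 1e-9)
})

test_that("HN loss is non-negative with a single maximum in log frequency", {
  set.seed(11)
  f <- 10^seq(-4, 8, by = 0.05)
  for (i in 1:25) {
    p <- relaxation_process("alpha", delta_eps = runif(1, 0.1, 10),
                            tau_hn = 10^runif(1, -6, 2),
                            a = runif(1, 0.3, 1), b = runif(1, 0.3, 1))
    y <- hn_loss(p, f)
    expect_true(all(y >= 0))
    interior <- which(diff(sign(diff(y))) < 0)
    expect_length(interior, 1)
  }
})

test_that("composite loss is additive and conductivity has log-log slope -s", {
  f <- 10^seq(-1, 6, by = 0.2)
  expect_equal(composite_loss(list(), conductivity_term(0), f),
               numeric(length(f)))

  p1 <- relaxation_process("alpha", 2, 1e-2, 0.9, 0.7)
  p2 <- relaxation_process("beta", 0.4, 1e-5, 0.5, model = "CC")
  expect_identical(composite_loss(list(p1, p2), NULL, f),
                   hn_loss(p1, f) + hn_loss(p2, f))

  y <- composite_loss(list(), conductivity_term(1e-10, s_exp = 0.9), f)
  slopes <- diff(log10(y)) / diff(log10(f))
  expect_equal(slopes, rep(-0.9, length(slopes)), tolerance = 1e-10)

  # two well-separated Debye processes peak at omega = 1/tau each
  pa <- relaxation_process("alpha", 1, 1e-1, 1, 1)
  pb <- relaxation_process("beta", 1, 1e-5, 1, model = "CC")
  fgrid <- 10^seq(-2, 8, by = 0.001)
  y2 <- composite_loss(list(pa, pb), NULL, fgrid)
  imax <- which(diff(sign(diff(y2))) < 0) + 1L
  expect_length(imax, 2)
  expect_equal(fgrid[imax], 1 / (2 * pi * c(1e-1, 1e-5)), tolerance = 1e-2)
})

test_that("tau_max agrees with brute-force peak search over random HN shapes", {
  # CC identity first
  expect_equal(tau_max(relaxation_process("beta", 1, 2e-4, 0.5, model = "CC")),
               2e-4)
  expect_equal(tau_max(relaxation_process("alpha", 1, 1, 1, 1)), 1)

  set.seed(7)
  for (i in 1:100) {
    a <- runif(1, 0.3, 1); b <- runif(1, 0.3, 1)
    tau <- 10^runif(1, -5, 1)
    expect_equal(tau_max(list(tau_hn = tau, a = a, b = b)),
                 oracle_tau_peak(1, tau, a, b), tolerance = 5e-3)
  }
})

test_that("tau_hn_from_max inverts tau_max exactly", {
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 0.3, 1); b <- runif(1, 0.3, 1)
    tau_pk <- 10^runif(1, -6, 1)
    p <- relaxation_process("alpha", 1, tau_hn_from_max(tau_pk, a, b), a, b)
    expect_equal(tau_max(p), tau_pk, tolerance = 1e-12)
  }
})

test_that("frequency-domain KWW reduces to the Debye loss at beta = 1", {
  tau <- 1 / (2 * pi)
  f <- 10^seq(-1, 6, by = 0.25)
  debye <- hn_loss(relaxation_process("alpha", 1, tau, 1, 1), f)
  kww <- kww_loss(kww_shape(1, tau), f, n_per_decade = 5000)
  expect_equal(kww, debye, tolerance = 1e-6)
})

test_that("KWW loss matches an independent adaptive-quadrature evaluation", {
  sh <- kww_shape(0.55, 1e-2, delta_eps = 2)
  f <- c(0.5, 5, 50, 500, 5e3)
  expect_equal(kww_loss(sh, f), oracle_kww_loss(0.55, 1e-2, 2, f),
               tolerance = 1e-4)
})

test_that("the KWW peak narrows monotonically as beta increases", {
  fwhm <- function(beta) {
    f <- 10^seq(-5, 7, by = 0.01)
    y <- kww_loss(kww_shape(beta, 1e-2), f)
    y <- y / max(y)
    above <- range(which(y >= 0.5))
    log10(f[above[2]]) - log10(f[above[1]])
  }
  widths <- vapply(c(0.4, 0.55, 0.7, 1.0), fwhm, numeric(1))
  expect_true(all(diff(widths) < 0))
})
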