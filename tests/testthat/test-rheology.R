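# Rheology estimators against constructed signals and independent oracles.

test_that("multi-tau correlator: constant, white noise, OU vs O(N^2) oracle", {
  # constant series: correlation = c^2 at every lag
  mc <- multitau_correlate(rep(3, 200), dt = 0.1)
  expect_true(all(abs(mc$acf - 9) < 1e-12))

  # white noise: variance at lag 0, near zero beyond
  set.seed(1)
  wn <- rnorm(20000, sd = 2)
  mw <- multitau_correlate(wn, dt = 1)
  expect_equal(mw$acf[1], 4, tolerance = 0.05)
  expect_true(all(abs(mw$acf[-1]) < 0.15))

  # OU process: agrees with the direct autocorrelation at every shared lag
  x <- ou_series(10000, tau = 5, var = 2, dt = 0.1, seed = 2)
  mt <- multitau_correlate(x, dt = 0.1)
  # compare over the resolved range (lags within 3 correlation times; both
  # estimators are pure noise far beyond that)
  keep <- mt$lag <= 15
  direct <- direct_acf(x, round(mt$lag[keep] / 0.1))
  expect_lt(max(abs(mt$acf[keep] - direct) / direct[1]), 0.02)

  expect_error(multitau_correlate(1:100, dt = c(0, 1, 3)), "non-uniform")
})

test_that("GK estimator: zero series, known exponential, linearity, fallback", {
  z <- synthetic_stress(rep(0, 1000))
  expect_true(all(gk_complex_modulus(z)$G == 0))

  # single-exponential autocorrelation injected into all channels: the
  # estimator returns V/(5 kB T) * 3 * C exp(-t/tau) (off-diagonals carry
  # the signal, the normal differences vanish for identical diagonals)
  x <- ou_series(200000, tau = 8, var = 1, dt = 0.1, seed = 3)
  st <- synthetic_stress(x, dt = 0.1, volume = 50, temperature = 2,
                         diag_sig = list(x, x, x))
  g <- gk_complex_modulus(st)
  pref <- 50 / (5 * 2) * 3
  expect_equal(g$G[1], pref, tolerance = 0.05)
  keep <- g$t < 20
  expect_lt(max(abs(g$G[keep] - pref * exp(-g$t[keep] / 8))) / pref, 0.05)

  # homogeneity: doubling every stress channel quadruples G*(t)
  st2 <- synthetic_stress(2 * x, dt = 0.1, volume = 50, temperature = 2,
                          diag_sig = list(2 * x, 2 * x, 2 * x))
  g2 <- gk_complex_modulus(st2)
  expect_equal(g2$G, 4 * g$G, tolerance = 1e-12)

  # normal differences contribute through the 1/6 coefficient: distinct
  # diagonal signals change the estimate by V/(5T) * (1/6) * sum C_N
  y <- ou_series(200000, tau = 8, var = 1, dt = 0.1, seed = 4)
  stn <- synthetic_stress(x, dt = 0.1, volume = 50, temperature = 2,
                          diag_sig = list(y, rep(0, length(y)), rep(0, length(y))))
  gn <- gk_complex_modulus(stn)
  # N_xy = y, N_xz = y, N_yz = 0 -> extra (1/6)(C_y + C_y) at lag 0
  expect_equal(gn$G[1], 50 / 10 * (3 * 1 + 2 / 6 * 1), tolerance = 0.05)

  # missing diagonals: flagged off-diagonal-only fallback
  dfr <- as.data.frame(st)[c("t", "strain", "sxy", "sxz", "syz", "Tkin")]
  stf <- stress_series(dfr, volume = 50, temperature = 2)
  gf <- gk_complex_modulus(stf)
  expect_true(attr(gf, "offdiag_only"))
  expect_equal(gf$G[1], 50 / (3 * 2) * 3, tolerance = 0.05)
})

test_that("OS moduli: constructed signal is recovered exactly", {
  t <- seq(0, 200, by = 0.05)
  w <- 0.5
  strain <- 0.1 * sin(w * t)
  stress <- 0.1 * (2 * sin(w * t) + 1 * cos(w * t))
  d <- data.frame(t = t, strain = strain, sxy = stress)
  m <- os_moduli(d, omega = w)
  expect_equal(m$Gp, 2, tolerance = 1e-8)
  expect_equal(m$Gpp, 1, tolerance = 1e-8)
  expect_equal(m$delta, atan2(1, 2), tolerance = 1e-8)
  expect_equal(m$sigma0, 0.1 * sqrt(5), tolerance = 1e-8)

  # in-phase stress: purely elastic, G'' = 0
  d2 <- data.frame(t = t, strain = strain, sxy = 0.3 * sin(w * t))
  m2 <- os_moduli(d2, omega = w)
  expect_equal(m2$Gpp, 0, tolerance = 1e-8)
  expect_equal(m2$delta, 0, tolerance = 1e-8)

  # a strong commensurate harmonic (the signature of a nonlinear response)
  # survives cycle-averaging and triggers the nonlinearity error
  d3 <- data.frame(t = t, strain = strain,
                   sxy = 0.05 * sin(w * t) + 0.2 * sin(3 * w * t))
  expect_error(os_moduli(d3, omega = w), "residual")
})

test_that("OS moduli recover the closed form for a simulated Maxwell element", {
  # constitutive ODE oracle: dS/dt = G gdot - S/tau, integrated at fine dt
  G1 <- 5; tau1 <- 2; w <- 0.8; g0 <- 0.1
  dt <- 1e-3
  t <- seq(0, 12 * 2 * pi / w, by = dt)
  S <- numeric(length(t))
  for (i in 2:length(t)) {
    gdot <- g0 * w * cos(w * t[i - 1])
    S[i] <- S[i - 1] + dt * (G1 * gdot - S[i - 1] / tau1)
  }
  keep <- seq(1, length(t), by = 50)
  d <- data.frame(t = t[keep], strain = g0 * sin(w * t[keep]), sxy = S[keep])
  m <- os_moduli(d, omega = w, discard_cycles = 4)
  expect_equal(m$Gp, G1 * (w * tau1)^2 / (1 + (w * tau1)^2), tolerance = 0.01)
  expect_equal(m$Gpp, G1 * w * tau1 / (1 + (w * tau1)^2), tolerance = 0.01)
})

test_that("linear-regime check finds the analytic nonlinearity threshold", {
  # ideal linear material: every amplitude accepted
  sweep_lin <- data.frame(gamma0 = c(0.01, 0.05, 0.1, 0.2),
                          Gp = rep(2, 4), Gpp = rep(1, 4))
  expect_equal(as.numeric(linear_regime_check(sweep_lin)), 0.2)

  # cubic stress term: apparent modulus G(1 + c gamma0^2); the window ends
  # where c gamma0^2 > 10%
  c3 <- 4
  g0s <- c(0.01, 0.05, 0.1, 0.15, 0.2, 0.3)
  sweep_nl <- data.frame(gamma0 = g0s,
                         Gp = 2 * (1 + c3 * g0s^2),
                         Gpp = rep(1, length(g0s)))
  got <- as.numeric(linear_regime_check(sweep_nl))
  expect_equal(got, max(g0s[c3 * g0s^2 / (1 + c3 * g0s[1]^2) <= 0.1]))
})

test_that("Maxwell fits: exact recovery, closed-form identities, two modes", {
  # one mode, exact model class -> recovered to high precision
  tt <- 10^seq(-1, 3, length.out = 60)
  d1 <- structure(data.frame(t = tt, G = 5 * exp(-tt / 100)),
                  class = c("complex_modulus", "data.frame"))
  f1 <- fit_maxwell(d1, n_modes = 1)
  expect_equal(unname(coef(f1)), c(5, 100), tolerance = 1e-6)

  # at omega tau = 1 the single mode gives G' = G'' = G/2
  sp <- predict(f1, omega = 1 / coef(f1)[["tau1"]])
  expect_equal(sp$Gp, 2.5, tolerance = 1e-5)
  expect_equal(sp$Gpp, 2.5, tolerance = 1e-5)

  # two modes separated by x100 in tau, recovered within 2%
  d2 <- structure(data.frame(t = tt, G = 4 * exp(-tt / 2) + 1 * exp(-tt / 200)),
                  class = c("complex_modulus", "data.frame"))
  f2 <- fit_maxwell(d2, n_modes = 2)
  m <- f2$modes[order(f2$modes$tau), ]
  expect_equal(m$G, c(4, 1), tolerance = 0.02)
  expect_equal(m$tau, c(2, 200), tolerance = 0.02)

  # frequency-domain fit of the same model class
  ww <- 10^seq(-3, 1, length.out = 40)
  spec <- maxwell_spectrum_exact(5, 100, ww)
  f3 <- fit_maxwell(spec, n_modes = 1)
  expect_equal(unname(coef(f3)), c(5, 100), tolerance = 1e-4)

  # automatic mode count settles on the generating count
  f4 <- fit_maxwell(d2)
  expect_equal(f4$n_modes, 2)
})

test_that("dynamic viscosity: analytic integral, quadrature, gel flag", {
  f1 <- fit_maxwell(structure(
    data.frame(t = 10^seq(-1, 3, length.out = 50),
               G = 5 * exp(-10^seq(-1, 3, length.out = 50) / 100)),
    class = c("complex_modulus", "data.frame")), n_modes = 1)
  expect_equal(dynamic_viscosity(f1), 500, tolerance = 1e-5)

  # zero modulus -> zero viscosity
  z <- structure(data.frame(t = seq(0, 10, 0.1), G = 0),
                 class = c("complex_modulus", "data.frame"))
  expect_equal(dynamic_viscosity(z), 0)

  # numerically integrated two-mode series vs sum G_i tau_i within 0.5%
  tt <- c(0, 10^seq(-3, 3.6, length.out = 4000))
  g2 <- structure(data.frame(t = tt, G = 4 * exp(-tt / 2) + exp(-tt / 200)),
                  class = c("complex_modulus", "data.frame"))
  expect_equal(dynamic_viscosity(g2), 4 * 2 + 1 * 200, tolerance = 0.005)

  # non-decaying G*(t): infinite-viscosity gel flag
  gel <- structure(data.frame(t = tt, G = 2 + exp(-tt / 5)),
                   class = c("complex_modulus", "data.frame"))
  v <- dynamic_viscosity(gel)
  expect_true(is.infinite(v))
  expect_true(attr(v, "gel"))
})

test_that("crossover finder: single mode, none, two sign changes", {
  ww <- 10^seq(-4, 2, length.out = 200)
  # single-mode Maxwell: exactly one crossover at omega = 1/tau
  sp <- maxwell_spectrum_exact(3, 50, ww)
  cw <- crossover_frequencies(sp)
  expect_equal(nrow(cw), 1)
  expect_equal(cw$omega, 1 / 50, tolerance = 0.01)
  expect_equal(cw$below, "viscous")
  expect_equal(cw$above, "elastic")

  # fully viscous spectrum: empty list
  spv <- modulus_spectrum(ww, 0.1 * ww^2 / (1 + ww^2), ww)
  expect_equal(nrow(crossover_frequencies(spv)), 0)

  # constructed spectrum with two sign changes, both found in order
  sp2 <- modulus_spectrum(ww, rep(1, length(ww)),
                          exp(abs(log10(ww) + 1)) / exp(1) * 1.0000001)
  # G'' dips below G' around omega = 0.1
  cw2 <- crossover_frequencies(sp2)
  expect_equal(nrow(cw2), 2)
  expect_true(all(diff(cw2$omega) > 0))
  expect_equal(cw2$below[1], "viscous")
  expect_equal(cw2$above[1], "elastic")
  expect_equal(cw2$above[2], "viscous")

  # brute-force agreement: dense-grid sign scan of the same model
  dense_w <- 10^seq(-4, 2, length.out = 20000)
  dsp <- maxwell_spectrum_exact(3, 50, dense_w)
  brute <- dense_w[which(diff(sign(dsp$Gp - dsp$Gpp)) != 0)]
  expect_lt(abs(log10(cw$omega) - log10(brute[1])), 0.01)
})

test_that("response classification on closed-form spectra", {
  ww <- 10^seq(-4, 1, length.out = 100)
  expect_equal(classify_response(maxwell_spectrum_exact(3, 50, ww))$classification,
               "maxwell_fluid")
  # Kelvin-Voigt: constant G' plateau with G'' = eta omega
  expect_equal(classify_response(modulus_spectrum(ww, rep(2, 100), 0.5 * ww))$classification,
               "kelvin_voigt_solid")
  # viscous fluid: G'' above G' everywhere
  expect_equal(classify_response(modulus_spectrum(ww, 1e-3 * ww^2, ww))$classification,
               "viscous_fluid")
  # insufficient bandwidth
  expect_equal(classify_response(maxwell_spectrum_exact(3, 50, c(1, 1.5, 2, 3)))$classification,
               "indeterminate")
})
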