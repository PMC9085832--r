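test_that("the Boltzmann model has its algebraic midpoint and monotone shape", {
  expect_equal(boltzmann_model(-100.6, V_half = -100.6, z_delta = 4), 0.5)
  V <- seq(-150, -70, by = 5)
  y <- boltzmann_model(V, -100, 3.5)
  expect_false(is.unsorted(rev(y)))  # activation grows with hyperpolarisation
})

test_that("tail-current normalisation maps the largest-magnitude amplitude to one", {
  expect_equal(normalize_tail_currents(c(0, 2, 4)), c(0, 0.5, 1))
  expect_equal(normalize_tail_currents(c(3, 3, 3)), c(1, 1, 1))
  # inward (negative) currents: order preserved, values in [0, 1]
  inward <- c(-0.05, -1, -2, -3.9, -4)
  norm <- normalize_tail_currents(inward)
  expect_true(all(norm >= 0 & norm <= 1))
  expect_false(is.unsorted(norm))
  expect_equal(norm[5], 1)
  expect_error(normalize_tail_currents(c(0, 0)), "all-zero")
})

test_that("Boltzmann fitting recovers parameters and flags wrong-direction data", {
  g <- generate_activation_traces(V_half = -96.1, z_delta = 3.5,
                                  amp_satV = 0.95, noise_sd = 0,
                                  n_recordings = 1, seed = 11)
  f <- fit_boltzmann(g$recordings[[1]]$voltage_mV,
                     g$recordings[[1]]$rel_tail)
  expect_equal(f$V_half, -96.1, tolerance = 1e-6)
  expect_equal(f$z_delta, 3.5, tolerance = 1e-6)
  expect_equal(f$amp_satV, 0.95, tolerance = 1e-6)
  # model value at V_half is amp/2
  expect_equal(boltzmann_model(f$V_half, f$V_half, f$z_delta, f$amp_satV),
               f$amp_satV / 2)
  # z_delta = slope x RT/F scales proportionally with the assumed T
  f2 <- fit_boltzmann(g$recordings[[1]]$voltage_mV,
                      g$recordings[[1]]$rel_tail, temperature = 310)
  expect_equal(f2$z_delta / 310, f$z_delta / 293.15, tolerance = 1e-4)
  expect_equal(f2$V_half, f$V_half, tolerance = 1e-4)
  V <- seq(-150, -70, 10)
  expect_warning(fit_boltzmann(V, seq(0.1, 0.9, length.out = length(V))),
                 "sign convention")
})

test_that("dV1/2 is zero for identical fit sets and propagates SEM", {
  vh <- c(-101, -100, -99.5, -100.5)
  d0 <- delta_v12(vh, vh)
  expect_equal(d0$delta_mV, 0)
  d <- delta_v12(vh, vh + 17.9)
  expect_equal(d$delta_mV, 17.9)
  expect_equal(d$sem, sqrt(2) * sem(vh))
})

test_that("delayed-exponential fitting recovers tau, delay and handles noise", {
  tr <- generate_activation_traces(tau_ms = 100, delay_ms = 20,
                                   noise_sd = 0, n_recordings = 1,
                                   trace_noise_sd = 0, seed = 21)
  f <- fit_exponential(tr$traces[[1]]$t_ms, tr$traces[[1]]$I)
  expect_equal(f$tau, 100, tolerance = 1e-4)
  expect_equal(f$delay, 20, tolerance = 0.5)
  # fixed-delay mode
  f2 <- fit_exponential(tr$traces[[1]]$t_ms, tr$traces[[1]]$I, delay = 20)
  expect_equal(f2$tau, 100, tolerance = 1e-6)
  # pure decaying exponential with zero delay
  t <- seq(0, 600, by = 2)
  f3 <- fit_exponential(t, 2 * exp(-t / 100), delay = 0)
  expect_equal(f3$tau, 100, tolerance = 1e-6)
  expect_equal(f3$A, 2, tolerance = 1e-6)
  # 5% amplitude noise: tau bias below 5% over 100 simulations
  err <- vapply(1:100, function(k) {
    trn <- generate_activation_traces(tau_ms = 100, delay_ms = 20,
                                      noise_sd = 0, trace_noise_sd = 0.05,
                                      n_recordings = 1, seed = 5000 + k)
    fit_exponential(trn$traces[[1]]$t_ms, trn$traces[[1]]$I)$tau - 100
  }, numeric(1))
  expect_lt(abs(mean(err)) / 100, 0.05)
})

test_that("Hill fitting honours the half-maximum identity and recovers truth", {
  expect_equal(hill_model(0.40, 0.40, 1.5), 0.5)
  expect_equal(hill_model(0.80, 0.40, 1.5), 1 / (1 + 0.5^1.5))
  b <- generate_binding_data(BC50 = 0.26, H = 1.8, noise_sd = 0, seed = 31)
  f <- fit_hill(b$conc_uM, b$F_over_Fmax)
  expect_equal(f$BC50, 0.26, tolerance = 1e-8)
  expect_equal(f$H, 1.8, tolerance = 1e-8)
  expect_equal(hill_model(f$BC50, f$BC50, f$H), 0.5)
  expect_error(fit_hill(c(0.1, 0.5, 2.5), rep(0.4, 3)), "all responses")
})

test_that("cPCF subtraction clips negative bound fractions with a flag and validates its inputs", {
  img <- generate_cpcf_images(bound_fraction = 0, noise_sd = 0, seed = 41)
  # subtracting too much green produces a negative raw ratio
  r <- cpcf_subtract(img$green - 5 * img$roi_dome, img$red, img$roi_dome,
                     img$roi_bath, img$roi_pipette, img$f_max)
  expect_true(r$clipped)
  expect_equal(r$F_over_Fmax, 0)
  expect_lt(r$F_over_Fmax_raw, 0)
  expect_error(
    cpcf_subtract(img$green, 0 * img$red, img$roi_dome, img$roi_bath,
                  img$roi_pipette, img$f_max), "zero red")
  expect_error(
    cpcf_subtract(img$green, img$red, img$roi_dome, img$roi_dome,
                  img$roi_pipette, img$f_max), "disjoint")
})

test_that("fit-engine bias vanishes as noise goes to zero", {
  for (sigma in c(0, 0.01, 0.05)) {
    vh <- vapply(1:20, function(k) {
      g <- generate_activation_traces(V_half = -100.6, noise_sd = sigma,
                                      n_recordings = 1, seed = 6000 + k)
      fit_boltzmann(g$recordings[[1]]$voltage_mV,
                    g$recordings[[1]]$rel_tail)$V_half
    }, numeric(1))
    tol <- if (sigma == 0) 1e-6 else 60 * sigma
    expect_lt(abs(mean(vh) + 100.6), tol)
  }
})
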