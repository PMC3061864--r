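test_that("parameter containers validate their invariants", {
  expect_error(pulse_parameters(-1, 640e-9, 120e-6, "top-hat",
                                1e-16, 0.1), "positive")
  expect_error(pulse_parameters(1e-6, 640e-9, 120e-6, "top-hat",
                                1e-16, 1.5), "quantum_yield")
  expect_error(sample_geometry(-0.1), "absorbance")
  expect_error(multipulse_schedule(1, 1, 0, 1.2), "recovery")
  expect_error(multipulse_schedule(-1, 1), ">= 0")
})

test_that("excitation strength is linear in energy and matches hand arithmetic", {
  p1 <- phytochrome_pulse()
  p2 <- p1; p2$energy <- 2 * p1$energy
  expect_equal(excitation_strength(p2), 2 * excitation_strength(p1),
               tolerance = 1e-12)
  # independent hand-arithmetic oracle: photons / (hc/lambda) / area
  photons <- 1.65e-6 / (6.62607015e-34 * 2.99792458e8 / 640e-9)
  x_hand <- photons / (pi * (60e-4)^2) * 1.08e-16 * 0.1
  expect_equal(excitation_strength(p1), x_hand, tolerance = 1e-3)
})

test_that("the Gaussian peak flux carries the 2-D integral-equality factor", {
  x_th <- excitation_strength(phytochrome_pulse())
  x_g <- excitation_strength(phytochrome_pulse(profile = "gaussian"))
  expect_equal(x_g / x_th, log(2), tolerance = 1e-12)
  # oracle: equate total photons of the two radial profiles numerically
  fwhm <- 120e-6; s <- fwhm / (2 * sqrt(2 * log(2)))
  rr <- seq(0, 10 * fwhm, length.out = 2e5)
  gauss_total <- sum(exp(-rr^2 / (2 * s^2)) * 2 * pi * rr) * diff(rr)[1]
  peak_ratio <- (pi * (fwhm / 2)^2) / gauss_total
  expect_equal(x_g / x_th, peak_ratio, tolerance = 1e-4)
})

test_that("orientational fraction obeys its geometric limits", {
  expect_equal(orientational_fraction(5, 0), 0)          # perpendicular
  expect_equal(orientational_fraction(0, c(0, 0.5, 1)), rep(0, 3))
  expect_equal(orientational_fraction(0, 0.5, "circular"), 0)
  expect_gt(orientational_fraction(100, 1), 0.999)       # saturation
  expect_gt(orientational_fraction(1, 0, "circular"), 0) # circular at p=0
  expect_error(orientational_fraction(1, 1.2), "p must")
  # monotone increasing in x at fixed orientation
  expect_true(all(diff(orientational_fraction(seq(0, 5, 0.2), 0.7)) > 0))
})

test_that("ensemble fraction matches quadrature, saturates below 1, grows concavely", {
  xg <- c(0.05, 0.2, 0.5076, 2, 10)
  for (x in xg)
    expect_equal(ensemble_fraction(x),
                 quad_oracle(function(p) orientational_fraction(x, p)),
                 tolerance = 1e-8)
  expect_equal(ensemble_fraction(0), 0)
  expect_lt(ensemble_fraction(1e4), 1)       # never reaches unity
  f <- ensemble_fraction(seq(0, 3, 0.1))
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(diff(f)) < 0))
  # circular absorber averages likewise
  expect_equal(ensemble_fraction(0.7, "circular"),
               quad_oracle(function(p)
                 orientational_fraction(0.7, p, "circular")),
               tolerance = 1e-8)
})

test_that("Taylor and quadrature ensemble averages agree below x = 0.1", {
  for (x in c(1e-4, 0.01, 0.05, 0.1)) {
    expect_equal(ensemble_fraction(x, method = "taylor"),
                 ensemble_fraction(x), tolerance = 1e-6)
    expect_equal(anisotropy_factor(x, method = "taylor"),
                 anisotropy_factor(x), tolerance = 1e-6)
  }
  expect_warning(ensemble_fraction(2, method = "taylor"), "validity")
})

test_that("beam profiles give constant/top-hat and monotone Gaussian fractions", {
  r <- seq(0, 150e-6, length.out = 16)
  th <- beam_profile_fraction(phytochrome_pulse(), r)
  expect_true(all(th$fraction[r <= 60e-6] == th$fraction[1]))
  expect_true(all(th$fraction[r > 60e-6] == 0))
  ga <- beam_profile_fraction(phytochrome_pulse(profile = "gaussian"), r)
  expect_true(all(diff(ga$fraction) < 0))
  expect_equal(ga$x[1] / th$x[1], log(2), tolerance = 1e-12)
})

test_that("optical anisotropy starts at 0.4, decreases, and matches quadrature", {
  expect_equal(anisotropy_factor(1e-8), 0.4, tolerance = 1e-6)
  x_work <- excitation_strength(phytochrome_pulse())
  num <- quad_oracle(function(p)
    orientational_fraction(x_work, p) * (3 * p^2 - 1) / 2)
  den <- quad_oracle(function(p) orientational_fraction(x_work, p))
  expect_equal(anisotropy_factor(x_work), num / den, tolerance = 1e-6)
  rx <- anisotropy_factor(seq(0.01, 5 * x_work, length.out = 40))
  expect_true(all(diff(rx) < 0))
  expect_lt(anisotropy_factor(5 * x_work), 0.33)  # markedly below 0.4
  expect_true(all(rx > 0 & rx <= 0.4))
})

test_that("measured anisotropy follows its defining ratio", {
  expect_equal(measured_anisotropy(0.3, 0.3)$r, 0)
  expect_equal(measured_anisotropy(0.5, 0)$r, 1)
  expect_equal(measured_anisotropy(2, 1)$r, (2 - 1) / (2 + 2 * 1))
  expect_equal(measured_anisotropy(2, 1)$magic_angle_signal, 4 / 3)
  expect_error(measured_anisotropy(2, -1), "undefined")
})

test_that("degenerate-transition anisotropy spans 0.1 to -0.2 monotonically", {
  expect_equal(anisotropy_degenerate(0), 0.1)
  expect_equal(anisotropy_degenerate(90), -0.2)
  ang <- seq(0, 90, 5)
  expect_true(all(diff(anisotropy_degenerate(ang)) < 0))
  expect_error(anisotropy_degenerate(120), "degrees")
})

test_that("dipole angles are recovered from anisotropy ratios", {
  expect_equal(extract_dipole_angle(0.4, 0.4), 0)
  expect_equal(extract_dipole_angle(0, 0.4), 54.7, tolerance = 1e-2)
  expect_equal(extract_dipole_angle(-0.2, 0.4), 90)
  expect_error(extract_dipole_angle(0.5, 0.4), "infeasible")
  # self-consistency: r = r_opt * P2(cos beta)
  beta <- 25
  r <- 0.35 * (3 * cos(beta * pi / 180)^2 - 1) / 2
  expect_equal(extract_dipole_angle(r, 0.35), beta, tolerance = 1e-10)
})

test_that("beam-ratio correction matches the printed factors and the 2-D oracle", {
  expect_equal(beam_ratio_correction(1), 0.71, tolerance = 0.005)
  expect_equal(beam_ratio_correction(2), 0.89, tolerance = 0.005)
  expect_equal(beam_ratio_correction(3), 0.95, tolerance = 0.005)
  for (R in c(0.5, 1, 2, 3, 5, 10))
    expect_equal(beam_ratio_correction(R), beam_ratio_oracle(R),
                 tolerance = 1e-4)
  cr <- beam_ratio_correction(seq(0.5, 30, 0.5))
  expect_true(all(diff(cr) > 0))
  expect_equal(beam_ratio_correction(1e6), 1, tolerance = 1e-9)
})

test_that("depth averaging reproduces the surface value at A = 0 and converges", {
  x0 <- excitation_strength(phytochrome_pulse())
  expect_equal(depth_average_anisotropy(x0, sample_geometry(0)),
               anisotropy_factor(x0))
  r200 <- depth_average_anisotropy(x0, sample_geometry(0.4))
  r1e4 <- depth_average_anisotropy(x0, sample_geometry(0.4,
                                                       n_layers = 1e4))
  expect_equal(r200, r1e4, tolerance = 1e-6)
  # attenuation lowers the average excitation, raising r towards 0.4
  rs <- vapply(c(0, 0.4, 1, 2), function(A)
    depth_average_anisotropy(x0, sample_geometry(A)), numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_true(all(rs <= 0.4))
})

test_that("pulse II on a fully recovered ground state is a single pulse", {
  p <- seq(0, 1, 0.05)
  sch <- multipulse_schedule(0.8, 0.6, recovery = 1)
  expect_equal(multipulse_fraction(sch, p),
               orientational_fraction(0.6, p), tolerance = 1e-14)
  expect_equal(multipulse_fraction(sch), ensemble_fraction(0.6),
               tolerance = 1e-10)
})

test_that("zero-delay equal pulses equal one pulse at doubled power", {
  for (x in c(0.1, 0.5, 1, 2, 5)) {
    sch <- multipulse_schedule(x, x, delay = 0, recovery = 0)
    expect_equal(multipulse_fraction(sch, which = "total"),
                 ensemble_fraction(2 * x), tolerance = 1e-10)
  }
})

test_that("pulse-II ensemble fraction grows with the recovery fraction", {
  x <- excitation_strength(phytochrome_pulse())
  f <- vapply(c(0.13, 0.64, 0.9), function(G)
    multipulse_fraction(multipulse_schedule(x, x, recovery = G)),
    numeric(1))
  expect_true(all(diff(f) > 0))
  # quadrature oracle at each recovery fraction
  for (i in seq_along(f)) {
    G <- c(0.13, 0.64, 0.9)[i]
    oracle <- quad_oracle(function(p)
      (1 - (1 - G) * orientational_fraction(x, p)) *
        orientational_fraction(x, p))
    expect_equal(f[i], oracle, tolerance = 1e-8)
  }
})

test_that("multipulse Taylor forms agree with quadrature below x = 0.1", {
  for (x in c(0.02, 0.1)) {
    sch <- multipulse_schedule(x, x, recovery = 0.5)
    expect_equal(multipulse_fraction(sch, method = "taylor"),
                 multipulse_fraction(sch), tolerance = 1e-6)
    expect_equal(multipulse_fraction(sch, which = "total",
                                     method = "taylor"),
                 multipulse_fraction(sch, which = "total"),
                 tolerance = 1e-6)
    expect_equal(multipulse_anisotropy(sch, method = "taylor"),
                 multipulse_anisotropy(sch), tolerance = 1e-6)
  }
})

test_that("multipulse anisotropy reduces to the single-pulse curve and departs with G", {
  expect_equal(multipulse_anisotropy(multipulse_schedule(1e-12, 0.5,
                                                         recovery = 1)),
               anisotropy_factor(0.5), tolerance = 1e-9)
  x <- 0.5
  rG <- vapply(c(0.13, 0.64, 0.9, 1), function(G)
    multipulse_anisotropy(multipulse_schedule(x, x, recovery = G)),
    numeric(1))
  r1 <- anisotropy_factor(x)
  expect_true(all(diff(abs(rG - r1)) < 0))   # smaller G, larger deviation
  # unequal pulse powers give distinct curves matching quadrature
  s21 <- multipulse_schedule(2 * x, x, recovery = 0.5)
  s11 <- multipulse_schedule(x, x, recovery = 0.5)
  oracle <- function(s) {
    fII <- function(p) (1 - (1 - s$recovery) *
                          orientational_fraction(s$x1, p)) *
      orientational_fraction(s$x2, p)
    quad_oracle(function(p) fII(p) * (3 * p^2 - 1) / 2) / quad_oracle(fII)
  }
  expect_equal(multipulse_anisotropy(s21), oracle(s21), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(multipulse_anisotropy(s21),
                                multipulse_anisotropy(s11))))
})

test_that("every fraction lies in [0,1] and every linear anisotropy in [-0.2, 0.4]", {
  xs <- c(0, 10^seq(-3, 1, length.out = 20))
  expect_true(all(ensemble_fraction(xs) >= 0 & ensemble_fraction(xs) <= 1))
  for (x in xs[c(3, 10, 18)]) {
    f <- orientational_fraction(x, seq(0, 1, 0.1))
    expect_true(all(f >= 0 & f <= 1))
  }
  r <- anisotropy_factor(xs)
  expect_true(all(r >= -0.2 & r <= 0.4))
})

test_that("the planted pure-intermediate signal is recovered exactly", {
  sched <- multipulse_schedule(0.5, 0.5, delay = 14, recovery = 0.64)
  mp <- make_multipulse_experiment(schedule = sched, seed = 4)
  rec <- pure_intermediate_signal(mp$S_pp, mp$S_dp, mp$S_pdp, mp$fractions)
  expect_lt(max(abs(rec$values - mp$truth$S_int$values)), 1e-12)
  # zero intermediate: S_pdp built without the intermediate term
  S_pdp0 <- data_matrix(mp$S_pp$times, mp$S_pp$channels,
                        mp$S_pp$values +
                          mp$fractions$ground_available * mp$S_dp$values)
  rec0 <- pure_intermediate_signal(mp$S_pp, mp$S_dp, S_pdp0, mp$fractions)
  expect_lt(max(abs(rec0$values)), 1e-12)
  # axis mismatch is rejected
  shifted <- data_matrix(mp$S_pp$times + 1, mp$S_pp$channels,
                         mp$S_pp$values)
  expect_error(pure_intermediate_signal(shifted, mp$S_dp, mp$S_pdp,
                                        mp$fractions), "axes")
})

test_that("the extracted intermediate refits to its planted lifetime within 1%", {
  sched <- multipulse_schedule(0.5, 0.5, delay = 14, recovery = 0.64)
  mp <- make_multipulse_experiment(schedule = sched, seed = 8)
  rec <- pure_intermediate_signal(mp$S_pp, mp$S_dp, mp$S_pdp, mp$fractions)
  fit <- fit_global(fit_problem(rec, build_sequential_scheme(c(1 / 3, 0)),
                                offset_enabled = FALSE))
  expect_equal(fit$lifetimes[1], 5, tolerance = 0.01)
})
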